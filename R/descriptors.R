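# Post-processing of quantum-chemical outputs: conceptual-DFT global
# reactivity descriptors from frontier-orbital energies, COSMO-RS
# sigma-profile region areas, and QTAIM bond-critical-point classification.
# Nothing here runs an electronic-structure calculation; the inputs are
# user-supplied tables.

#' Global conceptual-DFT reactivity descriptors
#'
#' From HOMO/LUMO energies computes the frontier gap
#' `gap = E_LUMO - E_HOMO`, chemical potential `mu = (E_HOMO + E_LUMO)/2`,
#' electronegativity `chi = -mu`, global hardness `eta = gap/2`,
#' electrophilicity index `omega = mu^2/(2*eta)` and the single-species
#' maximum charge-transfer index `dn_max = chi/eta`. All descriptors are in
#' eV except `dn_max` (an eV ratio, dimensionless).
#'
#' @param e_homo HOMO energy(ies), eV.
#' @param e_lumo LUMO energy(ies), eV; must strictly exceed `e_homo`
#'   (a zero gap leaves `omega` undefined).
#' @param species optional label(s) carried into the result.
#' @return A data.frame with one row per species: `species`, `e_homo`,
#'   `e_lumo`, `gap`, `mu`, `chi`, `eta`, `omega`, `dn_max`.
#' @examples
#' global_descriptors(-5.211, -3.110, "lignin")
#' @export
global_descriptors <- function(e_homo, e_lumo, species = NULL) {
  stopifnot(is.numeric(e_homo), is.numeric(e_lumo),
            length(e_homo) == length(e_lumo))
  if (is.null(species)) species <- paste0("species_", seq_along(e_homo))
  bad <- which(e_lumo <= e_homo)
  if (length(bad))
    stop("degenerate frontier orbitals (E_LUMO <= E_HOMO) for: ",
         paste(species[bad], collapse = ", "),
         "; the electrophilicity index is undefined at zero gap")
  gap <- e_lumo - e_homo
  mu <- (e_homo + e_lumo) / 2
  eta <- gap / 2
  data.frame(species = as.character(species),
             e_homo = e_homo, e_lumo = e_lumo,
             gap = gap, mu = mu, chi = -mu, eta = eta,
             omega = mu^2 / (2 * eta),
             dn_max = -mu / eta,
             stringsAsFactors = FALSE)
}

#' Maximum charge-transfer index
#'
#' Two conventions for the maximal electron transfer toward an
#' electrophile: `"pairwise"` uses the two-species expression
#' `(chi_acceptor - chi_donor) / (2 * (eta_acceptor + eta_donor))`, while
#' `"table_single"` is the one-species index `chi/eta` (of the acceptor when
#' both are given). Descriptor tables for metal-biopolymer systems are
#' commonly tabulated with the single-species convention, which is the
#' default here.
#'
#' @param acceptor one row of a [global_descriptors()] table (or any list
#'   with `chi` and `eta`) for the electron acceptor.
#' @param donor same, for the donor; required for the pairwise variant.
#' @param variant `"table_single"` or `"pairwise"`.
#' @return Dimensionless charge-transfer index (scalar).
#' @export
charge_transfer <- function(acceptor, donor = NULL,
                            variant = c("table_single", "pairwise")) {
  variant <- match.arg(variant)
  get1 <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || !is.finite(v[1])) stop("missing descriptor: ", f)
    v[1]
  }
  if (variant == "table_single") {
    return(get1(acceptor, "chi") / get1(acceptor, "eta"))
  }
  if (is.null(donor)) stop("the pairwise variant needs both acceptor and donor")
  (get1(acceptor, "chi") - get1(donor, "chi")) /
    (2 * (get1(acceptor, "eta") + get1(donor, "eta")))
}

#' Sigma-profile region areas and fractions
#'
#' Integrates a COSMO-RS sigma profile (trapezoidal rule) over the three
#' conventional regions of the screening-charge density: hydrogen-bond donor
#' (`sigma < -0.0075` e/A^2), nonpolar (`|sigma| <= 0.0075`), and
#' hydrogen-bond acceptor (`sigma > +0.0075`). Crossing points at the region
#' edges are inserted by linear interpolation so the three areas partition
#' the total exactly.
#'
#' @param sigma screening-charge density grid, e/A^2, strictly increasing.
#' @param p_sigma profile values (surface area density) at each grid point,
#'   all >= 0.
#' @param edge region boundary, e/A^2 (default 0.0075).
#' @return A list with `areas` and `fractions` (named `hbd`, `nonpolar`,
#'   `hba`), `total`, and a `degenerate` flag that is `TRUE` when the total
#'   area is zero (fractions are then `NA`).
#' @export
sigma_regions <- function(sigma, p_sigma, edge = 0.0075) {
  stopifnot(is.numeric(sigma), is.numeric(p_sigma),
            length(sigma) == length(p_sigma), edge > 0)
  if (length(sigma) < 2) stop("a sigma profile needs at least 2 grid points")
  if (any(diff(sigma) <= 0)) stop("'sigma' grid must be strictly increasing")
  if (any(p_sigma < 0)) stop("'p_sigma' must be >= 0")

  # refine the grid with the region edges so each trapezoid lies in one region
  cuts <- c(-edge, edge)
  cuts <- cuts[cuts > min(sigma) & cuts < max(sigma) & !(cuts %in% sigma)]
  if (length(cuts)) {
    p_cut <- stats::approx(sigma, p_sigma, xout = cuts)$y
    ord <- order(c(sigma, cuts))
    p_sigma <- c(p_sigma, p_cut)[ord]
    sigma <- c(sigma, cuts)[ord]
  }
  mid <- (sigma[-length(sigma)] + sigma[-1]) / 2
  piece <- diff(sigma) * (p_sigma[-length(p_sigma)] + p_sigma[-1]) / 2
  region <- ifelse(mid < -edge, "hbd", ifelse(mid > edge, "hba", "nonpolar"))
  areas <- c(hbd = sum(piece[region == "hbd"]),
             nonpolar = sum(piece[region == "nonpolar"]),
             hba = sum(piece[region == "hba"]))
  total <- sum(areas)
  degenerate <- total == 0
  list(areas = areas,
       fractions = if (degenerate) stats::setNames(rep(NA_real_, 3), names(areas))
                   else areas / total,
       total = total,
       degenerate = degenerate)
}

#' Classify QTAIM bond critical points
#'
#' From the electron density descriptors at a bond critical point computes
#' the total energy density `h = G + V` and the ratio `G/|V|`, then labels
#' the interaction: `"covalent"` when the Laplacian of the density is
#' negative (shared-shell); otherwise `"partially_covalent"` when
#' `G/|V| < 1` (equivalently `h < 0`, cohesion dominating) and
#' `"noncovalent_weak"` when `G/|V| >= 1` (kinetic energy dominating; the
#' boundary ratio of exactly 1 falls in this class).
#'
#' @param rho electron density at the BCP, a.u.
#' @param lap_rho Laplacian of the density, a.u.
#' @param g kinetic energy density `G(rc)`, a.u., >= 0.
#' @param v potential energy density `V(rc)`, a.u., <= 0 and nonzero.
#' @param bcp_id optional labels.
#' @return A data.frame with columns `bcp_id`, `rho`, `lap_rho`, `g`, `v`,
#'   `h`, `ratio`, `class`.
#' @export
classify_bcp <- function(rho, lap_rho, g, v, bcp_id = NULL) {
  n <- length(g)
  stopifnot(length(lap_rho) == n, length(v) == n, length(rho) == n)
  if (is.null(bcp_id)) bcp_id <- paste0("bcp_", seq_len(n))
  if (any(g < 0)) stop("'g' (kinetic energy density) must be >= 0")
  if (any(v > 0)) stop("'v' (potential energy density) must be <= 0")
  if (any(v == 0)) stop("v = 0 at ", paste(bcp_id[v == 0], collapse = ", "),
                        ": the G/|V| ratio is undefined")
  h <- g + v
  ratio <- g / abs(v)
  cls <- ifelse(lap_rho < 0, "covalent",
                ifelse(ratio < 1 & h < 0, "partially_covalent",
                       "noncovalent_weak"))
  data.frame(bcp_id = as.character(bcp_id), rho = rho, lap_rho = lap_rho,
             g = g, v = v, h = h, ratio = ratio, class = cls,
             stringsAsFactors = FALSE)
}
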