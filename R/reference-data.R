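# Published reference values for Cu2+ biosorption on olive-waste powder
# (OWP), its sodium-alginate composite (OWPSA) and pure alginate, embedded as
# plain data.frames. These are the printed inputs the package's worked
# examples and consistency checks run on; none of them is measured or fitted
# here.

#' Reference SLMRG parameter sets for Cu2+ on olive-waste adsorbents
#'
#' Fitted SLMRG parameters reported for Cu2+ uptake on olive-waste powder
#' (OWP), the olive-waste/sodium-alginate composite (OWPSA) and pure alginate
#' at 293, 303 and 313 K, together with the published saturation capacity
#' and goodness-of-fit statistics.
#'
#' @return A data.frame with columns `adsorbent`, `temperature` (K), `n`,
#'   `nm` (mg/g), `a` (1e-23 J*L/mg), `b` (L/mg), `w` (mg/L), `qsat` (mg/g,
#'   as published), `r2`, `rmse`.
#' @export
ref_slmrg_params <- function() {
  data.frame(
    adsorbent = rep(c("OWP", "OWPSA", "alginate"), each = 3),
    temperature = rep(c(293, 303, 313), 3),
    n = c(2.037, 2.422, 1.787, 2.860, 2.874, 2.0020, 0.696, 0.614, 0.481),
    nm = c(50.391, 45.050, 73.937, 44.712, 48.622, 67.544,
           314.370, 424.471, 532.179),
    a = c(8.46, 8.47, 8.48, 8.75, 8.60, 9.60, 10.59, 54.90, 67.10),
    b = c(0.0080, 0.0080, 0.0041, 0.0071, 0.0077, 0.0096,
          0.0084, 0.0084, 0.0087),
    w = c(9.283, 11.646, 14.424, 10.788, 12.726, 9.032,
          70.965, 12.481, 38.338),
    qsat = c(102.647, 109.111, 132.125, 127.869, 139.755, 135.224,
             218.707, 260.497, 256.085),
    r2 = c(0.9756, 0.9910, 0.9935, 0.9960, 0.9869, 0.9860,
           0.9787, 0.9733, 0.9873),
    rmse = c(4.7368, 3.2981, 2.6754, 3.5125, 10.3826, 6.8785,
             12.8099, 15.1116, 9.7747),
    stringsAsFactors = FALSE)
}

#' Reference thermodynamic table for Cu2+ on olive-waste adsorbents
#'
#' Published equilibrium adsorption constants and derived thermodynamic
#' parameters per adsorbent and temperature.
#'
#' @return A data.frame with columns `adsorbent`, `temperature` (K), `kads`,
#'   `dg` (kJ/mol), `dh` (kJ/mol), `ds` (kJ/(mol K)).
#' @export
ref_thermo <- function() {
  data.frame(
    adsorbent = rep(c("OWP", "OWPSA", "alginate"), each = 3),
    temperature = rep(c(293, 303, 313), 3),
    kads = c(1.4981, 1.5442, 1.5887, 1.6829, 2.0825, 2.5422,
             1.2283, 1.4131, 1.6111),
    dg = c(-0.985, -1.095, -1.205, -1.268, -1.848, -2.428,
           -0.501, -0.871, -1.241),
    dh = rep(c(2.2384, 15.726, 10.34), each = 3),
    ds = rep(c(0.011, 0.058, 0.037), each = 3),
    stringsAsFactors = FALSE)
}

#' Reference frontier-orbital energies and descriptors
#'
#' Published HOMO/LUMO energies (eV) of the Cu2+ ion and of the four
#' biopolymer building blocks of the olive-waste adsorbents, with the
#' tabulated global reactivity descriptors derived from them.
#'
#' @return A data.frame with columns `species`, `e_homo`, `e_lumo`, `gap`,
#'   `mu`, `chi`, `eta`, `omega`, `dn_max` (all eV except the dimensionless
#'   `dn_max`).
#' @export
ref_orbitals <- function() {
  data.frame(
    species = c("Cu2+", "alginate", "cellulose", "hemicellulose", "lignin"),
    e_homo = c(-17.855, -4.928, -5.776, -4.626, -5.211),
    e_lumo = c(-9.767, -0.525, 0.260, -0.950, -3.110),
    gap = c(8.088, 4.403, 6.036, 3.677, 2.101),
    mu = c(-13.811, -2.727, -2.758, -2.788, -4.160),
    chi = c(13.811, 2.727, 2.758, 2.788, 4.160),
    eta = c(4.044, 2.201, 3.018, 1.838, 1.050),
    omega = c(23.582, 1.689, 1.260, 2.114, 8.239),
    dn_max = c(3.415, 1.239, 0.914, 1.517, 3.960),
    stringsAsFactors = FALSE)
}
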