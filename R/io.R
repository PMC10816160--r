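# Delimited-text readers/writers with schema validation, and the end-to-end
# study pipeline. Files are comma- or tab-delimited with mandatory headers
# and a decimal point (no locale commas).

.schemas <- list(
  isotherm = c("Ce_mg_L", "qe_mg_g"),
  kinetics = c("t_min", "qt_mg_g"),
  thermo = c("T_K", "K_ads"),
  titration = c("pHi", "delta_pH"),
  orbitals = c("species", "E_HOMO_eV", "E_LUMO_eV"),
  sigma = c("sigma_eA2", "p_sigma"),
  bcp = c("bcp_id", "rho", "lap_rho", "G", "V"))

#' Read a validated delimited table
#'
#' Reads a comma- or tab-delimited text file (delimiter sniffed from the
#' header line) and validates it against one of the package's schemas:
#' `"isotherm"` (`Ce_mg_L,qe_mg_g`), `"kinetics"` (`t_min,qt_mg_g`),
#' `"thermo"` (`T_K,K_ads`), `"titration"` (`pHi,delta_pH`), `"orbitals"`
#' (`species,E_HOMO_eV,E_LUMO_eV`), `"sigma"` (`sigma_eA2,p_sigma`) or
#' `"bcp"` (`bcp_id,rho,lap_rho,G,V`). Malformed numeric cells and
#' invariant violations are rejected with their row number.
#'
#' @param path file path.
#' @param schema one of the schema names above.
#' @return A data.frame with the schema's columns; numeric columns parsed.
#' @export
read_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  if (!length(header) || !nzchar(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", strip.white = TRUE)
  want <- .schemas[[schema]]
  if (!identical(names(df), want))
    stop(sprintf("header of %s does not match the '%s' schema: expected %s, got %s",
                 path, schema, paste(want, collapse = ","),
                 paste(names(df), collapse = ",")))
  if (nrow(df) == 0) stop("no data rows in ", path)
  num_cols <- setdiff(want, c("species", "bcp_id"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) || anyNA(v))
      stop(sprintf("non-numeric value in column %s of %s at data row %d",
                   col, path, if (length(bad)) bad[1] else which(is.na(v))[1]))
    df[[col]] <- v
  }
  check_nonneg <- function(col) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative %s at data row %d of %s", col, bad[1], path))
  }
  switch(schema,
         isotherm = { check_nonneg("Ce_mg_L"); check_nonneg("qe_mg_g") },
         kinetics = { check_nonneg("t_min"); check_nonneg("qt_mg_g") },
         thermo = {
           bad <- which(df$K_ads <= 0 | df$T_K <= 0)
           if (length(bad))
             stop(sprintf("non-positive T_K or K_ads at data row %d of %s",
                          bad[1], path))
         },
         NULL)
  df
}

#' Write a delimited table
#'
#' Writes a data.frame as comma-separated text with a header, the format
#' [read_table()] reads back. Typed dataset objects ([isotherm_data()],
#' [kinetic_trace()]) are mapped onto their schema column names.
#'
#' @param x a data.frame, `isotherm_data` or `kinetic_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "isotherm_data"))
    x <- data.frame(Ce_mg_L = x$ce, qe_mg_g = x$qe)
  else if (inherits(x, "kinetic_trace"))
    x <- data.frame(t_min = x$t, qt_mg_g = x$qt)
  utils::write.table(x, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an isotherm file into a typed dataset
#'
#' @param path file with columns `Ce_mg_L,qe_mg_g`.
#' @param temperature absolute temperature, K.
#' @param adsorbent adsorbent label.
#' @return An [isotherm_data()] object.
#' @export
read_isotherm <- function(path, temperature, adsorbent = "adsorbent") {
  df <- read_table(path, "isotherm")
  isotherm_data(df$Ce_mg_L, df$qe_mg_g, temperature, adsorbent)
}

#' Read a kinetic trace file
#'
#' @param path file with columns `t_min,qt_mg_g`.
#' @return A [kinetic_trace()] object.
#' @export
read_kinetics <- function(path) {
  df <- read_table(path, "kinetics")
  kinetic_trace(df$t_min, df$qt_mg_g)
}

#' Run the full biosorption analysis pipeline
#'
#' Orchestrates the analysis chain over a study configuration: per-dataset
#' SLMRG isotherm fits (with saturation capacity), kinetic fits (PSO/PFO
#' linear and nonlinear plus a piecewise diffusion fit), van't Hoff
#' thermodynamics per adsorbent with sorption-regime classification, and
#' reactivity-descriptor tables when orbital energies are supplied. Failures
#' are isolated per dataset: the run continues and the error is recorded in
#' the report.
#'
#' @param config a list or path to a YAML file with (all optional except at
#'   least one input):
#'   \describe{
#'     \item{isotherms}{list of entries `path`, `adsorbent`, `temperature_K`}
#'     \item{kinetics}{list of entries `path`, `adsorbent`}
#'     \item{thermo}{list of entries `path` (schema `T_K,K_ads`), `adsorbent`}
#'     \item{orbitals}{path to a `species,E_HOMO_eV,E_LUMO_eV` file}
#'     \item{seed}{integer, default 1}
#'     \item{n_starts}{SLMRG starts, default 32}
#'     \item{chemisorption_threshold_kJ_mol}{default 40}
#'     \item{output_dir}{where `report.json` and `summary.txt` are written;
#'       omit to skip writing}
#'   }
#' @return Invisibly, the report list (also written as JSON + text summary
#'   when `output_dir` is set).
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_starts <- if (is.null(config$n_starts)) 32L else as.integer(config$n_starts)
  threshold <- if (is.null(config$chemisorption_threshold_kJ_mol)) 40
               else config$chemisorption_threshold_kJ_mol
  if (is.null(config$isotherms) && is.null(config$kinetics) &&
      is.null(config$thermo) && is.null(config$orbitals))
    stop("the study config lists no inputs")

  report <- list(seed = seed, errors = list())
  note_error <- function(stage, id, e) {
    report$errors[[length(report$errors) + 1]] <<-
      list(stage = stage, id = id, message = conditionMessage(e))
    warning(sprintf("[%s] %s failed: %s", stage, id, conditionMessage(e)),
            call. = FALSE)
  }

  if (!is.null(config$isotherms)) {
    report$isotherms <- list()
    for (i in seq_along(config$isotherms)) {
      entry <- config$isotherms[[i]]
      id <- sprintf("%s@%gK", entry$adsorbent, entry$temperature_K)
      tryCatch({
        d <- read_isotherm(entry$path, entry$temperature_K, entry$adsorbent)
        fit <- fit_slmrg(d, n_starts = n_starts, seed = seed + i)
        report$isotherms[[id]] <- list(
          adsorbent = entry$adsorbent,
          temperature_K = entry$temperature_K,
          params = as.list(unclass(fit$params)),
          qsat_mg_g = saturation_capacity(fit$params),
          r2 = fit$r2, rmse = fit$rmse, n_obs = fit$n_obs,
          residuals = as.numeric(residuals(fit)))
      }, error = function(e) note_error("isotherm", id, e))
    }
  }

  if (!is.null(config$kinetics)) {
    report$kinetics <- list()
    for (entry in config$kinetics) {
      id <- entry$adsorbent
      tryCatch({
        tr <- read_kinetics(entry$path)
        pso <- fit_kinetics("pso", tr)
        pfo <- fit_kinetics("pfo", tr)
        ipd <- fit_ipd_segments(tr, n_segments = min(3, (nrow(tr) - 1) %/% 2))
        report$kinetics[[id]] <- list(
          pso = list(coefficients = as.list(coef(pso)), r2 = pso$r2,
                     rmse = pso$rmse),
          pfo = list(coefficients = as.list(coef(pfo)), r2 = pfo$r2,
                     rmse = pfo$rmse),
          ipd = list(segments = ipd$segments,
                     breakpoints_min = ipd$breakpoints,
                     through_origin = ipd$through_origin))
      }, error = function(e) note_error("kinetics", id, e))
    }
  }

  if (!is.null(config$thermo)) {
    report$thermo <- list()
    for (entry in config$thermo) {
      id <- entry$adsorbent
      tryCatch({
        df <- read_table(entry$path, "thermo")
        if (nrow(df) < 2) {
          warning(sprintf("[thermo] %s: single temperature, van't Hoff skipped", id),
                  call. = FALSE)
          next
        }
        vh <- vant_hoff(df$T_K, df$K_ads, adsorbent = id,
                        threshold = threshold)
        report$thermo[[id]] <- list(
          dh_kJ_mol = vh$dh, ds_kJ_mol_K = vh$ds,
          dg_kJ_mol = as.numeric(vh$dg),
          temperatures_K = df$T_K, r2 = vh$r2, regime = vh$regime)
      }, error = function(e) note_error("thermo", id, e))
    }
  }

  if (!is.null(config$orbitals)) {
    tryCatch({
      df <- read_table(config$orbitals, "orbitals")
      report$descriptors <- global_descriptors(df$E_HOMO_eV, df$E_LUMO_eV,
                                               df$species)
    }, error = function(e) note_error("descriptors", config$orbitals, e))
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    writeLines(format_study_summary(report),
               file.path(config$output_dir, "summary.txt"))
  }
  invisible(report)
}

format_study_summary <- function(report) {
  out <- c("Biosorption study summary", "=========================", "")
  if (!is.null(report$isotherms)) {
    out <- c(out, "SLMRG isotherm fits:")
    for (id in names(report$isotherms)) {
      x <- report$isotherms[[id]]
      out <- c(out, sprintf(
        "  %-18s n=%.4g Nm=%.4g a=%.4g b=%.4g w=%.4g | Qsat=%.2f mg/g R2=%.4f RMSE=%.3f",
        id, x$params$n, x$params$nm, x$params$a, x$params$b, x$params$w,
        x$qsat_mg_g, x$r2, x$rmse))
    }
    out <- c(out, "")
  }
  if (!is.null(report$kinetics)) {
    out <- c(out, "Kinetic fits:")
    for (id in names(report$kinetics)) {
      x <- report$kinetics[[id]]
      out <- c(out, sprintf(
        "  %-10s PSO qe=%.3f k2=%.3g (R2=%.4f) | PFO qe=%.3f k1=%.3g (R2=%.4f)",
        id, x$pso$coefficients$qe, x$pso$coefficients$k2, x$pso$r2,
        x$pfo$coefficients$qe, x$pfo$coefficients$k1, x$pfo$r2))
    }
    out <- c(out, "")
  }
  if (!is.null(report$thermo)) {
    out <- c(out, "Thermodynamics (van't Hoff):")
    for (id in names(report$thermo)) {
      x <- report$thermo[[id]]
      out <- c(out, sprintf(
        "  %-10s dH=%.4f kJ/mol dS=%.4f kJ/(mol K) dG=[%s] kJ/mol -> %s",
        id, x$dh_kJ_mol, x$ds_kJ_mol_K,
        paste(sprintf("%.3f", x$dg_kJ_mol), collapse = ", "), x$regime))
    }
    out <- c(out, "")
  }
  if (!is.null(report$descriptors)) {
    out <- c(out, "Reactivity descriptors:",
             utils::capture.output(print(report$descriptors, row.names = FALSE)),
             "")
  }
  if (length(report$errors)) {
    out <- c(out, "Errors:")
    for (e in report$errors)
      out <- c(out, sprintf("  [%s] %s: %s", e$stage, e$id, e$message))
  }
  out
}
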