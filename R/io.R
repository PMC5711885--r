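# File-level pipeline entry points. CSV dialect: comma-separated, header
# row mandatory, '.' decimal; percentages as 0-100, probabilities as 0-1.
# Machine-readable outputs are JSON/CSV; messages go to stderr via
# warning()/message().

provenance <- function(seed = NULL) {
  list(package = "scramblefit",
       version = as.character(utils::packageVersion("scramblefit")),
       seed = seed)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e),
                                          call. = FALSE))
  if (!nrow(df)) stop("parse error in ", path, ": no data rows",
                      call. = FALSE)
  has_any <- vapply(required, function(cols) all(cols %in% names(df)),
                    logical(1))
  if (!any(has_any))
    stop("parse error in ", path, ": need columns ",
         paste(vapply(required, paste, "", collapse = "+"),
               collapse = " or "), call. = FALSE)
  for (cols in required[has_any]) {
    for (cc in cols) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
      if (length(bad))
        stop("parse error in ", path, ", column `", cc, "`, line ",
             bad[1L] + 1L, ": not a number", call. = FALSE)
    }
  }
  df
}

#' Fit the occupancy model to an assay CSV
#'
#' Reads an end-point assay table (columns `ppr` and `f_end`, or `ppr` and
#' `p_active`), runs the transformation and fit chain
#' ([normalize_reduction()] -> [ppr_star()] -> [fit_alpha()] ->
#' [alpha_to_mass()] -> [oligomer_order()]) and, when `out_dir` is given,
#' writes a JSON report plus a CSV of the fitted curve with its confidence
#' band.
#'
#' @param path Assay CSV path.
#' @inheritParams fit_alpha
#' @param out_dir Optional output directory for `occupancy_report.json`
#'   and `occupancy_curve.csv`.
#' @return The `occupancy_fit` (invisibly when writing files).
#' @export
fit_occupancy_csv <- function(path, population = vesicle_population(),
                              monomer_mass = 41700, out_dir = NULL) {
  df <- read_csv_checked(path, list(c("ppr", "f_end"),
                                    c("ppr", "p_active")))
  fit <- fit_alpha(df, population, monomer_mass)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      alpha = fit$alpha, alpha_se = fit$alpha_se,
      molar_mass = fit$molar_mass, molar_mass_se = fit$molar_mass_se,
      oligomer_order = fit$oligomer$label, n_points = fit$n_points,
      epsilon_nm = fit$epsilon, provenance = provenance())
    jsonlite::write_json(report,
                         file.path(out_dir, "occupancy_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(predict(fit), file.path(out_dir, "occupancy_curve.csv"),
              row.names = FALSE)
    return(invisible(fit))
  }
  fit
}

#' Fit every quench trace in a directory
#'
#' Fits each `*.csv` trace (columns `time_s`, `fluorescence`) with
#' [fit_trace()] and summarises the group the way assay tables report it:
#' n, half-life mean +/- SEM, drift-magnitude mean +/- SEM. Unreadable
#' files are skipped with a warning.
#'
#' @param paths A directory or explicit vector of trace CSV paths.
#' @param out_csv Optional path for the summary CSV.
#' @return List with `fits` (per-trace `trace_fit`s), `per_trace`
#'   (data frame) and `summary` (one-row data frame).
#' @export
fit_traces_dir <- function(paths, out_csv = NULL) {
  files <- if (length(paths) == 1L && dir.exists(paths))
    list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  else paths
  if (!length(files)) stop("no trace files found", call. = FALSE)
  fits <- list()
  for (f in files) {
    ft <- tryCatch(
      fit_trace(read_csv_checked(f, list(c("time_s", "fluorescence")))),
      error = function(e) {
        warning("skipping ", f, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(ft)) fits[[f]] <- ft
  }
  if (!length(fits)) stop("no trace could be fit", call. = FALSE)
  per <- data.frame(
    file = basename(names(fits)),
    plateau = vapply(fits, function(x) x$plateau, numeric(1)),
    k = vapply(fits, function(x) x$k, numeric(1)),
    s_slope = vapply(fits, function(x) x$s_slope, numeric(1)),
    half_life = vapply(fits, function(x) x$half_life, numeric(1)),
    f_end = vapply(fits, endpoint_reduction, numeric(1)),
    row.names = NULL)
  n <- nrow(per)
  sem <- function(v) if (n > 1L) sd(v) / sqrt(n) else 0
  summary <- data.frame(
    n = n,
    half_life_mean = mean(per$half_life),
    half_life_sem = sem(per$half_life),
    s_slope_mean = mean(per$s_slope),
    s_slope_sem = sem(per$s_slope))
  if (!is.null(out_csv)) write.csv(summary, out_csv, row.names = FALSE)
  list(fits = fits, per_trace = per, summary = summary)
}

#' Count bleaching steps from spot-trace files
#'
#' Reads one CSV per movie — a frames x spots matrix of background-
#' subtracted intensities (each column one spot) — counts steps with
#' [count_spot_steps()] and summarises with [step_distribution()]. When
#' `out_json` is given, writes the distribution (fractions, SEMs, per-spot
#' counts) as JSON.
#'
#' @param paths Vector of per-movie CSV paths (or a directory of them).
#' @param k_max Largest countable step number (default 5).
#' @param out_json Optional JSON output path.
#' @return The `step_distribution`.
#' @export
count_steps_csv <- function(paths, k_max = 5L, out_json = NULL) {
  files <- if (length(paths) == 1L && dir.exists(paths))
    list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  else paths
  if (!length(files)) stop("empty input: no spot-trace files",
                           call. = FALSE)
  movies <- lapply(files, function(f)
    count_spot_steps(as.matrix(read_csv_checked(f, list(character(0))))))
  dist <- step_distribution(movies, k_max = k_max)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(fractions = as.list(dist$fractions),
           sem = as.list(dist$sem), n_movies = dist$n_movies,
           n_spots = dist$n_spots, provenance = provenance()),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  dist
}

#' Per-helix RHM report for a structure
#'
#' Runs the slab-partition RHM calculation ([rhm_profile()]) on a PDB file
#' — or applies the penalty rules to an externally computed RSA-style
#' accessibility table ([exposure_from_rsa()]) — and optionally writes the
#' per-helix and per-residue CSVs.
#'
#' @param pdb Path to a PDB file (ignored when `rsa_table` is given).
#' @param helices Named list of residue-number ranges.
#' @inheritParams rhm_profile
#' @param rsa_table Optional RSA-style table (data frame or CSV path) with
#'   per-residue `sa_mem` / `sa_prot`; bypasses the internal SASA.
#' @param out_dir Optional output directory for `rhm_helices.csv` and
#'   `rhm_residues.csv`.
#' @return As [rhm_profile()].
#' @export
rhm_report <- function(pdb = NULL, helices = list(),
                       slab = membrane_slab(), probe_radius = 1.4,
                       n_points = 960L, sigma_res = 0.0028,
                       rsa_table = NULL, out_dir = NULL) {
  if (!is.null(rsa_table)) {
    expo <- exposure_from_rsa(rsa_table, slab)
    if (!length(helices)) {
      warning("no helix ranges defined; treating all residues as one helix")
      helices <- list(all = range(expo$resno))
    }
    per <- lapply(names(helices), function(nm)
      helix_rhm_energy(expo, helices[[nm]], nm, sigma_res))
    names(per) <- names(helices)
    out <- list(
      helices = data.frame(
        helix = names(helices),
        energy_kcal_mol = vapply(per, function(h) h$energy, numeric(1)),
        n_res = vapply(per, function(h) h$n_res, integer(1))),
      exposure = expo, per_helix = per)
  } else {
    if (is.null(pdb)) stop("need a `pdb` path or an `rsa_table`",
                           call. = FALSE)
    mod <- read_structure_pdb(pdb, helices)
    out <- rhm_profile(mod, slab, probe_radius, n_points, sigma_res)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out$helices, file.path(out_dir, "rhm_helices.csv"),
              row.names = FALSE)
    write.csv(out$exposure, file.path(out_dir, "rhm_residues.csv"),
              row.names = FALSE)
  }
  out
}
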