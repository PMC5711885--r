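#' Describe a reconstituted vesicle population
#'
#' Bundles the ensemble parameters that the occupancy analysis needs: the
#' Gaussian size distribution of the large unilamellar vesicles, the fraction
#' of vesicles refractory to protein reconstitution, the phospholipid
#' cross-sectional radius used to convert the fit constant into a molar mass,
#' and the fluorescence end-point scale of the dithionite assay.
#'
#' Defaults are the values characterising the POPC/POPG vesicle preparations
#' used in scramblase reconstitution assays: mean radius 88 nm with SD 28 nm,
#' ~35% refractory vesicles, a lipid cross-sectional radius of 0.472 nm, a
#' protein-free end point of ~45% reduction and a saturating end point of
#' 82.5%.
#'
#' @param mean_radius Mean vesicle radius, nm.
#' @param sd_radius Standard deviation of the vesicle radius, nm.
#' @param refractory_fraction Fraction of vesicles that never receives
#'   protein during reconstitution, in `[0, 1)`. The measured
#'   protein/phospholipid ratio is divided by `1 - refractory_fraction` to
#'   give the effective ratio PPR* experienced by reconstitutable vesicles.
#' @param lipid_radius_epsilon Cross-sectional radius of a phospholipid, nm;
#'   links the fit constant alpha to the molar mass via
#'   `M = 16 / (alpha * epsilon^2)`.
#' @param f_o Percent fluorescence reduction for protein-free liposomes
#'   (the assay baseline; outer-leaflet reporter only).
#' @param f_max Maximum percent reduction observed at saturating protein
#'   (below 100 because of the refractory subpopulation).
#'
#' @return An object of class `vesicle_population`.
#' @examples
#' vesicle_population()
#' vesicle_population(f_o = 47)  # baseline measured for a given prep
#' @export
vesicle_population <- function(mean_radius = 88, sd_radius = 28,
                               refractory_fraction = 0.35,
                               lipid_radius_epsilon = 0.472,
                               f_o = 45, f_max = 82.5) {
  stop_if_not_scalar(mean_radius, "mean_radius", positive = TRUE)
  stop_if_not_scalar(sd_radius, "sd_radius")
  stop_if_not_scalar(refractory_fraction, "refractory_fraction")
  stop_if_not_scalar(lipid_radius_epsilon, "lipid_radius_epsilon",
                     positive = TRUE)
  stop_if_not_scalar(f_o, "f_o")
  stop_if_not_scalar(f_max, "f_max")
  if (sd_radius < 0) stop("`sd_radius` must be >= 0", call. = FALSE)
  if (refractory_fraction < 0 || refractory_fraction >= 1)
    stop("`refractory_fraction` must be in [0, 1)", call. = FALSE)
  if (!(f_o >= 0 && f_o < f_max && f_max <= 100))
    stop("need 0 <= f_o < f_max <= 100", call. = FALSE)
  structure(
    list(mean_radius = mean_radius, sd_radius = sd_radius,
         refractory_fraction = refractory_fraction,
         lipid_radius_epsilon = lipid_radius_epsilon,
         f_o = f_o, f_max = f_max),
    class = "vesicle_population")
}

#' @export
print.vesicle_population <- function(x, ...) {
  cat("Vesicle population\n")
  cat(sprintf("  radius: %.1f +/- %.1f nm (Gaussian)\n",
              x$mean_radius, x$sd_radius))
  cat(sprintf("  refractory fraction: %.2f  (PPR* = PPR/%.2f)\n",
              x$refractory_fraction, 1 - x$refractory_fraction))
  cat(sprintf("  lipid cross-section radius epsilon: %.3f nm\n",
              x$lipid_radius_epsilon))
  cat(sprintf("  end-point scale: F_o = %.1f%%, F_max = %.1f%%\n",
              x$f_o, x$f_max))
  invisible(x)
}

as_vesicle_population <- function(x) {
  if (inherits(x, "vesicle_population")) return(x)
  if (is.list(x)) return(do.call(vesicle_population, x))
  stop("expected a `vesicle_population` (or a list of its fields)",
       call. = FALSE)
}
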