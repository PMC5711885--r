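#' Convert an end-point fluorescence reduction to p(>=1 scramblase)
#'
#' Linearly rescales the end-point percent reduction `F` of a dithionite
#' trace between the protein-free baseline `F_o` and the saturating value
#' `F_max`:
#' \deqn{p(\ge 1) = (F - F_o) / (F_{max} - F_o)}
#' The result is the fraction of reconstitutable vesicles that carry at
#' least one functional scramblase. Values below the baseline (measurement
#' noise) are clamped to 0 with a warning; values above `F_max` clamp to 1.
#'
#' @param f_end End-point percent fluorescence reduction (0-100), vectorised.
#' @param population A [vesicle_population()] supplying `f_o` and `f_max`.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' pop <- vesicle_population()
#' normalize_reduction(c(45, 63.75, 82.5), pop)
#' @export
normalize_reduction <- function(f_end, population = vesicle_population()) {
  population <- as_vesicle_population(population)
  if (population$f_max <= population$f_o)
    stop("configuration error: f_max must exceed f_o", call. = FALSE)
  if (!is.numeric(f_end)) stop("`f_end` must be numeric", call. = FALSE)
  p <- (f_end - population$f_o) / (population$f_max - population$f_o)
  if (any(p < -1e-8, na.rm = TRUE))
    warning("end points below the protein-free baseline F_o clamped to p = 0")
  pmin(pmax(p, 0), 1)
}

#' Effective protein/phospholipid ratio PPR*
#'
#' Corrects the measured protein/phospholipid ratio (mg protein per mmol
#' lipid, i.e. g/mol) for the vesicle fraction refractory to reconstitution:
#' the protein partitions into only `1 - refractory_fraction` of the
#' vesicles, so those vesicles see `PPR* = PPR / (1 - refractory_fraction)`
#' (PPR/0.65 at the default 35% refractory fraction).
#'
#' @param ppr Measured protein/phospholipid ratio, g/mol; vectorised.
#' @inheritParams normalize_reduction
#' @return Effective ratio PPR*, g/mol.
#' @export
ppr_star <- function(ppr, population = vesicle_population()) {
  population <- as_vesicle_population(population)
  if (!is.numeric(ppr) || any(ppr < 0, na.rm = TRUE))
    stop("`ppr` must be numeric and >= 0", call. = FALSE)
  ppr / (1 - population$refractory_fraction)
}

#' Expected scramblase count for a vesicle of given radius
#'
#' The Poisson mean of the per-vesicle occupancy: a vesicle of radius `r`
#' (nm) carries on average `alpha * x * r^2 / 2` scramblases at effective
#' protein load `x` (PPR*, g/mol). Equivalently, with
#' `alpha = 16 / (M eps^2)` this is the number of lipids in the vesicle,
#' `8 r^2 / eps^2`, times the protein-to-lipid molar ratio `x / M`.
#'
#' @param radius Vesicle radius, nm.
#' @param alpha Fit constant, mol g^-1 nm^-2.
#' @param x Effective protein/phospholipid ratio PPR*, g/mol.
#' @return Expected scramblase count (nonnegative).
#' @export
mean_occupancy <- function(radius, alpha, x) {
  if (any(radius < 0) || any(alpha < 0) || any(x < 0))
    stop("`radius`, `alpha` and `x` must be >= 0", call. = FALSE)
  alpha * x * radius^2 / 2
}

#' Coefficients of the closed-form occupancy expression
#'
#' Averaging the Poisson zero-class over a Gaussian vesicle-radius ensemble
#' `r ~ N(rbar, sigma)` gives the closed form used by
#' [predict_p_at_least_one()]:
#' \deqn{p(\ge 1) = 1 - (1 + \alpha x \sigma^2)^{-1/2}
#'   \exp\!\left(-\frac{\alpha x\, \bar r^2/2}{1 + \alpha x \sigma^2}\right)}
#' This helper returns the two ensemble coefficients multiplying
#' `alpha * x`: `sigma^2` (inside the square root) and `rbar^2 / 2` (in the
#' exponent). With the default population (rbar = 88 nm, sigma = 28 nm)
#' these are exactly 784 and 3872 nm^2.
#'
#' @inheritParams normalize_reduction
#' @return Named numeric vector `c(sqrt_coef, exp_coef)`, nm^2.
#' @examples
#' occupancy_coefficients(vesicle_population())
#' @export
occupancy_coefficients <- function(population = vesicle_population()) {
  population <- as_vesicle_population(population)
  c(sqrt_coef = population$sd_radius^2,
    exp_coef = population$mean_radius^2 / 2)
}

#' Probability that a vesicle carries at least one scramblase
#'
#' Evaluates the closed-form Poisson occupancy curve for a Gaussian vesicle
#' ensemble (see [occupancy_coefficients()] for the derivation). The curve
#' is 0 at `x = 0`, strictly increasing in `x` and in `alpha`, concave over
#' the assay range, and tends to 1 as `x` grows.
#'
#' @param alpha Fit constant, mol g^-1 nm^-2; must be > 0.
#' @param x Effective protein/phospholipid ratio PPR*, g/mol; vectorised.
#' @inheritParams normalize_reduction
#' @return p(>=1 scramblase) in `[0, 1]`.
#' @examples
#' predict_p_at_least_one(8.17e-4, 1)   # 0.8864 with the default ensemble
#' @export
predict_p_at_least_one <- function(alpha, x,
                                   population = vesicle_population()) {
  population <- as_vesicle_population(population)
  stop_if_not_scalar(alpha, "alpha", positive = TRUE)
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE))
    stop("domain error: `x` must be numeric and >= 0", call. = FALSE)
  cf <- occupancy_coefficients(population)
  ax <- alpha * x
  1 - (1 + ax * cf[["sqrt_coef"]])^(-0.5) *
    exp(-ax * cf[["exp_coef"]] / (1 + ax * cf[["sqrt_coef"]]))
}

#' Convert the occupancy fit constant to a molar mass (and back)
#'
#' The fit constant alpha of the occupancy curve is inversely proportional
#' to the molar mass `M` of the functional scramblase:
#' `alpha = 16 / (M * epsilon^2)`, with `epsilon` the phospholipid
#' cross-sectional radius (nm). `alpha_to_mass()` and `mass_to_alpha()` are
#' exact inverses.
#'
#' @param alpha Fit constant, mol g^-1 nm^-2; > 0.
#' @param molar_mass Molar mass, g/mol; > 0.
#' @param epsilon Phospholipid cross-sectional radius, nm (default 0.472).
#' @return `alpha_to_mass()`: molar mass in g/mol. `mass_to_alpha()`: the
#'   fit constant in mol g^-1 nm^-2.
#' @examples
#' alpha_to_mass(8.17e-4)    # ~87,905 g/mol
#' alpha_to_mass(18.90e-4)   # ~38,000 g/mol
#' @export
alpha_to_mass <- function(alpha, epsilon = 0.472) {
  if (any(alpha <= 0) || any(epsilon <= 0))
    stop("domain error: `alpha` and `epsilon` must be > 0", call. = FALSE)
  16 / (alpha * epsilon^2)
}

#' @rdname alpha_to_mass
#' @export
mass_to_alpha <- function(molar_mass, epsilon = 0.472) {
  if (any(molar_mass <= 0) || any(epsilon <= 0))
    stop("domain error: `molar_mass` and `epsilon` must be > 0",
         call. = FALSE)
  16 / (molar_mass * epsilon^2)
}

#' Assign an oligomeric order from a molar mass
#'
#' Divides the fitted molar mass of the functional unit by the monomer mass
#' and rounds to the nearest integer >= 1. When the mass ratio exceeds the
#' assigned integer by more than `margin`, the order is flagged as a lower
#' bound ("at least n"): a functional unit measurably heavier than an exact
#' n-mer indicates a contribution from higher-order species.
#'
#' @param molar_mass Fitted molar mass of the functional unit, g/mol.
#' @param monomer_mass Monomer molar mass, g/mol (default 41,700, an opsin
#'   monomer).
#' @param margin Fractional excess over the assigned integer that triggers
#'   the "at least" flag (default 0.05).
#' @return An object of class `oligomer_order` with fields `order`
#'   (integer), `at_least` (logical), `ratio` and `label` (e.g. `">=2"`).
#' @examples
#' oligomer_order(38000)   # "1"  : a monomer
#' oligomer_order(87905)   # ">=2": slightly heavier than a dimer
#' @export
oligomer_order <- function(molar_mass, monomer_mass = 41700, margin = 0.05) {
  stop_if_not_scalar(molar_mass, "molar_mass", positive = TRUE)
  stop_if_not_scalar(monomer_mass, "monomer_mass", positive = TRUE)
  ratio <- molar_mass / monomer_mass
  n <- max(1L, as.integer(round(ratio)))
  at_least <- (ratio - n) > margin
  structure(
    list(order = n, at_least = at_least, ratio = ratio,
         label = paste0(if (at_least) ">=", n)),
    class = "oligomer_order")
}

#' @export
print.oligomer_order <- function(x, ...) {
  cat(sprintf("oligomer order: %s (mass ratio %.3f)\n", x$label, x$ratio))
  invisible(x)
}

#' @export
format.oligomer_order <- function(x, ...) x$label

#' Fit the occupancy curve to an assay series
#'
#' Estimates the fit constant alpha of the closed-form occupancy model (see
#' [predict_p_at_least_one()]) from end-point assay data by
#' Levenberg-Marquardt nonlinear least squares, then converts it to the
#' molar mass of the functional scramblase and an oligomeric order.
#'
#' `points` must contain either a `p_active` column (probabilities already
#' in `[0,1]`) or an `f_end` column (percent reduction, transformed via
#' [normalize_reduction()]), plus either `ppr` (transformed to PPR* via
#' [ppr_star()]) or `ppr_star` directly. Unit weights are used; the
#' standard error of alpha comes from the Jacobian at the optimum, the
#' molar-mass SE by first-order propagation (`SE_M / M = SE_alpha / alpha`)
#' and the confidence band from the t-quantile on the alpha SE.
#'
#' @param points Data frame of assay points (see Details).
#' @inheritParams normalize_reduction
#' @param monomer_mass Monomer molar mass, g/mol, for the order assignment.
#' @param conf_level Confidence level for the reported band (default 0.95).
#' @return An object of class `occupancy_fit` with fields `alpha`,
#'   `alpha_se`, `molar_mass`, `molar_mass_se`, `oligomer`, `epsilon`,
#'   `data`, `df_residual`, `conf_level` and the underlying `nls` fit.
#' @seealso [predict.occupancy_fit()] for the fitted curve with its
#'   confidence band, [simulate_assay_series()] to generate test input.
#' @export
fit_alpha <- function(points, population = vesicle_population(),
                      monomer_mass = 41700, conf_level = 0.95) {
  population <- as_vesicle_population(population)
  if (!is.data.frame(points)) stop("`points` must be a data frame",
                                   call. = FALSE)
  x <- if ("ppr_star" %in% names(points)) points$ppr_star
       else if ("ppr" %in% names(points)) ppr_star(points$ppr, population)
       else stop("`points` needs a `ppr` or `ppr_star` column",
                 call. = FALSE)
  p <- if ("p_active" %in% names(points)) points$p_active
       else if ("f_end" %in% names(points))
         normalize_reduction(points$f_end, population)
       else stop("`points` needs a `p_active` or `f_end` column",
                 call. = FALSE)
  ok <- is.finite(x) & is.finite(p)
  x <- x[ok]; p <- pmin(pmax(p[ok], 0), 1)
  if (length(x) < 3L || length(unique(x)) < 2L)
    stop("need >= 3 points spanning more than one distinct PPR*",
         call. = FALSE)
  if (all(p <= 0))
    stop("degenerate data: all p(>=1) values are zero", call. = FALSE)

  cf <- occupancy_coefficients(population)
  s2 <- cf[["sqrt_coef"]]; h2 <- cf[["exp_coef"]]
  # initial slope of the curve at x=0 is alpha*(sigma^2/2 + rbar^2/2)
  pos <- x > 0 & p > 0
  a0 <- median(p[pos] / (x[pos] * (s2 / 2 + h2)))
  a0 <- max(a0, 1e-9)
  dat <- data.frame(x = x, p = p)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ 1 - (1 + alpha * x * s2)^(-0.5) *
        exp(-alpha * x * h2 / (1 + alpha * x * s2)),
      data = dat, start = list(alpha = a0),
      lower = 1e-12, control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("occupancy fit did not converge (start alpha = ",
           signif(a0, 4), "; n = ", nrow(dat), "): ",
           conditionMessage(e), call. = FALSE))
  est <- summary(fit)$coefficients
  alpha <- est["alpha", "Estimate"]
  alpha_se <- est["alpha", "Std. Error"]
  eps <- population$lipid_radius_epsilon
  m <- alpha_to_mass(alpha, eps)
  m_se <- m * alpha_se / alpha
  structure(
    list(alpha = alpha, alpha_se = alpha_se,
         molar_mass = m, molar_mass_se = m_se,
         oligomer = oligomer_order(m, monomer_mass),
         epsilon = eps, population = population,
         data = dat, n_points = nrow(dat),
         df_residual = nrow(dat) - 1L,
         conf_level = conf_level, fit = fit),
    class = "occupancy_fit")
}

#' Predicted occupancy curve with confidence band
#'
#' Evaluates the fitted occupancy curve at new PPR* values together with a
#' confidence band obtained from the t-quantile on the alpha standard error
#' (the curve is monotone in alpha, so the band is the curve at
#' `alpha -/+ t * SE`).
#'
#' @param object An `occupancy_fit`.
#' @param newdata Optional data frame with an `x` column (PPR*, g/mol);
#'   defaults to a grid over the fitted range.
#' @param ... Unused.
#' @return Data frame with columns `x`, `p`, `lwr`, `upr`.
#' @export
predict.occupancy_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) seq(0, max(object$data$x), length.out = 101)
       else newdata$x
  tq <- qt(1 - (1 - object$conf_level) / 2, df = object$df_residual)
  a_lo <- max(object$alpha - tq * object$alpha_se, 1e-12)
  a_hi <- object$alpha + tq * object$alpha_se
  data.frame(
    x = x,
    p = predict_p_at_least_one(object$alpha, x, object$population),
    lwr = predict_p_at_least_one(a_lo, x, object$population),
    upr = predict_p_at_least_one(a_hi, x, object$population))
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Occupancy fit (Poisson vesicle-occupancy model)\n")
  cat(sprintf("  n points: %d\n", x$n_points))
  cat(sprintf("  alpha: %.4g +/- %.2g mol g^-1 nm^-2\n",
              x$alpha, x$alpha_se))
  cat(sprintf("  molar mass: %s +/- %s g/mol (epsilon = %.3f nm)\n",
              format(round(x$molar_mass), big.mark = ","),
              format(round(x$molar_mass_se), big.mark = ","), x$epsilon))
  cat(sprintf("  oligomer order: %s\n", x$oligomer$label))
  invisible(x)
}
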