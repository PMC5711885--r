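# Single-molecule photobleaching step counting.
#
# Traces are background-subtracted spot intensities at fixed frame rate.
# Segmentation is binary: recursively split at the point minimizing the
# within-segment sum of squares, accepting a split only when both sides
# satisfy the minimum dwell and the level change exceeds the step
# threshold; adjacent levels closer than the threshold are merged back.

estimate_noise_sd <- function(x) {
  # robust: successive differences are ~N(0, 2 sigma^2) away from steps
  mad(diff(x)) / sqrt(2)
}

best_split <- function(x, min_dwell) {
  n <- length(x)
  if (n < 2L * min_dwell) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- min_dwell:(n - min_dwell)
  sse_l <- cs2[k] - cs[k]^2 / k
  sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  i <- which.min(sse_l + sse_r)
  kk <- k[i]
  list(k = kk,
       dmean = abs(cs[kk] / kk - (cs[n] - cs[kk]) / (n - kk)))
}

segment_trace <- function(x, min_dwell, thresh) {
  n <- length(x)
  bounds <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]
    sp <- best_split(x[lo:hi], min_dwell)
    if (is.null(sp) || sp$dmean < thresh) next
    cut <- lo + sp$k - 1L
    bounds <- c(bounds, cut)
    stack <- c(stack, list(c(lo, cut)), list(c(cut + 1L, hi)))
  }
  bounds <- sort(bounds)
  # merge adjacent segments whose level difference is below threshold
  repeat {
    edges <- c(0L, bounds, n)
    lens <- diff(edges)
    levels <- vapply(seq_along(lens), function(i)
      mean(x[(edges[i] + 1L):edges[i + 1L]]), numeric(1))
    if (length(levels) < 2L) break
    d <- abs(diff(levels))
    if (all(d >= thresh)) break
    bounds <- bounds[-which.min(d)]
  }
  list(bounds = bounds, levels = levels, lengths = lens)
}

#' Detect photobleaching steps in a spot intensity trace
#'
#' Segments a background-subtracted single-molecule intensity trace into
#' piecewise-constant levels by binary change-point segmentation and counts
#' the downward steps. A spot is flagged *uncountable* when the trace
#' re-brightens by more than half a step, when the residual noise exceeds a
#' third of the step size, or when no bleaching step is found at all —
#' mirroring the categories used in manual classification.
#'
#' When a `unit_step` intensity is supplied (typically the field-level
#' median single-fluorophore step from [count_spot_steps()]), each drop is
#' divided by it and rounded, so two fluorophores bleaching within the
#' minimum dwell of each other are still counted as two steps.
#'
#' @param intensity Numeric intensity trace (>= 100 frames recommended).
#' @param noise_sd Noise SD; estimated robustly from successive differences
#'   when `NULL`.
#' @param min_dwell Minimum segment length in frames (default 5).
#' @param step_sd_mult Minimum step size in noise-SD units (default 3).
#' @param unit_step Optional single-fluorophore step size.
#' @return Object of class `step_detection`: `n_steps`, `uncountable`,
#'   `reason`, `changepoints` (frame indices), `levels`, `drops`,
#'   `noise_sd`.
#' @examples
#' x <- c(rep(1000, 200), rep(0, 200))
#' detect_steps(x)$n_steps  # 1
#' @export
detect_steps <- function(intensity, noise_sd = NULL, min_dwell = 5L,
                         step_sd_mult = 3, unit_step = NULL) {
  if (!is.numeric(intensity) || length(intensity) < 2L * min_dwell)
    stop("`intensity` must be numeric with >= 2 * min_dwell frames",
         call. = FALSE)
  x <- as.numeric(intensity)
  sigma <- noise_sd %||% estimate_noise_sd(x)
  rng <- diff(range(x))
  thresh <- max(step_sd_mult * sigma, 1e-9 * max(rng, 1))
  seg <- segment_trace(x, as.integer(min_dwell), thresh)
  drops <- -diff(seg$levels)

  unit <- unit_step %||%
    (if (any(drops > 0)) median(drops[drops > 0]) else NA_real_)
  uncountable <- FALSE; reason <- ""
  if (!any(drops > 0)) {
    uncountable <- TRUE; reason <- "no bleaching step"
    n_steps <- 0L
  } else {
    if (any(drops < -0.5 * unit)) {
      uncountable <- TRUE; reason <- "re-brightening"
    }
    fitted <- rep(seg$levels, seg$lengths)
    if (is.finite(unit) && sd(x - fitted) > unit / 3) {
      uncountable <- TRUE
      reason <- paste0(reason, if (nzchar(reason)) "; ", "residual noise")
    }
    # background-subtracted traces must end at background: a trace still
    # holding >= half a fluorophore's intensity never finished bleaching
    if (is.finite(unit) && seg$levels[length(seg$levels)] > 0.5 * unit) {
      uncountable <- TRUE
      reason <- paste0(reason, if (nzchar(reason)) "; ",
                       "incomplete bleaching")
    }
    # total bleached intensity over the unit step: robust to change points
    # placed slightly off when two fluorophores bleach close together
    n_steps <- max(1L, as.integer(round(sum(drops[drops > 0]) / unit)))
  }
  structure(
    list(n_steps = n_steps, uncountable = uncountable, reason = reason,
         changepoints = seg$bounds, levels = seg$levels, drops = drops,
         noise_sd = sigma, unit_step = unit),
    class = "step_detection")
}

#' @export
print.step_detection <- function(x, ...) {
  cat(sprintf("step detection: %d step(s)%s\n", x$n_steps,
              if (x$uncountable) paste0(" [uncountable: ", x$reason, "]")
              else ""))
  invisible(x)
}

#' Count bleaching steps across a field of spots
#'
#' Runs [detect_steps()] on every trace of a movie, then re-counts each
#' spot's drops against the field-level unit step (the median detected drop
#' over the whole movie), so that coincident double bleaches are resolved
#' into two steps. Traces failing the monotonicity or noise gates are
#' reported with `n_steps = NA` (uncountable).
#'
#' @param traces A numeric matrix (frames x spots) or a list of numeric
#'   traces.
#' @inheritParams detect_steps
#' @return Data frame with columns `spot`, `n_steps` (NA when
#'   uncountable), `uncountable`, `reason`; the estimated `unit_step` is
#'   attached as an attribute.
#' @export
count_spot_steps <- function(traces, noise_sd = NULL, min_dwell = 5L,
                             step_sd_mult = 3) {
  tl <- if (is.matrix(traces)) lapply(seq_len(ncol(traces)),
                                      function(j) traces[, j])
        else if (is.list(traces)) traces
        else stop("`traces` must be a matrix or a list", call. = FALSE)
  if (!length(tl)) stop("empty input: no spot traces", call. = FALSE)
  det <- lapply(tl, detect_steps, noise_sd = noise_sd,
                min_dwell = min_dwell, step_sd_mult = step_sd_mult)
  all_drops <- unlist(lapply(det, function(d) d$drops[d$drops > 0]))
  unit <- if (length(all_drops)) median(all_drops) else NA_real_
  res <- lapply(det, function(d) {
    if (d$uncountable || !is.finite(unit))
      return(list(n = NA_integer_, unc = d$uncountable, reason = d$reason))
    list(n = max(1L, as.integer(round(sum(d$drops[d$drops > 0]) / unit))),
         unc = FALSE, reason = "")
  })
  out <- data.frame(
    spot = seq_along(tl),
    n_steps = vapply(res, function(r) r$n, integer(1)),
    uncountable = vapply(res, function(r) r$unc, logical(1)),
    reason = vapply(res, function(r) r$reason, character(1)))
  attr(out, "unit_step") <- unit
  out
}

#' Summarise step counts into a per-movie averaged distribution
#'
#' Converts per-movie step counts into fractions of spots bleaching in
#' 1..`k_max` steps plus an uncountable fraction, averages the fractions
#' across movies and reports the standard error of the mean across movies.
#' Counts above `k_max` are deemed uncountable, as in manual
#' classification. Movies with no countable spot are dropped with a
#' warning.
#'
#' @param counts A list with one element per movie: either the data frame
#'   from [count_spot_steps()] or an integer vector of step counts (`NA`
#'   for uncountable spots).
#' @param k_max Largest countable step number (default 5).
#' @return Object of class `step_distribution`: `fractions` (named mean
#'   fractions over `"1"… "k_max"` and `"uncountable"`), `sem`,
#'   `per_movie` (matrix), `n_movies`, `n_spots`.
#' @export
step_distribution <- function(counts, k_max = 5L) {
  if (!is.list(counts) || is.data.frame(counts)) counts <- list(counts)
  if (!length(counts)) stop("need >= 1 movie", call. = FALSE)
  cats <- c(as.character(seq_len(k_max)), "uncountable")
  per_movie <- lapply(counts, function(m) {
    v <- if (is.data.frame(m)) m$n_steps else m
    v[!is.na(v) & (v < 1L | v > k_max)] <- NA_integer_
    if (!any(!is.na(v))) return(NULL)  # no countable spot
    fr <- c(tabulate(v[!is.na(v)], nbins = k_max), sum(is.na(v)))
    fr / length(v)
  })
  bad <- vapply(per_movie, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " movie(s) with zero countable spots dropped")
    per_movie <- per_movie[!bad]
  }
  if (!length(per_movie)) stop("no movie with countable spots", call. = FALSE)
  pm <- do.call(rbind, per_movie)
  colnames(pm) <- cats
  nm <- nrow(pm)
  sem <- if (nm > 1L) apply(pm, 2L, sd) / sqrt(nm) else rep(0, ncol(pm))
  structure(
    list(fractions = colMeans(pm), sem = setNames(sem, cats),
         per_movie = pm, n_movies = nm,
         n_spots = sum(vapply(counts[!bad], function(m)
           length(if (is.data.frame(m)) m$n_steps else m), integer(1)))),
    class = "step_distribution")
}

#' @export
print.step_distribution <- function(x, ...) {
  cat(sprintf("Step distribution over %d movie(s), %d spots\n",
              x$n_movies, x$n_spots))
  for (nm in names(x$fractions))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", nm, x$fractions[[nm]],
                x$sem[[nm]]))
  invisible(x)
}

#' Expected visible-step distribution for an n-mer
#'
#' Model for the number of bleaching steps observed at a diffraction-limited
#' spot occupied by one n-meric complex: each of the `n_mer` protomers is
#' fluorescently labeled independently with probability `label_eff`, a spot
#' is observed only if at least one label is present (the primary count is
#' binomial conditioned on >= 1), and with probability `coincidence_p` a
#' second, independently labeled complex falls in the same spot (its label
#' count is unconditioned and may be zero). Blinking and FRET are ignored.
#'
#' @param n_mer Number of protomers per complex (>= 1).
#' @param label_eff Labeling probability per protomer, in (0, 1].
#' @param coincidence_p Probability of a coincident second complex, in
#'   `[0, 1)`.
#' @return Named numeric vector of probabilities over 1..`2 * n_mer`
#'   visible steps (sums to 1).
#' @examples
#' expected_step_distribution(2, 0.8, 0)  # {1: 1/3, 2: 2/3}
#' @export
expected_step_distribution <- function(n_mer, label_eff, coincidence_p = 0) {
  stopifnot(n_mer >= 1, label_eff > 0, label_eff <= 1,
            coincidence_p >= 0, coincidence_p < 1)
  n_mer <- as.integer(n_mer)
  # primary complex: Binom(n, q) | >= 1 label
  p_lab <- dbinom(seq_len(n_mer), n_mer, label_eff) /
    (1 - dbinom(0L, n_mer, label_eff))
  # coincident complex: absent, or present with Binom(n, q) labels
  p_extra <- c(
    (1 - coincidence_p) + coincidence_p * dbinom(0L, n_mer, label_eff),
    coincidence_p * dbinom(seq_len(n_mer), n_mer, label_eff))
  out <- numeric(2L * n_mer)
  for (j in seq_len(n_mer))            # primary labels
    for (e in 0:n_mer)                 # extra labels
      out[j + e] <- out[j + e] + p_lab[j] * p_extra[e + 1L]
  setNames(out, seq_along(out))
}

#' Infer the oligomeric state from an observed step distribution
#'
#' Compares the observed fractions of 1..k-step spots (uncountable spots
#' excluded, countable fractions renormalized) with
#' [expected_step_distribution()] for candidate `n_mer` values and returns
#' the best-matching order by least squared distance. The result is flagged
#' inconclusive when the distribution is essentially flat or two candidate
#' orders fit equally well.
#'
#' @param observed A `step_distribution`, or a named numeric vector of
#'   fractions over step counts (names "1", "2", ...).
#' @inheritParams expected_step_distribution
#' @param n_max Largest candidate order (default 4).
#' @return List with `n_mer` (best order), `sse` (per-candidate squared
#'   distances), `inconclusive` flag.
#' @export
infer_oligomer <- function(observed, label_eff = 0.8, coincidence_p = 0.08,
                           n_max = 4L) {
  fr <- if (inherits(observed, "step_distribution")) {
    f <- observed$fractions
    f[setdiff(names(f), "uncountable")]
  } else observed
  if (length(fr) < 2L)
    stop("observed distribution needs >= 2 categories", call. = FALSE)
  if (sum(fr) <= 0) stop("observed distribution is empty", call. = FALSE)
  fr <- fr / sum(fr)
  ks <- as.integer(names(fr) %||% seq_along(fr))
  sse <- vapply(seq_len(n_max), function(n) {
    ex <- expected_step_distribution(n, label_eff, coincidence_p)
    len <- max(ks, length(ex))
    o <- numeric(len); o[ks] <- fr
    e <- numeric(len); e[seq_along(ex)] <- ex
    sum((o - e)^2)
  }, numeric(1))
  best <- which.min(sse)
  gap <- sort(sse)[2L] - min(sse)
  inconclusive <- gap < 1e-6 || max(fr) < 1.5 / length(fr)
  list(n_mer = best, sse = setNames(sse, seq_len(n_max)),
       inconclusive = inconclusive)
}
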