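# Synthetic-data generators with known ground truth. Every stochastic
# generator takes a mandatory seed and restores the caller's RNG state.

#' Sample a vesicle ensemble with Poisson scramblase occupancy
#'
#' Draws vesicle radii from the population's Gaussian (truncated at 0 by
#' resampling), marks a Bernoulli refractory subpopulation that receives no
#' protein, and assigns each reconstitutable vesicle a Poisson scramblase
#' count with mean `alpha * x * r^2 / 2` (see [mean_occupancy()]). The
#' fraction of non-refractory vesicles with >= 1 scramblase converges on
#' [predict_p_at_least_one()] up to the (sub-1e-3) truncation difference.
#'
#' @param n_vesicles Number of vesicles (>= 1).
#' @param alpha Fit constant, mol g^-1 nm^-2.
#' @param x Effective protein load PPR*, g/mol.
#' @inheritParams normalize_reduction
#' @param seed RNG seed (mandatory).
#' @return Data frame: `radius` (nm), `refractory` (logical), `count`.
#' @export
sample_vesicle_ensemble <- function(n_vesicles, alpha, x,
                                    population = vesicle_population(),
                                    seed) {
  population <- as_vesicle_population(population)
  stopifnot(n_vesicles >= 1)
  if (alpha < 0 || x < 0) stop("`alpha` and `x` must be >= 0",
                               call. = FALSE)
  with_local_seed(seed, {
    r <- rnorm(n_vesicles, population$mean_radius, population$sd_radius)
    while (any(bad <- r <= 0))
      r[bad] <- rnorm(sum(bad), population$mean_radius,
                      population$sd_radius)
    refractory <- rbinom(n_vesicles, 1L,
                         population$refractory_fraction) == 1L
    count <- integer(n_vesicles)
    idx <- which(!refractory)
    count[idx] <- rpois(length(idx), mean_occupancy(r[idx], alpha, x))
    data.frame(radius = r, refractory = refractory, count = count)
  })
}

#' Simulate an end-point assay series over a PPR range
#'
#' For each protein/phospholipid ratio, computes the effective load
#' `x = PPR*`, the occupancy probability `p` (by ensemble sampling or from
#' the closed form), and an end point
#' `f_end = F_o + p (F_max - F_o) + noise`. The generating molar mass sets
#' `alpha = 16 / (M eps^2)`.
#'
#' @param ppr Numeric vector of protein/phospholipid ratios, g/mol.
#' @param molar_mass Generating molar mass of the functional unit, g/mol.
#' @inheritParams normalize_reduction
#' @param n_vesicles Vesicles per point for `method = "ensemble"`.
#' @param noise_sd Gaussian noise SD. For `on = "f_end"` this is in
#'   percentage points (default 1); for `on = "p"` it is applied to the
#'   probability directly.
#' @param on Where noise is applied: the end point (default) or p itself.
#' @param method `"ensemble"` (vesicle sampling) or `"closed_form"`.
#' @param seed RNG seed (mandatory).
#' @return Data frame: `ppr`, `ppr_star`, `p_true`, `p_active`, `f_end`.
#' @export
simulate_assay_series <- function(ppr, molar_mass,
                                  population = vesicle_population(),
                                  n_vesicles = 1e5, noise_sd = 1,
                                  on = c("f_end", "p"),
                                  method = c("ensemble", "closed_form"),
                                  seed) {
  population <- as_vesicle_population(population)
  stop_if_not_scalar(molar_mass, "molar_mass", positive = TRUE)
  on <- match.arg(on); method <- match.arg(method)
  alpha <- mass_to_alpha(molar_mass, population$lipid_radius_epsilon)
  x <- ppr_star(ppr, population)
  with_local_seed(seed, {
    p_true <- vapply(x, function(xi) {
      if (method == "closed_form" || xi == 0)
        return(predict_p_at_least_one(alpha, xi, population))
      ens <- sample_vesicle_ensemble(n_vesicles, alpha, xi, population,
                                     seed = NULL)
      mean(ens$count[!ens$refractory] >= 1L)
    }, numeric(1))
    if (on == "p") {
      p_obs <- pmin(pmax(p_true + rnorm(length(x), 0, noise_sd), 0), 1)
      f_end <- population$f_o +
        p_obs * (population$f_max - population$f_o)
    } else {
      f_end <- population$f_o +
        p_true * (population$f_max - population$f_o) +
        rnorm(length(x), 0, noise_sd)
      p_obs <- normalize_reduction(
        pmax(f_end, population$f_o), population)
    }
    data.frame(ppr = ppr, ppr_star = x, p_true = p_true,
               p_active = p_obs, f_end = f_end)
  })
}

#' Simulate a dithionite fluorescence-quench trace
#'
#' Generates a trace from [trace_model()] with plateau `1 - f_end/100`,
#' the given rate and drift, and Gaussian noise — the forward model of
#' [fit_trace()].
#'
#' @param f_end Target end-point percent reduction (0-100).
#' @param k Rate constant, s^-1 (default 0.69/22.63 s^-1, a ~22.6 s
#'   half-life typical of the dithionite reaction).
#' @param s_slope Linear drift magnitude, s^-1 (default 1.4e-4).
#' @param duration Trace length, s (default 300).
#' @param sample_rate Samples per second (default 2).
#' @param noise_sd Gaussian noise SD on normalized fluorescence
#'   (default 0.005).
#' @param seed RNG seed (mandatory; `NULL` only for noiseless traces).
#' @return Data frame `time_s`, `fluorescence` (class includes
#'   `dithionite_trace`).
#' @export
simulate_dithionite_trace <- function(f_end, k = 0.69 / 22.63,
                                      s_slope = 1.4e-4, duration = 300,
                                      sample_rate = 2, noise_sd = 0.005,
                                      seed = NULL) {
  stopifnot(f_end >= 0, f_end <= 100, duration > 0, sample_rate > 0)
  plateau <- 1 - f_end / 100
  t <- seq(0, duration, by = 1 / sample_rate)
  with_local_seed(seed, {
    f <- trace_model(t, plateau, k, s_slope) +
      rnorm(length(t), 0, noise_sd)
    out <- data.frame(time_s = t, fluorescence = f)
    class(out) <- c("dithionite_trace", class(out))
    out
  })
}

#' Simulate a field of single-molecule bleaching spot traces
#'
#' Each spot holds one n-meric complex whose protomers are labeled
#' independently with probability `label_eff`, conditioned on at least one
#' label (unlabeled complexes are invisible); with probability
#' `coincidence_p` a second, independently labeled complex shares the
#' spot. Each fluorophore bleaches at an exponential time with mean
#' `1 / bleach_rate`; intensity is the number of surviving fluorophores
#' times `step_height` plus Gaussian noise with SD `step_height / snr`.
#'
#' @param n_spots Number of spots.
#' @param n_mer Protomers per complex.
#' @param label_eff Per-protomer labeling probability.
#' @param coincidence_p Probability of a coincident second complex.
#' @param bleach_rate Bleaching rate per fluorophore, s^-1. The default
#'   0.1 (mean bleach time 10 s) puts ~95% of single-fluorophore bleach
#'   events inside the first 30 s of a movie, matching fields where most
#'   spots bleach within 30 s.
#' @param frame_rate Frames per second (default 20).
#' @param n_frames Frames per trace (default 1200, i.e. a 60 s movie,
#'   more than five bleach lifetimes).
#' @param snr Step height over noise SD (default 8).
#' @param step_height Single-fluorophore intensity (default 1).
#' @param seed RNG seed (mandatory).
#' @return List: `traces` (matrix frames x spots), `truth` (data frame
#'   `n_fluor`, `n_primary`, `coincident`), and the generating parameters.
#' @export
simulate_spot_traces <- function(n_spots, n_mer = 1L, label_eff = 0.8,
                                 coincidence_p = 0.08, bleach_rate = 0.1,
                                 frame_rate = 20, n_frames = 1200L,
                                 snr = 8, step_height = 1, seed) {
  stopifnot(n_spots >= 1, n_mer >= 1, label_eff > 0, label_eff <= 1,
            coincidence_p >= 0, coincidence_p < 1)
  with_local_seed(seed, {
    # primary label count: Binom(n_mer, label_eff) conditioned on >= 1
    pk <- dbinom(seq_len(n_mer), n_mer, label_eff)
    n_primary <- sample(seq_len(n_mer), n_spots, replace = TRUE,
                        prob = pk)
    coincident <- rbinom(n_spots, 1L, coincidence_p) == 1L
    n_extra <- ifelse(coincident, rbinom(n_spots, n_mer, label_eff), 0L)
    n_fluor <- n_primary + n_extra
    times <- (seq_len(n_frames) - 1L) / frame_rate
    noise_sd <- step_height / snr
    traces <- vapply(seq_len(n_spots), function(i) {
      bt <- rexp(n_fluor[i], bleach_rate)
      surviving <- colSums(outer(bt, times, ">"))
      surviving * step_height + rnorm(n_frames, 0, noise_sd)
    }, numeric(n_frames))
    list(traces = traces,
         truth = data.frame(n_fluor = n_fluor, n_primary = n_primary,
                            coincident = coincident),
         n_mer = n_mer, label_eff = label_eff,
         coincidence_p = coincidence_p, frame_rate = frame_rate,
         snr = snr, step_height = step_height, seed = seed)
  })
}

# effective side-chain sphere radii (Angstrom) for the toy helix builder
.side_chain_radii <- c(
  GLY = NA, ALA = 1.9, SER = 1.9, CYS = 2.0, THR = 2.2, VAL = 2.4,
  PRO = 2.3, ILE = 2.6, LEU = 2.6, MET = 2.7, ASN = 2.4, ASP = 2.4,
  GLN = 2.6, GLU = 2.6, LYS = 2.8, ARG = 3.0, HIS = 2.6, PHE = 2.8,
  TYR = 2.9, TRP = 3.1)

.aa_1to3 <- c(G = "GLY", A = "ALA", S = "SER", C = "CYS", T = "THR",
              V = "VAL", P = "PRO", I = "ILE", L = "LEU", M = "MET",
              N = "ASN", D = "ASP", Q = "GLN", E = "GLU", K = "LYS",
              R = "ARG", H = "HIS", F = "PHE", Y = "TYR", W = "TRP")

#' Build an ideal toy transmembrane helix
#'
#' Deterministic test fixture: an ideal alpha-helix along z (rise 1.5
#' Angstrom per residue, 100 degrees twist) with one C-alpha atom per
#' residue on a 2.3 Angstrom axial radius and one outward-pointing
#' pseudo-side-chain sphere per residue (radius from a per-residue table;
#' Gly has none). The helix is centred at `z_center`.
#'
#' @param sequence One-letter string (e.g. `"LLLLLLLL"`) or vector of
#'   3-letter residue codes.
#' @param rise Rise per residue, Angstrom (default 1.5).
#' @param twist Twist per residue, degrees (default 100).
#' @param z_center z of the helix midpoint, Angstrom (default 0).
#' @param ca_radius Helix axial radius of the C-alpha trace (default 2.3).
#' @return A [structure_model()] whose single helix spans the sequence.
#' @examples
#' h <- toy_helix_structure("LLLLLLLLLLLLLLLL")
#' @export
toy_helix_structure <- function(sequence, rise = 1.5, twist = 100,
                                z_center = 0, ca_radius = 2.3) {
  res3 <- if (length(sequence) == 1L && !sequence[1L] %in%
              names(.side_chain_radii)) {
    codes <- strsplit(toupper(sequence), "")[[1L]]
    unknown <- setdiff(codes, names(.aa_1to3))
    if (length(unknown))
      stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    unname(.aa_1to3[codes])
  } else toupper(sequence)
  if (any(!res3 %in% names(.side_chain_radii)))
    stop("unknown residue code(s): ",
         paste(setdiff(res3, names(.side_chain_radii)), collapse = ", "),
         call. = FALSE)
  n <- length(res3)
  if (n < 5L) stop("sequence length must be >= 5", call. = FALSE)
  ang <- (seq_len(n) - 1L) * twist * pi / 180
  z <- (seq_len(n) - (n + 1) / 2) * rise + z_center
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      element = "C", resname = res3[i], resno = i, chain = "A",
      name = "CA", x = ca_radius * cos(ang[i]),
      y = ca_radius * sin(ang[i]), z = z[i], radius = 1.87)
    rb <- .side_chain_radii[[res3[i]]]
    if (!is.na(rb)) {
      rr <- ca_radius + 1.53
      rows[[length(rows) + 1L]] <- data.frame(
        element = "C", resname = res3[i], resno = i, chain = "A",
        name = "CB", x = rr * cos(ang[i]), y = rr * sin(ang[i]),
        z = z[i], radius = rb)
    }
  }
  structure_model(do.call(rbind, rows),
                  helices = list(helix = c(1L, n)))
}
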