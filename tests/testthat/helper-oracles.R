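# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Monte-Carlo occupancy: fraction of vesicles with >= 1 scramblase, radii
# Gaussian truncated at 0, Poisson counts with mean alpha*x*r^2/2.
mc_occupancy <- function(alpha, x, n = 1e6, mean_r = 88, sd_r = 28,
                         seed = 99) {
  set.seed(seed)
  r <- rnorm(n, mean_r, sd_r)
  while (any(bad <- r <= 0)) r[bad] <- rnorm(sum(bad), mean_r, sd_r)
  counts <- rpois(n, alpha * x * r^2 / 2)
  mean(counts >= 1)
}

# tolerance for closed-form vs Monte-Carlo: 3 binomial SE plus the <1e-3
# budget for the truncation difference between the two radius models
mc_tol <- function(p, n = 1e6) 3 * sqrt(p * (1 - p) / n) + 1e-3

# Monte-Carlo SASA with random (not Fibonacci) directions; returns total
# accessible area and the accessible area above a z cut, per atom summed.
mc_sasa <- function(xyz, radii, probe = 1.4, n_dirs = 20000, z_above = NULL,
                    seed = 123) {
  set.seed(seed)
  re <- radii + probe
  total <- 0; above <- 0
  for (i in seq_len(nrow(xyz))) {
    u <- matrix(rnorm(3 * n_dirs), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * re[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_dirs)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= re[j]^2
    }
    w <- 4 * pi * re[i]^2 / n_dirs
    total <- total + sum(acc) * w
    if (!is.null(z_above)) above <- above + sum(acc & p[, 3] > z_above) * w
  }
  list(total = total, above = above)
}

# exhaustive enumeration of the visible-step model for one spot:
# primary n-mer conditioned on >= 1 label, optional coincident n-mer
enum_step_dist <- function(n_mer, q, cp) {
  out <- numeric(2 * n_mer)
  p0 <- (1 - q)^n_mer
  for (j in 1:n_mer) {                      # primary labels (>= 1)
    pj <- choose(n_mer, j) * q^j * (1 - q)^(n_mer - j) / (1 - p0)
    for (e in 0:n_mer) {                    # coincident labels
      pe <- if (e == 0) (1 - cp) + cp * (1 - q)^n_mer
            else cp * choose(n_mer, e) * q^e * (1 - q)^(n_mer - e)
      out[j + e] <- out[j + e] + pj * pe
    }
  }
  out
}

# assay grid used for simulated occupancy series: 12 PPR points spanning
# 0-3 g/mol, sampled densely at low PPR where a saturating curve is
# informative
assay_ppr_grid <- c(0, 0.03, 0.05, 0.08, 0.1, 0.13, 0.17, 0.22, 0.3, 0.5, 1,
                    3)

quad_alpha <- 18.90e-4   # fit constant of the monomeric construct
wt_alpha <- 8.17e-4      # fit constant of the wild-type construct
opsin_monomer_mass <- 41700
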