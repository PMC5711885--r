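slab <- membrane_slab(-15, 15, headgroup_margin = 3)

one_atom <- function(r = 1.9, z = 0, resname = "ALA") {
  structure_model(data.frame(element = "C", resname = resname, resno = 1,
                             x = 0, y = 0, z = z, radius = r))
}

test_that("isolated and buried spheres bracket the SASA computation", {
  s <- compute_sasa(one_atom(1.9))
  expect_equal(s$area, 4 * pi * 3.3^2, tolerance = 1e-9)
  expect_equal(s$residues$area, 4 * pi * 3.3^2, tolerance = 1e-9)
  # atom caged by close neighbours on all six axes is fully occluded
  cage <- data.frame(element = "C", resname = "ALA",
                     resno = c(1, rep(2, 6)),
                     x = c(0, 2, -2, 0, 0, 0, 0),
                     y = c(0, 0, 0, 2, -2, 0, 0),
                     z = c(0, 0, 0, 0, 0, 2, -2), radius = 1.9)
  sc <- compute_sasa(structure_model(cage))
  expect_equal(sc$area[1], 0)
})

test_that("two-sphere accessible area matches the spherical-cap closed form", {
  d <- 3
  atoms <- data.frame(element = "C", resname = "ALA", resno = c(1, 2),
                      x = c(0, d), y = 0, z = 0, radius = 1.9)
  s <- compute_sasa(structure_model(atoms), n_points = 4000)
  R <- 1.9 + 1.4
  exposed <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_equal(s$area[1], exposed, tolerance = 0.02 * exposed)
  expect_equal(s$area[2], exposed, tolerance = 0.02 * exposed)
  expect_warning(
    compute_sasa(structure_model(
      data.frame(element = "C", resname = "ALA", resno = c(1, 2),
                 x = 0, y = 0, z = 0, radius = 1.9))),
    "overlapping")
})

test_that("residue classes follow the exemption rules", {
  expect_equal(classify_residue("SER", 0, slab), "exempt")
  expect_equal(classify_residue("THR", -20, slab), "exempt")
  expect_equal(classify_residue("TRP", 15, slab), "exempt")   # interfacial
  expect_equal(classify_residue("TRP", -14, slab), "exempt")  # within margin
  expect_equal(classify_residue("TRP", 0, slab), "polar")     # mid-slab
  expect_equal(classify_residue("ARG", 13, slab), "exempt")
  expect_equal(classify_residue("LYS", -16, slab), "exempt")
  expect_equal(classify_residue("ARG", 0, slab), "polar")
  expect_equal(classify_residue("LEU", 0, slab), "hydrophobic")
  expect_equal(classify_residue("GLY", 0, slab), "hydrophobic")
  expect_warning(cl <- classify_residue("XYZ", 0, slab), "unknown")
  expect_equal(cl, "polar")
})

test_that("mismatch areas follow the slab partition rule", {
  # hydrophobic residue fully inside the slab: nothing protrudes
  expo_in <- residue_exposure(one_atom(1.9, z = 0, resname = "LEU"), slab)
  expect_equal(expo_in$sa_res, 0)
  expect_equal(expo_in$sa_prot, 4 * pi * 3.3^2, tolerance = 1e-9)
  # polar residue fully outside the slab: SA_prot - SA_mem = 0
  expo_out <- residue_exposure(one_atom(1.9, z = 40, resname = "ASN"), slab)
  expect_equal(expo_out$class, "polar")
  expect_equal(expo_out$sa_res, 0)
  # hydrophobic residue far outside: everything is mismatched
  expo_far <- residue_exposure(one_atom(1.9, z = 40, resname = "LEU"), slab)
  expect_equal(expo_far$sa_res, expo_far$sa_prot)
})

test_that("partition is complete and the helix energy additive", {
  helix <- toy_helix_structure("LLLLLLLLLLAANNQQLLLL", z_center = 8)
  sasa <- compute_sasa(helix)
  expo <- residue_exposure(helix, slab, sasa)
  # inside + outside areas reconstruct the protein-only SASA exactly
  expect_equal(expo$sa_prot,
               (expo$sa_prot - expo$sa_mem) + expo$sa_mem)
  expect_equal(sum(expo$sa_prot), sum(sasa$area), tolerance = 1e-9)
  h <- helix_rhm_energy(expo, c(1, 20), "TM", sigma_res = 0.0028)
  expect_equal(h$energy, sum(h$residues$energy))
  expect_equal(h$energy, 0.0028 * sum(expo$sa_res))
  # arithmetic anchor: 100 A^2 of mismatch costs 0.28 kcal/mol
  expect_equal(helix_rhm_energy(
    data.frame(resno = 1, resname = "LEU", class = "hydrophobic",
               sa_prot = 120, sa_mem = 100, sa_res = 100),
    sigma_res = 0.0028)$energy, 0.28)
  expect_warning(h0 <- helix_rhm_energy(expo, c(900, 950)), "empty")
  expect_equal(h0$energy, 0)
})

test_that("energies are invariant to xy translation and rigid z shifts", {
  helix <- toy_helix_structure("LLLLNNLLLLQQLLLL", z_center = 10)
  e0 <- rhm_profile(helix, slab)$helices$energy_kcal_mol
  shift <- function(model, dx = 0, dy = 0, dz = 0) {
    model$atoms$x <- model$atoms$x + dx
    model$atoms$y <- model$atoms$y + dy
    model$atoms$z <- model$atoms$z + dz
    model
  }
  e_xy <- rhm_profile(shift(helix, dx = 40, dy = -7), slab)$helices$energy_kcal_mol
  expect_equal(e_xy, e0, tolerance = 1e-9)
  slab_up <- membrane_slab(-15 + 5, 15 + 5, 3)
  e_z <- rhm_profile(shift(helix, dz = 5), slab_up)$helices$energy_kcal_mol
  expect_equal(e_z, e0, tolerance = 1e-9)
})

test_that("energies converge in the sphere-point count", {
  helix <- toy_helix_structure("LLLLLLNNLLQQLLLL", z_center = 9)
  e960 <- rhm_profile(helix, slab, n_points = 960)$helices$energy_kcal_mol
  e4000 <- rhm_profile(helix, slab, n_points = 4000)$helices$energy_kcal_mol
  expect_lt(abs(e960 - e4000), 0.02 * max(e4000, 1e-6))
})

test_that("widening the slab moves each class monotonically", {
  helix <- toy_helix_structure("LLLLLNNNQQLLLLLL", z_center = 10)
  widths <- c(10, 12, 15, 18)
  res <- lapply(widths, function(w)
    residue_exposure(helix, membrane_slab(-w, w, 0)))
  hyd <- vapply(res, function(e)
    sum(e$sa_res[e$class == "hydrophobic"]), numeric(1))
  pol <- vapply(res, function(e)
    sum(e$sa_res[e$class == "polar"]), numeric(1))
  expect_true(all(diff(hyd) <= 1e-9))
  expect_true(all(diff(pol) >= -1e-9))
})

test_that("protruding poly-Leu area matches an independent point-count oracle", {
  helix <- toy_helix_structure("LLLLLLLLLL", z_center = 12)
  # residues near z ~ 12-19: slab top at 15, no margin so nothing is exempt
  s <- membrane_slab(-15, 15, headgroup_margin = 0)
  expo <- residue_exposure(helix, s, n_points = 4000)
  impl_area <- sum(expo$sa_mem)  # all-Leu: area outside the slab
  at <- helix$atoms
  orc <- mc_sasa(as.matrix(at[, c("x", "y", "z")]), at$radius,
                 z_above = 15, n_dirs = 30000)
  # helix sits fully above z = -15, so "outside" means above the top bound
  expect_equal(impl_area, orc$above, tolerance = 0.02 * orc$above)
  expect_equal(sum(expo$sa_prot), orc$total, tolerance = 0.02 * orc$total)
  e <- helix_rhm_energy(expo, NULL, sigma_res = 0.0028)
  expect_equal(e$energy, 0.0028 * impl_area)
})

test_that("replicate bootstrap reproduces the three-of-four resampling", {
  expect_equal(bootstrap_sd(c(7, 7, 7, 7), seed = 1), 0)
  expect_error(bootstrap_sd(c(1, 2, 3), seed = 1), ">= 4")
  # {0,0,0,12}: every triple mean is 0 or 4, so the SD of four draws is
  # bounded by the SD of the most dissimilar achievable draw set
  v <- c(0, 0, 0, 12)
  sds <- vapply(1:20, function(s) bootstrap_sd(v, seed = s), numeric(1))
  achievable <- vapply(0:4, function(k) sd(c(rep(0, k), rep(4, 4 - k))),
                       numeric(1))
  expect_true(all(sds >= 0 & sds <= max(achievable) + 1e-12))
  expect_true(all(vapply(sds, function(x)
    any(abs(x - achievable) < 1e-12), logical(1))))
  # {1,2,3,4}: bounded by the spread of all four possible triple means
  means <- c(mean(c(1, 2, 3)), mean(c(1, 2, 4)), mean(c(1, 3, 4)),
             mean(c(2, 3, 4)))
  sds2 <- vapply(1:20, function(s) bootstrap_sd(c(1, 2, 3, 4), seed = s),
                 numeric(1))
  # SD of four draws cannot exceed the range of the achievable triple means
  expect_true(all(sds2 >= 0 & sds2 <= max(means) - min(means) + 1e-12))
  # deterministic given the seed, and the caller's RNG stream is untouched
  expect_identical(bootstrap_sd(v, seed = 3), bootstrap_sd(v, seed = 3))
  set.seed(10); before <- rnorm(1)
  set.seed(10); invisible(bootstrap_sd(v, seed = 3)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("construct comparison reports deltas and unpaired t-test p-values", {
  a <- rbind(TM1 = c(1, 1.1, 0.9, 1), TM4 = c(3, 3.2, 2.9, 3.1))
  cmp0 <- compare_constructs(a, a)
  expect_equal(cmp0$delta, c(0, 0))
  expect_true(all(cmp0$p_value > 0.9))
  # closed-form pooled t statistic oracle
  g1 <- c(1.2, 1.4, 1.1, 1.3); g2 <- c(2.0, 2.2, 1.9, 2.1)
  sp2 <- (3 * var(g1) + 3 * var(g2)) / 6
  tstat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_oracle <- 2 * pt(-abs(tstat), df = 6)
  cmp <- compare_constructs(rbind(TM = g1), rbind(TM = g2))
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(cmp$delta, mean(g1) - mean(g2))
  # near-degenerate contrast: tiny p
  cmp2 <- compare_constructs(rbind(TM = c(1, 1, 1, 1)),
                             rbind(TM = c(2, 2, 2, 2.0001)))
  expect_equal(cmp2$delta, -1.000025, tolerance = 1e-6)
  expect_lt(cmp2$p_value, 1e-10)
  # both groups constant and equal: p = 1 by convention
  cmp3 <- compare_constructs(rbind(TM = c(1, 1, 1)), rbind(TM = c(1, 1, 1)))
  expect_equal(cmp3$p_value, 1)
})
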