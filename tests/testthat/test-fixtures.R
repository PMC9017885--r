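test_that("deterministic geometries have their defining properties", {
  tet <- make_structure("tetrahedron", spacing = 3.8)
  d <- dist(tet$coords)
  expect_equal(as.vector(d), rep(3.8, 6), tolerance = 1e-12)
  zig <- make_structure("zigzag_chain", n = 5)
  expect_identical(zig$coords, make_structure("zigzag_chain", n = 5)$coords)
  steps <- sqrt(rowSums(diff(zig$coords)^2))
  expect_equal(steps, rep(3.8, 4), tolerance = 1e-12)
  helix <- make_structure("helix", n = 20)
  rise <- diff(helix$coords[, 3])
  expect_equal(rise, rep(1.5, 19), tolerance = 1e-12)
  expect_error(make_structure("collinear_chain", n = 2), ">= 3")
})

test_that("the compact random coil is seeded, self-avoiding and connected", {
  ch1 <- make_structure("random_compact", n = 50, seed = 7)
  ch2 <- make_structure("random_compact", n = 50, seed = 7)
  expect_identical(ch1$coords, ch2$coords)
  ch3 <- make_structure("random_compact", n = 50, seed = 8)
  expect_false(identical(ch1$coords, ch3$coords))
  steps <- sqrt(rowSums(diff(ch1$coords)^2))
  expect_equal(steps, rep(3.8, 49), tolerance = 1e-9)
  expect_gt(min(dist(ch1$coords)), 0.75 * 3.8 - 1e-9)
  # compact: radius of gyration well below the extended-chain value
  rg <- sqrt(mean(rowSums(scale(ch1$coords, scale = FALSE)^2)))
  expect_lt(rg, 0.25 * 49 * 3.8)
})

test_that("generators leave the global random stream untouched", {
  set.seed(123)
  before <- .Random.seed
  make_structure("random_compact", n = 10, seed = 5)
  ch <- make_structure("random_compact", n = 10, seed = 5)
  G0 <- pseudo_inverse(build_hessian(ch))
  make_gaussian_ensemble(G0, ch, 10, seed = 3)
  make_variant_cohort(ch, functional_sites(2), 5, seed = 4,
                      A = perturbation_matrix(G0))
  expect_identical(.Random.seed, before)
})

test_that("the Gaussian ensemble reproduces its generator covariance", {
  ch <- make_structure("random_compact", n = 10, seed = 3)
  G0 <- pseudo_inverse(build_hessian(ch))
  traj <- make_gaussian_ensemble(G0, ch, 20000, seed = 5)
  X <- matrix(0, 20000, 30)
  X[, seq(1, 30, 3)] <- traj$frames[, , 1]
  X[, seq(2, 30, 3)] <- traj$frames[, , 2]
  X[, seq(3, 30, 3)] <- traj$frames[, , 3]
  S <- cov(X)
  expect_lt(norm(S - G0$entries, "F") / norm(G0$entries, "F"), 0.05)
  # mean structure is recovered too
  mu <- colMeans(X)
  expect_equal(matrix(mu, 10, 3, byrow = TRUE), ch$coords, tolerance = 0.1)
  # different seeds give different draws
  t2 <- make_gaussian_ensemble(G0, ch, 10, seed = 6)
  t3 <- make_gaussian_ensemble(G0, ch, 10, seed = 7)
  expect_false(identical(t2$frames, t3$frames))
})

test_that("a diagonal generator covariance yields uncorrelated coordinates", {
  ch <- make_structure("random_compact", n = 5, seed = 2)
  G0 <- covariance_like(diag(15) * 0.25, check = FALSE)
  traj <- make_gaussian_ensemble(G0, ch, 8000, seed = 9)
  X <- matrix(aperm(traj$frames, c(1, 3, 2)), nrow = 8000)
  S <- cov(X)
  off <- abs(S[row(S) != col(S)])
  expect_lt(max(off), 0.03)
})

test_that("variant cohorts plant the promised coupling signal", {
  ch <- make_structure("random_compact", n = 60, seed = 12)
  fun <- functional_sites(c(15, 40))
  A <- perturbation_matrix(pseudo_inverse(build_hessian(ch)))
  coh0 <- make_variant_cohort(ch, fun, 58, signal = 0, seed = 1, A = A)
  expect_equal(mean(coh0$label), 0.5, tolerance = 0.2)
  expect_lt(abs(roc_auc(coh0$pct_dci, coh0$label) - 0.5), 0.2)
  coh1 <- make_variant_cohort(ch, fun, 58, signal = 1, seed = 1,
                              steepness = 50, A = A)
  # disease labels are enriched at high-%DCI sites
  top <- coh1$pct_dci > 0.7
  expect_gt(mean(coh1$label[top]) / mean(coh1$label), 1)
  expect_gt(roc_auc(coh1$pct_dci, coh1$label), 0.85)
  expect_identical(coh1, make_variant_cohort(ch, fun, 58, signal = 1,
                                             seed = 1, steepness = 50, A = A))
  expect_error(make_variant_cohort(ch, fun, 60, A = A), "exceeds available")
})

test_that("fixtures round-trip through the PDB formats the pipeline reads", {
  ch <- make_structure("random_compact", n = 10, seed = 31)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ch, path)
  back <- read_calpha_chain(path, "A")
  expect_equal(back$residue_ids, ch$residue_ids)
  expect_equal(back$coords, ch$coords, tolerance = 1e-3)
})
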