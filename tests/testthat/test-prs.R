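fixture_A <- function(n = 5, seed = 11, ...) {
  ch <- make_structure("random_compact", n = n, seed = seed)
  perturbation_matrix(pseudo_inverse(build_hessian(ch)), ...)
}

test_that("an identity covariance gives a diagonal unit response matrix", {
  G <- covariance_like(diag(12), check = FALSE)
  A <- perturbation_matrix(G)
  expect_equal(A$entries, diag(4))
})

test_that("the response matrix is exact against the closed-form direction average", {
  A <- fixture_A(5, seed = 11)
  G <- pseudo_inverse(build_hessian(make_structure("random_compact", 5, seed = 11)))
  expect_equal(A$entries, oracle_prs_matrix(G, "meansq"), tolerance = 1e-10)
  # displacement-norm variant: the 10-direction quadrature is close to, but
  # not exactly, the analytic spherical mean (Carlson R_G)
  An <- perturbation_matrix(G, magnitude = "norm")$entries
  Arg <- oracle_prs_matrix(G, "norm")
  expect_lt(max(abs(An - Arg) / Arg), 0.03)
})

test_that("tetrahedral symmetry makes all responses permutation-invariant", {
  G <- pseudo_inverse(build_hessian(make_structure("tetrahedron")))
  A <- perturbation_matrix(G)$entries
  expect_equal(max(diag(A)) - min(diag(A)), 0, tolerance = 1e-12)
  off <- A[row(A) != col(A)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-12)
})

test_that("direction schemes are reproducible as promised", {
  G <- pseudo_inverse(build_hessian(make_structure("random_compact", 6, seed = 1)))
  expect_identical(perturbation_matrix(G)$entries,
                   perturbation_matrix(G)$entries)
  r1 <- perturbation_matrix(G, 25, "seeded_random", seed = 7)$entries
  r2 <- perturbation_matrix(G, 25, "seeded_random", seed = 7)$entries
  r3 <- perturbation_matrix(G, 25, "seeded_random", seed = 8)$entries
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
  expect_error(prs_directions(10, "seeded_random"), "seed")
  expect_error(prs_directions(12, "fixed_set"), "exactly 10")
})

test_that("DFI is the normalised row sum and always sums to one", {
  A <- structure(list(entries = diag(4), n = 4L), class = "perturbation_matrix")
  expect_equal(dfi(A)$values, rep(0.25, 4))
  At <- perturbation_matrix(pseudo_inverse(build_hessian(make_structure("tetrahedron"))))
  expect_equal(dfi(At)$values, rep(0.25, 4), tolerance = 1e-12)
  A5 <- fixture_A(5)
  expect_equal(dfi(A5)$values, rowSums(A5$entries) / sum(A5$entries))
  expect_equal(sum(dfi(A5)$values), 1, tolerance = 1e-14)
  Az <- structure(list(entries = matrix(0, 3, 3), n = 3L),
                  class = "perturbation_matrix")
  expect_error(dfi(Az), "null response")
})

test_that("percentile ranks count values at or below, sharing ties upward", {
  expect_equal(percentile_rank(c(0.1, 0.4, 0.2)), c(1 / 3, 1, 2 / 3))
  expect_equal(percentile_rank(rep(2, 5)), rep(1, 5))
  expect_equal(percentile_rank(c(0.2, 0.2, 0.5)), c(2 / 3, 2 / 3, 1))
  set.seed(3)
  v <- rnorm(40)
  r <- percentile_rank(v)
  expect_true(all(r > 0 & r <= 1))
  expect_equal(max(r), 1)
  expect_equal(r, vapply(v, function(x) mean(v <= x), numeric(1)))
})

test_that("DCI is the functional-to-global mean response ratio", {
  A5 <- fixture_A(5)
  expect_equal(dci(A5, as.character(1:5))$values, rep(1, 5), tolerance = 1e-14)
  Aid <- structure(list(entries = diag(4), n = 4L),
                   class = "perturbation_matrix")
  expect_equal(dci(Aid, "2")$values, c(0, 4, 0, 0))
  byhand <- rowMeans(A5$entries[, 3, drop = FALSE]) / rowMeans(A5$entries)
  expect_equal(dci(A5, "3")$values, byhand)
  expect_error(dci(A5, character(0)), "empty functional")
})

test_that("coupling asymmetry is exactly antisymmetric and compositional", {
  A <- fixture_A(20, seed = 13)
  set.seed(1)
  pairs <- cbind(sample(1:20), sample(1:20))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ab <- dci_asymmetry(A, i, j)
    ba <- dci_asymmetry(A, j, i)
    expect_identical(ab$raw + ba$raw, 0)
    expect_identical(ab$percent + ba$percent, 0)
  }
  expect_identical(dci_asymmetry(A, 7, 7), list(raw = 0, percent = 0))
  # equals two independent dci() calls differenced
  ab <- dci_asymmetry(A, 2, 9)
  expect_equal(ab$raw, dci(A, "9")$values[2] - dci(A, "2")$values[9])
  expect_equal(ab$percent, dci(A, "9")$ranks[2] - dci(A, "2")$ranks[9])
})

test_that("delta profiles are element-wise relative changes", {
  A <- fixture_A(6, seed = 2)
  p <- dfi(A)
  expect_equal(delta_profile(p, p)$values, rep(0, 6))
  doubled <- p; doubled$values <- p$values * 2
  expect_equal(delta_profile(doubled, p)$values, rep(1, 6))
  set.seed(5)
  m <- runif(6); w <- runif(6)
  expect_equal(delta_profile(m, w)$values, (m - w) / w)
  expect_error(delta_profile(m, c(w[-6], 0)), "division by zero at residue 6")
  expect_error(delta_profile(m, w[-1]), "length mismatch")
})

test_that("DARC classification needs both distance and coupling arms", {
  lin <- make_structure("collinear_chain", n = 10)  # residue i at 3.8*(i-1)
  fun <- functional_sites(1)
  ranks <- rep(0.5, 10)
  ranks[c(3, 5)] <- 0.7
  # site 5: 15.2 A away and rank 0.7 -> DARC
  expect_true(classify_darc(lin, 5, fun, ranks))
  # site 3: rank 0.7 but 7.6 A away -> fails the distance arm
  expect_false(classify_darc(lin, 3, fun, ranks))
  # site 9: 30.4 A away but rank 0.5 -> fails the coupling arm
  expect_false(classify_darc(lin, 9, fun, ranks))
  # functional residues are never DARC (distance 0)
  expect_false(classify_darc(lin, 1, fun, rep(1, 10)))
})

test_that("the prs() fit assembles consistent per-residue results", {
  ch <- make_structure("random_compact", n = 25, seed = 19)
  fun <- functional_sites(c(5, 18))
  fit <- prs(ch, functional = fun)
  tab <- as.data.frame(fit)
  expect_equal(sum(tab$dfi), 1, tolerance = 1e-12)
  expect_equal(tab$pct_dfi, percentile_rank(tab$dfi))
  expect_equal(tab$is_darc,
               tab$min_dist_A > 10 & tab$pct_dci > 0.6)
  expect_equal(unname(coef(fit)), fit$dfi$values)
  s <- summary(fit)
  expect_equal(s$n_darc, sum(tab$is_darc))
  # supplying the covariance directly reproduces the ENM route
  fit2 <- prs(ch, functional = fun, covariance = fit$covariance)
  expect_equal(as.data.frame(fit2)$dci, tab$dci)
})
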