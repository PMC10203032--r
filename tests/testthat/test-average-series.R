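test_that("isotropic G gives exact averages at order zero", {
  G <- diag(5) * 2
  expect_equal(avg_evolvability(G), 2)
  cc <- avg_cond_evolvability(G)
  expect_equal(cc$value, 2)
  expect_equal(cc$M_used, 0)
  expect_equal(cc$error_bound, 0)
  rr <- avg_respondability(G)
  expect_equal(rr$value, 2)
  expect_equal(rr$M_used, 0)
  ff <- avg_flexibility(G)
  expect_equal(ff$value, 1)
  expect_equal(ff$M_used, 0)
  expect_equal(avg_autonomy(G)$value, 1)
  expect_equal(avg_integration(G)$value, 0)
  expect_equal(avg_response_difference(G, G)$value, 0)
  expect_equal(avg_response_correlation(G, 0.5 * G)$value, 1,
               tolerance = 1e-7)
})

test_that("p = 2 average conditional evolvability is the geometric mean", {
  expect_equal(avg_cond_evolvability(diag(c(1, 4)))$value, 2,
               tolerance = 1e-8)
  set.seed(31)
  for (rep in 1:5) {
    G <- rand_psd(2) + 0.05 * diag(2)
    expect_equal(avg_cond_evolvability(G, tol = 1e-10)$value,
                 sqrt(prod(eigen(G)$values)), tolerance = 1e-8)
  }
})

test_that("singular G short-circuits to the exact range-space values", {
  Gs <- diag(c(1, 1, 0))
  cc <- avg_cond_evolvability(Gs)
  expect_equal(cc$value, 0)
  expect_true(cc$converged)
  expect_match(cc$diagnostics, "singular")
  expect_equal(avg_autonomy(Gs)$value, 0)
  expect_equal(avg_integration(Gs)$value, 1)
  # rbar and fbar remain well defined (no bound available)
  rr <- avg_respondability(Gs)
  expect_true(rr$converged)
  expect_true(is.na(rr$error_bound))
  expect_equal(rr$value, mc_average("r", Gs, n_iter = 4e4, seed = 1)$mean,
               tolerance = 4 * mc_average("r", Gs, n_iter = 4e4, seed = 1)$se)
})

test_that("partial sums are monotone and bounds have the documented signs", {
  G <- G_one_large(5, 0.5)
  cc <- avg_cond_evolvability(G)
  expect_true(all(diff(cc$partial_sums) >= 0))     # underestimating series
  expect_true(all(cc$bounds >= 0))
  expect_lte(abs(cc$error_bound), cc$tol)
  rr <- avg_respondability(G)
  expect_true(all(diff(rr$partial_sums)[-1] <= 0)) # overestimating after k=0
  expect_true(all(rr$bounds <= 0))
  ff <- avg_flexibility(G)
  expect_true(all(diff(ff$partial_sums) >= 0))
  expect_true(all(ff$bounds >= 0))
  dd <- avg_response_difference(G, G_quadratic(5))
  expect_true(all(diff(dd$partial_sums)[-1] <= 0))
  expect_true(all(dd$bounds <= 0))
  # invariants of the evaluation object
  expect_equal(cc$partial_sums, cumsum(cc$terms))
  expect_equal(cc$value, cc$partial_sums[cc$M_used + 1])
})

test_that("converged values do not depend on the alpha constant", {
  G <- G_quadratic(5)
  ref <- avg_cond_evolvability(G)$value
  expect_equal(avg_cond_evolvability(G, alpha_factor = 0.5)$value, ref,
               tolerance = 1e-7)
  expect_warning(up <- avg_cond_evolvability(G, alpha_factor = 1.5),
                 "bounds are void")
  expect_equal(up$value, ref, tolerance = 1e-7)
  expect_equal(up$criterion, "stabilized")
  expect_error(avg_cond_evolvability(G, alpha_factor = 2.5), "alpha_factor")
  rref <- avg_respondability(G)$value
  expect_equal(avg_respondability(G, alpha_factor = 0.7)$value, rref,
               tolerance = 1e-7)
})

test_that("series estimates agree with Monte Carlo within four standard errors", {
  set.seed(32)
  G <- rand_psd(5) + 0.05 * diag(5)
  G2 <- rand_psd(5) + 0.05 * diag(5)
  checks <- list(
    c = list(s = avg_cond_evolvability(G)$value,
             m = mc_average("c", G, n_iter = 1e5, seed = 2)),
    a = list(s = avg_autonomy(G)$value,
             m = mc_average("a", G, n_iter = 1e5, seed = 3)),
    r = list(s = avg_respondability(G)$value,
             m = mc_average("r", G, n_iter = 1e5, seed = 4)),
    f = list(s = avg_flexibility(G)$value,
             m = mc_average("f", G, n_iter = 1e5, seed = 5)),
    d = list(s = avg_response_difference(G, G2)$value,
             m = mc_average("d", G, G2, n_iter = 1e5, seed = 6)),
    rho = list(s = avg_response_correlation(G, G2)$value,
               m = mc_average("rho", G, G2, n_iter = 1e5, seed = 7)))
  for (nm in names(checks)) {
    ck <- checks[[nm]]
    expect_lt(abs(ck$s - ck$m$mean), 4 * ck$m$se, label = nm)
  }
  # bracketing: value + bound still within the Monte Carlo band
  cc <- avg_cond_evolvability(G)
  expect_gt(cc$value + cc$error_bound,
            checks$c$m$mean - 4 * checks$c$m$se)
})

test_that("two-matrix series respect symmetry and degenerate inputs", {
  G1 <- G_one_large(5, 0.1)
  G2 <- G_quadratic(5)
  expect_equal(avg_response_difference(G1, G2)$value,
               avg_response_difference(G2, G1)$value, tolerance = 1e-9)
  z <- avg_response_difference(G1, G1)
  expect_equal(z$value, 0)
  expect_equal(z$criterion, "exact")
  expect_error(avg_response_correlation(G1, matrix(0, 5, 5)), "zero matrix")
  expect_error(avg_response_difference(G1, diag(4)), "same dimension")
})

test_that("non-commuting pairs use the matrix path consistently", {
  # Givens-rotated copies have the same spectra but different eigenvectors;
  # the matrix-path series must agree with Monte Carlo
  # quadratic spectrum: distinct eigenvalues, so rotated copies genuinely
  # fail to commute (a one-large spectrum has sign-limited eigenvectors)
  pr <- eigen_profile("quadratic", 4)
  A <- make_covariance(pr, "givens_correlation", seed = 1)
  B <- make_covariance(pr, "givens_correlation", seed = 2)
  expect_gt(max(abs(A$values %*% B$values - B$values %*% A$values)), 1e-6)
  rho <- avg_response_correlation(A, B)
  mc <- mc_average("rho", A, B, n_iter = 1e5, seed = 8)
  expect_lt(abs(rho$value - mc$mean), 4 * mc$se)
  dd <- avg_response_difference(A, B)
  mcd <- mc_average("d", A, B, n_iter = 1e5, seed = 9)
  expect_lt(abs(dd$value - mcd$mean), 4 * mcd$se)
})

test_that("order caps yield structured non-convergence, not errors", {
  G1 <- G_one_large(20, 0.5)
  G2 <- G_quadratic(20)
  nc <- avg_response_correlation(G1, G2, max_order = 150)
  expect_false(nc$converged)
  expect_true(is.finite(nc$value))
  expect_match(nc$diagnostics, "order cap")
  expect_equal(nc$M_used, 150)
  nc2 <- avg_cond_evolvability(G_quadratic(20), max_order = 64)
  expect_false(nc2$converged)
  expect_match(nc2$diagnostics, "order cap")
})
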