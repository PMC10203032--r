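test_that("eigenvalue conformations follow their defining formulas", {
  l <- make_eigenvalues(eigen_profile("one_large", 5, v_rel = 0.1))
  expect_equal(l, c(2.264911, rep(0.683772, 4)), tolerance = 1e-6)
  lq <- make_eigenvalues(eigen_profile("quadratic", 5))
  expect_equal(lq, 5 * c(25, 16, 9, 4, 1) / 55, tolerance = 1e-12)
  expect_equal(make_eigenvalues(eigen_profile("one_large", 5, v_rel = 0)),
               rep(1, 5))
  ex <- eigen_profile("explicit", 3, eigenvalues = c(0.5, 2, 1))
  expect_equal(make_eigenvalues(ex), c(2, 1, 0.5))
  expect_error(eigen_profile("one_large", 5, v_rel = 1), "v_rel")
  expect_error(eigen_profile("one_large", 1, v_rel = 0.1), "p")
})

test_that("one_large spectra have mean 1 and the requested relative variance", {
  for (p in c(2, 5, 50, 200)) for (v in c(0, 0.1, 0.5, 0.9)) {
    l <- make_eigenvalues(eigen_profile("one_large", p, v_rel = v))
    expect_true(all(l > 0))
    expect_equal(mean(l), 1, tolerance = 1e-14)
    expect_equal(sum((l - 1)^2) / (p * (p - 1)), v, tolerance = 1e-12)
  }
  for (p in c(2, 5, 50, 200)) {
    l <- make_eigenvalues(eigen_profile("quadratic", p))
    expect_true(all(l > 0))
    expect_equal(mean(l), 1, tolerance = 1e-14)
  }
})

test_that("Givens construction yields seeded correlation matrices with the right spectrum", {
  pr <- eigen_profile("one_large", 6, v_rel = 0.3)
  A <- make_covariance(pr, "givens_correlation", seed = 7)
  expect_s3_class(A, "cov_matrix")
  expect_equal(diag(A$values), rep(1, 6), tolerance = 1e-10)
  expect_equal(sort(A$eigenvalues), sort(make_eigenvalues(pr)),
               tolerance = 1e-10)
  # bit-reproducible per seed; different seed gives different eigenvectors
  B <- make_covariance(pr, "givens_correlation", seed = 7)
  expect_identical(A$values, B$values)
  C <- make_covariance(pr, "givens_correlation", seed = 8)
  expect_gt(max(abs(A$values - C$values)), 1e-4)
  # mean-1 requirement
  bad <- eigen_profile("explicit", 3, eigenvalues = c(3, 2, 2))
  expect_error(make_covariance(bad, "givens_correlation", seed = 1), "mean 1")
})

test_that("matrix files round-trip and malformed tables are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  G <- diag(c(1, 2, 3))
  write_matrix(G, f)
  expect_equal(read_matrix(f)$values, G)
  # full-precision round trip of an irrational-entry matrix
  set.seed(3)
  R <- rand_psd(4)
  write_matrix(R, f)
  expect_equal(read_matrix(f)$values, R, tolerance = 1e-15)
  # header and row-name detection
  writeLines(c("a,b", "1,0.5", "0.5,2"), f)
  expect_equal(read_matrix(f)$values, matrix(c(1, .5, .5, 2), 2))
  writeLines(c(",a,b", "a,1,0.5", "b,0.5,2"), f)
  expect_equal(read_matrix(f)$values, matrix(c(1, .5, .5, 2), 2))
  # tab-delimited auto-detection
  writeLines(c("1\t0.5", "0.5\t2"), f)
  expect_equal(read_matrix(f)$values, matrix(c(1, .5, .5, 2), 2))
  # non-square
  writeLines(c("1,2,3", "4,5,6"), f)
  expect_error(read_matrix(f), "non-square")
  # non-numeric interior cell
  writeLines(c("1,0.5,0", "0.5,x,0", "0,0,2"), f)
  expect_error(read_matrix(f), "non-numeric")
})

test_that("asymmetry handling: silent below tol, warning mid-range, error above 1e-6", {
  f <- withr::local_tempfile(fileext = ".csv")
  A <- matrix(c(1, 0.5, 0.5 + 1e-12, 2), 2, byrow = TRUE)
  write_matrix_raw <- function(A) writeLines(
    apply(format(A, digits = 17), 1, paste, collapse = ","), f)
  write_matrix_raw(A)
  expect_silent(G <- read_matrix(f))
  expect_equal(G$values, (A + t(A)) / 2)
  A[1, 2] <- 0.5 + 1e-7
  write_matrix_raw(A)
  expect_warning(read_matrix(f), "symmetriz")
  A[1, 2] <- 0.6
  write_matrix_raw(A)
  expect_error(read_matrix(f), "asymmetric")
})

test_that("generalized inverse handles singular and nonsingular matrices", {
  expect_equal(generalized_inverse(diag(c(1, 4))), diag(c(1, 0.25)))
  expect_equal(generalized_inverse(diag(c(2, 0))), diag(c(0.5, 0)))
  set.seed(5)
  for (rep in 1:3) {
    A <- rand_psd(3, rank = 2)
    Ai <- generalized_inverse(A)
    expect_equal(A %*% Ai %*% A, A, tolerance = 1e-10)
    expect_equal(Ai, t(Ai))
    B <- rand_psd(4) + diag(4) * 0.1
    expect_equal(generalized_inverse(B), solve(B), tolerance = 1e-10)
  }
  expect_equal(generalized_inverse(matrix(0, 2, 2)), matrix(0, 2, 2))
})

test_that("cov_matrix validates and caches a consistent decomposition", {
  set.seed(6)
  A <- rand_psd(4, rank = 2)
  G <- as_cov_matrix(A)
  expect_equal(G$rank, 2)
  expect_true(all(diff(G$eigenvalues) <= 0))
  expect_true(all(G$eigenvalues >= 0))
  expect_equal(G$eigenvectors %*% (G$eigenvalues * t(G$eigenvectors)),
               G$values, tolerance = 1e-12)
  expect_error(as_cov_matrix(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(as_cov_matrix(diag(c(1, -1))), "nonnegative definite")
  expect_error(as_cov_matrix(matrix(1)), "p < 2")
})
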