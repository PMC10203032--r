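d1v <- evolvavg:::cpp_d1_vec
d1m <- evolvavg:::cpp_d1_mat
d2v <- evolvavg:::cpp_d2_vec_table
d2m <- evolvavg:::cpp_d2_mat_table
d2h <- evolvavg:::cpp_d2h_vec
d3lv <- evolvavg:::cpp_d3l_vec_table
d3m <- evolvavg:::cpp_d3_mat_table

test_that("single-index coefficients match the univariate series oracle", {
  set.seed(11)
  for (rep in 1:3) {
    A <- rand_sym(3)
    lam <- eigen(A, symmetric = TRUE)$values
    want <- oracle_d1(lam, 12)
    expect_equal(dval(d1v(lam, 12)), want, tolerance = 1e-10)
    expect_equal(dval(d1m(A, 12)), want, tolerance = 1e-10)
  }
  # scalar argument: generating function (1 - t)^(-1/2)
  expect_equal(dval(d1v(1, 8)), poch(0.5, 0:8) / factorial(0:8),
               tolerance = 1e-12)
  expect_equal(dval(d1v(1, 2))[3], 3 / 8)
  # first-order term is tr(A)/2
  expect_equal(dval(d1v(c(2, 4), 1)), c(1, 3))
})

test_that("two-index coefficients match the bivariate oracle and identities", {
  set.seed(12)
  la <- rexp(3); lb <- rexp(3)
  tab <- dval(d2v(la, lb, 8))
  want <- oracle_d2(la, lb, 8)
  for (i in 0:8) for (j in 0:(8 - i))
    expect_equal(tab[idx2(i, j)], want[i + 1, j + 1], tolerance = 1e-10)
  # d_{1,1}(I2, I2) = 2
  expect_equal(dval(d2v(c(1, 1), c(1, 1), 2))[idx2(1, 1)], 2)
  # setting t2 = 0: d_{i,0}(A1, A2) = d_i(A1), general matrices
  A1 <- rand_sym(4); A2 <- rand_sym(4)
  tabm <- dval(d2m(A1, A2, 6))
  d1ref <- dval(d1m(A1, 6))
  for (i in 0:6) expect_equal(tabm[idx2(i, 0)], d1ref[i + 1],
                              tolerance = 1e-10)
  # binomial collapse d_{i,j}(A, A) = C(i+j, i) d_{i+j}(A)
  tabaa <- dval(d2m(A1, A1, 10))
  d1a <- dval(d1m(A1, 10))
  for (i in 0:5) for (j in 0:(10 - i))
    expect_equal(tabaa[idx2(i, j)], choose(i + j, i) * d1a[i + j + 1],
                 tolerance = 1e-9)
})

test_that("ray identity links general two-index tables to single-index runs", {
  # d_k(u A + v B) = sum_{i+j=k} u^i v^j d_{i,j}(A, B), any symmetric A, B
  set.seed(13)
  A <- rand_sym(3); B <- rand_sym(3)
  expect_gt(max(abs(A %*% B - B %*% A)), 1e-3)  # genuinely non-commuting
  tab <- dval(d2m(A, B, 8))
  for (uv in list(c(1, 1), c(0.3, 0.7))) {
    lam <- eigen(uv[1] * A + uv[2] * B, symmetric = TRUE)$values
    dray <- dval(d1v(lam, 8))
    for (k in 0:8) {
      i <- 0:k
      expect_equal(sum(uv[1]^i * uv[2]^(k - i) * tab[idx2(i, k - i)]),
                   dray[k + 1], tolerance = 1e-9)
    }
  }
})

test_that("capped-index d_{k,1} agrees with the full two-index recursion", {
  set.seed(14)
  A <- rand_sym(3); B <- rand_sym(3)
  eA <- eigen(A, symmetric = TRUE)
  bdiag <- diag(crossprod(eA$vectors, B %*% eA$vectors))
  hy <- dval(d2h(eA$values, bdiag, 8))
  # d_{0,1}(A, B) = tr(B)/2
  expect_equal(hy[1], sum(diag(B)) / 2)
  # consistency with d2(A, B) at index (k, 1), non-commuting pair
  tab <- dval(d2m(A, B, 9))
  for (k in 0:8) expect_equal(hy[k + 1], tab[idx2(k, 1)], tolerance = 1e-10)
  # B = A: d_{k,1}(A, A) = (k+1) d_{k+1}(A)
  ha <- dval(d2h(eA$values, eA$values, 10))
  da <- dval(d1v(eA$values, 11))
  expect_equal(ha, (1:11) * da[-1], tolerance = 1e-10)
})

test_that("three-index last-one coefficients match the trivariate oracle", {
  set.seed(15)
  la <- rexp(3); lb <- rexp(3); lc <- rnorm(3)
  tab <- d3lv(la, lb, lc, 6)
  want <- oracle_d3(la, lb, lc, 7)
  for (i in 0:6) for (j in 0:(6 - i)) {
    expect_equal(dval(tab, "mant0", "ex0")[idx2(i, j)],
                 want[i + 1, j + 1, 1], tolerance = 1e-10)
    expect_equal(dval(tab, "mant1", "ex1")[idx2(i, j)],
                 want[i + 1, j + 1, 2], tolerance = 1e-10)
  }
  # d_{0,0,1} = tr(B)/2; inert second slot when A2 = 0
  expect_equal(dval(tab, "mant1", "ex1")[1], sum(lc) / 2)
  tab0 <- d3lv(la, rep(0, 3), lc, 6)
  hy <- dval(d2h(la, lc, 6))
  for (i in 0:6) {
    expect_equal(dval(tab0, "mant1", "ex1")[idx2(i, 0)], hy[i + 1],
                 tolerance = 1e-12)
    if (i >= 1) expect_equal(dval(tab0, "mant1", "ex1")[idx2(0, i)], 0)
  }
})

test_that("full three-index table matches the oracle and special cases", {
  set.seed(16)
  # diagonal instance incl. a rank-one third argument (mu mu^T, mu = (m,0,0))
  la <- rexp(3); lb <- rexp(3); m <- 1.3
  A3 <- diag(c(m^2, 0, 0))
  tab <- dval(d3m(diag(la), diag(lb), A3, 6))
  want <- oracle_d3(la, lb, c(m^2, 0, 0), 6)
  for (i in 0:6) for (j in 0:(6 - i)) for (k in 0:(6 - i - j))
    expect_equal(tab[idx3(i, j, k)], want[i + 1, j + 1, k + 1],
                 tolerance = 1e-10)
  # mu = 0: all k > 0 coefficients vanish
  tab0 <- dval(d3m(diag(la), diag(lb), matrix(0, 3, 3), 5))
  for (i in 0:4) for (j in 0:(4 - i)) for (k in 1:(5 - i - j))
    expect_equal(tab0[idx3(i, j, k)], 0)
  # scalar case: d_{0,0,k}(0, 0, m^2) = (1/2)_k m^(2k) / k!
  z1 <- matrix(0, 1, 1)
  tsc <- dval(d3m(z1, z1, matrix(m^2, 1, 1), 8))
  for (k in 0:8)
    expect_equal(tsc[idx3(0, 0, k)], poch(0.5, k) * m^(2 * k) / factorial(k),
                 tolerance = 1e-12)
})

test_that("coefficients of PSD arguments with spectra in [0,1] are nonnegative", {
  set.seed(17)
  for (rep in 1:3) {
    a <- runif(4); b <- runif(4)
    expect_true(all(dval(d1v(a, 40)) >= 0))
    expect_true(all(dval(d2v(a, b, 12)) >= 0))
    t3 <- d3lv(a, b, runif(4), 10)
    expect_true(all(dval(t3, "mant1", "ex1") >= 0))
  }
})

test_that("scaled representation reproduces an unscaled computation", {
  # growth regime: eigenvalues > 1 make d_k explode; compare against a plain
  # double-precision recursion while the latter is still finite
  lam <- c(3, 2.5, 2)
  M <- 560  # d_M ~ 1e267: unscaled still finite, rescale threshold crossed
  g <- numeric(3); d <- numeric(M + 1); d[1] <- 1
  for (k in 1:M) { g <- lam * (g + d[k]); d[k + 1] <- sum(g) / (2 * k) }
  sc <- d1v(lam, M)
  expect_equal(dval(sc), d, tolerance = 1e-12)
  expect_true(any(sc$ex != 0))  # rescaling actually engaged
  expect_true(all(is.finite(sc$mant)))
})
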