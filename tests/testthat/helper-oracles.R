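# Brute-force generating-function oracles for the polynomial coefficients:
# d indexed by (i[,j[,k]]) are the Taylor coefficients of
# prod_l (1 - t1 a_l - t2 b_l - t3 c_l)^(-1/2) (diagonal arguments), built by
# truncated multivariate series multiplication, independent of the recursions.

poch <- function(a, k) exp(lgamma(a + k) - lgamma(a))

oracle_d1 <- function(lam, M) {
  out <- c(1, rep(0, M))
  for (l in lam) {
    f <- poch(0.5, 0:M) / factorial(0:M) * l^(0:M)
    new <- numeric(M + 1)
    for (k in 0:M) new[k + 1] <- sum(out[1:(k + 1)] * rev(f[1:(k + 1)]))
    out <- new
  }
  out
}

# (M+1) x (M+1) matrix, entries with i + j <= M valid
oracle_d2 <- function(la, lb, M) {
  out <- matrix(0, M + 1, M + 1); out[1, 1] <- 1
  for (l in seq_along(la)) {
    f <- matrix(0, M + 1, M + 1)
    for (i in 0:M) for (j in 0:(M - i))
      f[i + 1, j + 1] <- poch(0.5, i + j) / (factorial(i) * factorial(j)) *
        la[l]^i * lb[l]^j
    new <- matrix(0, M + 1, M + 1)
    for (i in 0:M) for (j in 0:(M - i)) {
      s <- 0
      for (u in 0:i) for (v in 0:j)
        s <- s + out[u + 1, v + 1] * f[i - u + 1, j - v + 1]
      new[i + 1, j + 1] <- s
    }
    out <- new
  }
  out
}

# 3D array, entries with i + j + k <= M valid
oracle_d3 <- function(la, lb, lc, M) {
  out <- array(0, rep(M + 1, 3)); out[1, 1, 1] <- 1
  for (l in seq_along(la)) {
    f <- array(0, rep(M + 1, 3))
    for (i in 0:M) for (j in 0:(M - i)) for (k in 0:(M - i - j))
      f[i + 1, j + 1, k + 1] <- poch(0.5, i + j + k) /
        (factorial(i) * factorial(j) * factorial(k)) *
        la[l]^i * lb[l]^j * lc[l]^k
    new <- array(0, rep(M + 1, 3))
    for (i in 0:M) for (j in 0:(M - i)) for (k in 0:(M - i - j)) {
      s <- 0
      for (u in 0:i) for (v in 0:j) for (w in 0:k)
        s <- s + out[u + 1, v + 1, w + 1] *
          f[i - u + 1, j - v + 1, k - w + 1]
      new[i + 1, j + 1, k + 1] <- s
    }
    out <- new
  }
  out
}

# reconstruct true values from scaled (mantissa, base-2 exponent) pairs
dval <- function(co, which_m = "mant", which_e = "ex")
  co[[which_m]] * 2^co[[which_e]]

# flattened-triangle index helpers matching the C++ layouts
idx2 <- function(i, j) { s <- i + j; s * (s + 1) / 2 + i + 1 }
idx3 <- function(i, j, k) {
  s <- i + j + k
  s * (s + 1) * (s + 2) / 6 + k * (s + 1) - k * (k - 1) / 2 + i + 1
}

rand_psd <- function(p, rank = p) {
  X <- matrix(rnorm(p * rank), p, rank)
  tcrossprod(X) / rank
}

rand_sym <- function(p) {
  X <- matrix(rnorm(p * p), p, p)
  (X + t(X)) / 2
}

# diagonal test conformations used throughout
G_one_large <- function(p, v)
  make_covariance(eigen_profile("one_large", p, v_rel = v))
G_quadratic <- function(p)
  make_covariance(eigen_profile("quadratic", p))
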