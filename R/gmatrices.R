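#' Validated covariance matrix with cached eigen-decomposition
#'
#' Constructs a `cov_matrix` object from a symmetric nonnegative-definite
#' matrix. The eigen-decomposition is computed once and cached; eigenvalues
#' below `-tol * lambda_max` raise an error, small negative eigenvalues are
#' clamped to zero, and the numerical rank is the number of eigenvalues
#' exceeding `tol * lambda_max * p`.
#'
#' @param x square numeric matrix, symmetric within `tol` (relative to its
#'   largest absolute entry); a `cov_matrix` is returned unchanged.
#' @param tol relative tolerance for symmetry, definiteness and rank checks.
#'   Defaults to 100 times the machine epsilon.
#'
#' @return An object of class `cov_matrix`: a list with elements `values`
#'   (the symmetrized matrix), `p`, `eigenvalues` (nonincreasing),
#'   `eigenvectors`, `rank` and `tol`.
#' @export
as_cov_matrix <- function(x, tol = 100 * .Machine$double.eps) {
  if (inherits(x, "cov_matrix")) return(x)
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) != ncol(x))
    stop("'x' must be a square numeric matrix")
  p <- nrow(x)
  if (p < 2L) stop("matrices of dimension p < 2 are not supported")
  amax <- max(abs(x))
  if (amax == 0) {
    ev <- list(values = rep(0, p), vectors = diag(p))
  } else {
    asym <- max(abs(x - t(x)))
    if (asym > tol * amax && asym > 1e-8 * amax)
      stop("'x' is not symmetric (relative asymmetry ",
           format(asym / amax, digits = 3), ")")
    x <- (x + t(x)) / 2
    ev <- eigen(x, symmetric = TRUE)
  }
  lmax <- max(ev$values, 0)
  if (min(ev$values) < -tol * max(lmax, 1) * p)
    stop("'x' is not nonnegative definite (smallest eigenvalue ",
         format(min(ev$values), digits = 3), ")")
  lam <- pmax(ev$values, 0)
  structure(
    list(values = x, p = p, eigenvalues = lam, eigenvectors = ev$vectors,
         rank = sum(lam > tol * lmax * p), tol = tol),
    class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat("cov_matrix: ", x$p, " x ", x$p, ", rank ", x$rank, "\n", sep = "")
  cat("eigenvalues:", format(x$eigenvalues, digits = 5), "\n")
  invisible(x)
}

#' @rdname as_cov_matrix
#' @export
is_cov_matrix <- function(x) inherits(x, "cov_matrix")

# internal: eigenvalues of anything coercible
cm_eigenvalues <- function(G) as_cov_matrix(G)$eigenvalues

#' Test eigenvalue conformations
#'
#' Specifies a test eigenvalue spectrum. Two parametric conformations are
#' available, both with eigenvalue mean exactly 1:
#' * `"one_large"`: a single large eigenvalue with the remaining `p - 1`
#'   equal, parameterized by the relative eigenvalue variance
#'   `v_rel = sum((lambda - 1)^2) / (p * (p - 1))`, an integration index in
#'   `[0, 1)`. Explicitly, `lambda_1 = 1 + (p - 1) * sqrt(v_rel)` and
#'   `lambda_i = 1 - sqrt(v_rel)` for `i > 1`.
#' * `"quadratic"`: a quadratically decreasing spectrum,
#'   `lambda_i = p * (p + 1 - i)^2 / sum(j^2)`.
#'
#' `"explicit"` passes a user-supplied positive spectrum through unchanged.
#'
#' @param kind one of `"one_large"`, `"quadratic"`, `"explicit"`.
#' @param p dimension, at least 2.
#' @param v_rel relative eigenvalue variance in `[0, 1)` (`"one_large"` only).
#' @param eigenvalues explicit spectrum (`"explicit"` only).
#' @return An object of class `eigen_profile`.
#' @export
#' @examples
#' eigen_profile("one_large", p = 5, v_rel = 0.1)
eigen_profile <- function(kind = c("one_large", "quadratic", "explicit"),
                          p, v_rel = NULL, eigenvalues = NULL) {
  kind <- match.arg(kind)
  p <- as.integer(p)
  if (is.na(p) || p < 2L) stop("'p' must be an integer >= 2")
  if (kind == "one_large") {
    if (is.null(v_rel) || v_rel < 0 || v_rel >= 1)
      stop("'v_rel' must lie in [0, 1): v_rel >= 1 implies a nonpositive eigenvalue")
  }
  if (kind == "explicit") {
    if (is.null(eigenvalues) || length(eigenvalues) != p ||
        any(eigenvalues < 0))
      stop("'eigenvalues' must be a nonnegative vector of length p")
    eigenvalues <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  }
  structure(list(kind = kind, p = p, v_rel = v_rel,
                 eigenvalues = eigenvalues),
            class = "eigen_profile")
}

#' Generate the eigenvalues of a conformation
#'
#' @param profile an [eigen_profile()].
#' @return Nonincreasing positive numeric vector; mean exactly 1 for the
#'   parametric kinds.
#' @export
#' @examples
#' make_eigenvalues(eigen_profile("quadratic", p = 5))
make_eigenvalues <- function(profile) {
  stopifnot(inherits(profile, "eigen_profile"))
  p <- profile$p
  switch(profile$kind,
    one_large = {
      s <- sqrt(profile$v_rel)
      c(1 + (p - 1) * s, rep(1 - s, p - 1))
    },
    quadratic = p * (p:1)^2 / sum((1:p)^2),
    explicit = profile$eigenvalues)
}

#' Construct a covariance matrix from an eigenvalue conformation
#'
#' `evec_mode = "diagonal"` returns the diagonal matrix of the conformation
#' eigenvalues. `evec_mode = "givens_correlation"` returns a correlation
#' matrix (unit diagonal) with the same spectrum, built by a seeded random
#' orthogonal similarity followed by Givens rotations that drive the diagonal
#' to one (the Bendel-Mickey / Davies-Higham construction); this requires the
#' eigenvalue mean to be 1.
#'
#' @param profile an [eigen_profile()].
#' @param evec_mode `"diagonal"` or `"givens_correlation"`.
#' @param seed integer seed for the random orthogonal rotation
#'   (`givens_correlation` only; construction is reproducible per seed).
#' @return A [as_cov_matrix()] object.
#' @export
#' @examples
#' G <- make_covariance(eigen_profile("one_large", 5, v_rel = 0.1))
#' diag(make_covariance(eigen_profile("quadratic", 5),
#'                      "givens_correlation", seed = 1)$values)
make_covariance <- function(profile, evec_mode = c("diagonal", "givens_correlation"),
                            seed = NULL) {
  evec_mode <- match.arg(evec_mode)
  lam <- make_eigenvalues(profile)
  if (evec_mode == "diagonal") return(as_cov_matrix(diag(lam)))
  if (abs(mean(lam) - 1) > 1e-12)
    stop("givens_correlation requires eigenvalue mean 1 (unit diagonal unattainable)")
  if (is.null(seed)) stop("'seed' is required for givens_correlation")
  p <- length(lam)
  Q <- with_local_seed(seed, random_orthogonal(p))
  A <- Q %*% (lam * t(Q))
  A <- (A + t(A)) / 2
  # Givens sweep: each rotation pins one diagonal entry to exactly 1
  for (step in seq_len(p - 1)) {
    dg <- diag(A)
    if (all(abs(dg - 1) < 1e-13)) break
    i <- which.min(dg)
    j <- which.max(dg)
    if (dg[i] > 1 - 1e-13 || dg[j] < 1 + 1e-13) break
    aii <- A[i, i]; ajj <- A[j, j]; aij <- A[i, j]
    # solve (ajj-1) t^2 - 2 aij t + (aii-1) = 0 for t = s/c; smaller root
    disc <- sqrt(aij^2 - (aii - 1) * (ajj - 1))
    t1 <- (aij + disc) / (ajj - 1)
    t2 <- (aij - disc) / (ajj - 1)
    tt <- if (abs(t1) < abs(t2)) t1 else t2
    cc <- 1 / sqrt(1 + tt^2); ss <- cc * tt
    Rot <- diag(p)
    Rot[i, i] <- cc; Rot[j, j] <- cc
    Rot[i, j] <- ss; Rot[j, i] <- -ss
    A <- t(Rot) %*% A %*% Rot
    A <- (A + t(A)) / 2
    A[i, i] <- 1
  }
  diag(A) <- 1
  as_cov_matrix(A)
}

# run expr under a temporary RNG state; restores the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Haar-ish random orthogonal matrix via QR with sign correction
random_orthogonal <- function(p) {
  qrx <- qr(matrix(stats::rnorm(p * p), p, p))
  Q <- qr.Q(qrx)
  Q * rep(sign(diag(qr.R(qrx))), each = p)
}

#' Read a covariance matrix from a delimited text file
#'
#' Accepts CSV/TSV (delimiter auto-detected when not given) with an optional
#' header row and/or leading row-name column, auto-detected. The matrix must
#' be square and numeric; asymmetry above `1e-6` (relative) is an error,
#' smaller asymmetry is removed by averaging with `(A + t(A))/2` (with a
#' warning when it exceeds `warn_tol`).
#'
#' @param path file path.
#' @param delimiter field delimiter; `NULL` auto-detects tab, comma or
#'   whitespace.
#' @param warn_tol relative asymmetry above which symmetrization warns.
#' @return A [as_cov_matrix()] object.
#' @export
read_matrix <- function(path, delimiter = NULL, warn_tol = 1e-8) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[1])) "\t"
      else if (grepl(",", lines[1])) "," else ""
  }
  split1 <- function(x) {
    out <- if (nzchar(delimiter)) strsplit(x, delimiter, fixed = TRUE)[[1]]
      else strsplit(trimws(x), "[[:space:]]+")[[1]]
    trimws(out)
  }
  is_num <- function(v) !any(is.na(suppressWarnings(as.numeric(v))))
  rows <- lapply(lines, split1)
  # header row iff its last token is non-numeric; row-name column iff the
  # first token of the (remaining) rows is non-numeric
  header <- !is_num(rows[[1]][length(rows[[1]])])
  if (header) rows <- rows[-1]
  first_col <- vapply(rows, `[`, "", 1L)
  rownames_col <- !is_num(first_col)
  if (rownames_col) rows <- lapply(rows, `[`, -1L)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stop("ragged rows in matrix file: ", path)
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncols)))
  if (anyNA(vals)) stop("non-numeric cells in matrix file: ", path)
  A <- t(matrix(vals, nrow = ncols))
  if (nrow(A) != ncol(A))
    stop("non-square table (", nrow(A), " x ", ncol(A), ") in ", path)
  rel <- if (max(abs(A)) > 0) max(abs(A - t(A))) / max(abs(A)) else 0
  if (rel > 1e-6)
    stop("matrix in ", path, " is asymmetric (relative asymmetry ",
         format(rel, digits = 3), " > 1e-6)")
  if (rel > warn_tol)
    warning("symmetrizing matrix with relative asymmetry ",
            format(rel, digits = 3))
  as_cov_matrix((A + t(A)) / 2)
}

#' Write a covariance matrix to a delimited text file
#'
#' Values are written at full double precision so that a write/read
#' round-trip reproduces the matrix exactly.
#'
#' @param x matrix or `cov_matrix`.
#' @param path output file path.
#' @param delimiter field delimiter (default comma).
#' @export
write_matrix <- function(x, path, delimiter = ",") {
  if (is_cov_matrix(x)) x <- x$values
  txt <- apply(format(x, digits = 17, scientific = TRUE, trim = TRUE), 1,
               paste, collapse = delimiter)
  writeLines(txt, path)
  invisible(path)
}

#' Moore-Penrose generalized inverse via eigen-decomposition
#'
#' Inverts only the eigenvalues exceeding the rank tolerance
#' `tol * lambda_max * p`, so singular (and zero) matrices are handled;
#' satisfies `A %*% ginv(A) %*% A = A`.
#'
#' @param G matrix or `cov_matrix`.
#' @return Symmetric matrix of the same dimension.
#' @export
#' @examples
#' generalized_inverse(diag(c(2, 0)))
generalized_inverse <- function(G) {
  G <- as_cov_matrix(G)
  lam <- G$eigenvalues
  keep <- seq_len(G$rank)
  if (!length(keep)) return(matrix(0, G$p, G$p))
  V <- G$eigenvectors[, keep, drop = FALSE]
  Gi <- V %*% (1 / lam[keep] * t(V))
  (Gi + t(Gi)) / 2
}

# largest eigenvalue helper
lambda_max <- function(G) max(cm_eigenvalues(G))
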