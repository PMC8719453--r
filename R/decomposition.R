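# internal: column standardization with population-sd convention.
# Constant columns are set to zero and flagged, not dropped: voxel order is
# part of the geometry contract.
.standardize_columns <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, `-`)
  s <- sqrt(colMeans(Xc^2))
  constant <- s < tol
  s[constant] <- 1
  Z <- sweep(Xc, 2, s, `/`)
  Z[, constant] <- 0
  list(data = Z, constant = constant)
}

#' Standardize each voxel time course
#'
#' Centers each column to zero mean and scales to unit variance
#' (population-sd convention, i.e. dividing by `sqrt(mean((x - mean)^2))`).
#' Constant columns cannot be standardized; they are set to zero and
#' recorded in the `constant_mask` attribute.
#'
#' @param b A `bold_series` (or a plain T x V matrix).
#' @return A standardized `bold_series` (or matrix) with attribute
#'   `constant_mask`, a logical vector over voxels.
#' @export
standardize_series <- function(b) {
  if (inherits(b, "bold_series")) {
    if (isTRUE(b$standardized)) return(b)
    st <- .standardize_columns(b$data)
    out <- bold_series(st$data, b$geometry, b$subject_id, b$condition,
                       standardized = TRUE)
    attr(out, "constant_mask") <- st$constant
    out
  } else {
    st <- .standardize_columns(b)
    out <- st$data
    attr(out, "constant_mask") <- st$constant
    out
  }
}

#' Temporally concatenate standardized subjects
#'
#' Stacks subject matrices row-wise in input order. All subjects must share
#' one geometry and be standardized (done here if not already).
#'
#' @param series List of `bold_series`.
#' @return List with `X` (sum(T_s) x V matrix), `row_index` (subject id per
#'   row) and `blocks` (named list of row ranges per subject).
#' @export
concat_subjects <- function(series) {
  if (!length(series)) stop("`series` must contain at least one subject", call. = FALSE)
  if (!all(vapply(series, inherits, logical(1), "bold_series"))) {
    stop("`series` must be a list of bold_series", call. = FALSE)
  }
  g <- series[[1]]$geometry
  same <- vapply(series, function(b) identical(b$geometry, g), logical(1))
  if (!all(same)) stop("all subjects must share one voxel geometry", call. = FALSE)
  series <- lapply(series, standardize_series)
  mats <- lapply(series, `[[`, "data")
  X <- do.call(rbind, mats)
  Ts <- vapply(mats, nrow, integer(1))
  ids <- vapply(series, `[[`, character(1), "subject_id")
  ends <- cumsum(Ts)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  blocks <- Map(function(a, b) c(a, b), starts, ends)
  names(blocks) <- ids
  list(X = X, row_index = rep(ids, Ts), blocks = blocks)
}

.soft <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' L1-penalized sparse coding against a fixed dictionary
#'
#' Solves, for every data column `x_v`, the lasso problem
#' `min_a 0.5 * ||x_v - D a||^2 + lambda * ||a||_1`
#' by Gram-matrix coordinate descent, vectorized across voxels. Dictionary
#' columns must have unit L2 norm. With `lambda = 0` the exact least-squares
#' solution is returned.
#'
#' @param X T x V data matrix.
#' @param D T x K dictionary with unit-norm columns.
#' @param lambda Non-negative L1 weight.
#' @param tol Convergence tolerance on the KKT residual.
#' @param max_pass Maximum coordinate-descent sweeps.
#' @return K x V coefficient matrix `A`.
#' @export
sparse_code <- function(X, D, lambda, tol = 1e-8, max_pass = 5000L) {
  X <- as.matrix(X); D <- as.matrix(D)
  if (nrow(X) != nrow(D)) stop("X and D must share the time dimension", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  nrm <- sqrt(colSums(D^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("dictionary columns must have unit L2 norm", call. = FALSE)
  }
  K <- ncol(D); V <- ncol(X)
  if (lambda == 0) {
    return(qr.solve(D, X))
  }
  G <- crossprod(D)          # K x K
  C <- crossprod(D, X)       # K x V
  A <- matrix(0, K, V)
  for (pass in seq_len(max_pass)) {
    for (k in seq_len(K)) {
      r_k <- C[k, ] - G[k, , drop = FALSE] %*% A + G[k, k] * A[k, ]
      A[k, ] <- .soft(as.numeric(r_k), lambda) / G[k, k]
    }
    if (pass %% 5L == 0L || pass == max_pass) {
      if (kkt_residual(G = G, C = C, A = A, lambda = lambda) < tol) break
    }
  }
  A
}

#' Maximum KKT optimality residual of a sparse coding solution
#'
#' For the lasso objective the optimum satisfies, per coefficient,
#' `|d_k' (x - D a)| <= lambda` where `a_k = 0` and
#' `d_k' (x - D a) = lambda * sign(a_k)` where `a_k != 0`. Returns the
#' largest violation over all coefficients and columns.
#'
#' @param X,D,A Problem data and solution (`A` is K x V).
#' @param lambda L1 weight.
#' @param G,C Optional precomputed `crossprod(D)` and `crossprod(D, X)`.
#' @return Scalar residual (0 at the exact optimum).
#' @export
kkt_residual <- function(X = NULL, D = NULL, A, lambda, G = NULL, C = NULL) {
  if (is.null(G)) G <- crossprod(D)
  if (is.null(C)) C <- crossprod(D, X)
  grad <- C - G %*% A          # d_k' (x - D a), K x V
  zero <- A == 0
  r_zero <- if (any(zero)) max(pmax(abs(grad[zero]) - lambda, 0)) else 0
  r_act <- if (any(!zero)) max(abs(grad[!zero] - lambda * sign(A[!zero]))) else 0
  max(r_zero, r_act)
}

# Greedy farthest-point column selection: start from a random column, then
# repeatedly add the column least similar (absolute inner product of
# standardized columns) to those already chosen. Gives one seed per planted
# component with high probability; deterministic given the RNG state.
.init_dictionary <- function(X, K) {
  V <- ncol(X)
  nrm <- sqrt(colSums(X^2))
  ok <- nrm > 1e-12
  if (sum(ok) < K) stop("not enough non-constant columns to initialize ", K, " atoms", call. = FALSE)
  Xn <- sweep(X, 2, pmax(nrm, 1e-12), `/`)
  first <- sample(which(ok), 1)
  chosen <- first
  maxsim <- abs(crossprod(Xn[, first], Xn))[1, ]
  maxsim[!ok] <- Inf
  for (i in seq_len(K - 1)) {
    maxsim[chosen] <- Inf
    nxt <- which.min(maxsim)
    chosen <- c(chosen, nxt)
    sim <- abs(crossprod(Xn[, nxt], Xn))[1, ]
    maxsim <- pmax(maxsim, ifelse(ok, sim, Inf))
  }
  Xn[, chosen, drop = FALSE]
}

#' Learn a temporal dictionary and sparse group spatial maps
#'
#' Batch alternating minimization of
#' `0.5 * ||X - D A||_F^2 + lambda * ||A||_1` subject to unit-norm
#' dictionary atoms: sparse coding of all voxel columns (coordinate
#' descent) alternates with an exact block-coordinate dictionary update on
#' the unit sphere, so the recorded objective is non-increasing. Atoms with
#' all-zero usage are reinitialized from the worst-reconstructed data
#' column (ties broken by lowest voxel index). On return each component is
#' oriented so its spatial map row has non-negative sum (the sign of a
#' (atom, map) pair is not identified; positive maps are required for
#' one-sided z thresholding downstream).
#'
#' @param X T x V matrix (typically concatenated standardized subjects).
#' @param K Dictionary size (number of components), `K < min(T, V)`.
#' @param lambda L1 weight; default `0.1 * sqrt(nrow(X))`, which scales
#'   with the norm of a standardized column (`||x_v|| = sqrt(T)`).
#' @param n_iter Maximum alternations (default 30).
#' @param tol Relative objective-change stopping tolerance.
#' @param seed Integer RNG seed (initialization).
#' @return A `group_decomposition`: `D` (T x K, unit-norm atoms), `A`
#'   (K x V), `K`, `lambda`, `objective_trace`, `seed`, `n_iter_run`.
#' @export
learn_dictionary <- function(X, K, lambda = 0.1 * sqrt(nrow(X)), n_iter = 30L,
                             tol = 1e-5, seed = 1) {
  X <- as.matrix(X)
  n_time <- nrow(X); V <- ncol(X)
  if (K >= min(n_time, V)) stop("`K` must be smaller than min(T, V)", call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  set.seed(seed)
  D <- .init_dictionary(X, K)
  obj <- numeric(0)
  A <- NULL
  for (it in seq_len(n_iter)) {
    A <- sparse_code(X, D, lambda)
    R <- X - D %*% A
    obj[it] <- 0.5 * sum(R^2) + lambda * sum(abs(A))
    if (it > 1 && (obj[it - 1] - obj[it]) < tol * abs(obj[it - 1])) break
    # exact block update of each atom on the unit sphere; A is unchanged so
    # reinitializing a dead atom (zero usage row) leaves the objective intact
    Ct <- tcrossprod(A)      # K x K
    B <- X %*% t(A)          # T x K
    recon_err <- colSums(R^2)
    used <- logical(V)
    for (j in seq_len(K)) {
      u <- B[, j] - D %*% Ct[, j] + D[, j] * Ct[j, j]
      nu <- sqrt(sum(u^2))
      if (Ct[j, j] < 1e-12 || nu < 1e-12) {
        cand <- recon_err
        cand[used] <- -Inf
        w <- which.max(cand)   # ties -> lowest voxel index
        used[w] <- TRUE
        cn <- sqrt(sum(X[, w]^2))
        D[, j] <- if (cn > 0) X[, w] / cn else stats::rnorm(n_time) / sqrt(n_time)
      } else {
        D[, j] <- u / nu
      }
    }
  }
  # orient components: spatial map rows sum >= 0
  flip <- rowSums(A) < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    D[, flip] <- -D[, flip, drop = FALSE]
  }
  structure(
    list(D = D, A = A, K = K, lambda = lambda, objective_trace = obj,
         seed = seed, n_iter_run = length(obj)),
    class = "group_decomposition"
  )
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat(sprintf("<group_decomposition> K = %d atoms over %d time points, %d voxels\n",
              x$K, nrow(x$D), ncol(x$A)))
  cat(sprintf("  lambda = %.4g, %d iterations, final objective %.6g\n",
              x$lambda, x$n_iter_run, utils::tail(x$objective_trace, 1)))
  invisible(x)
}
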