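#' Uniform one-cycle sampling grid
#'
#' Describes the sampling of exactly one cycle of a periodic movement:
#' `N` samples indexed `n = 1..N` at phases `2*pi*n/N`. The cycle is closed,
#' i.e. sample `N + 1` is identified with sample 1; the endpoint is not
#' duplicated in the data. The optional `period` (seconds) is needed only for
#' time derivatives.
#'
#' @param N integer sample count per cycle (at least 4).
#' @param period cycle duration in seconds, or `NULL` if no derivatives are
#'   required.
#' @return an object of class `"cycle_grid"` with elements `N`, `period` and
#'   `phase` (the `N` phases in radians).
#' @export
cycle_grid <- function(N, period = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 4L)
    stop("cycle_grid: N must be an integer >= 4")
  if (!is.null(period) && (!is.numeric(period) || period <= 0))
    stop("cycle_grid: period must be a positive duration in seconds")
  structure(list(N = N, period = period, phase = 2 * pi * seq_len(N) / N),
            class = "cycle_grid")
}

#' @export
print.cycle_grid <- function(x, ...) {
  cat(sprintf("<cycle_grid> N = %d%s\n", x$N,
              if (is.null(x$period)) "" else sprintf(", period = %g s", x$period)))
  invisible(x)
}

check_order <- function(grid, K) {
  if (K < 1L) stop("Fourier order K must be >= 1")
  if (K >= grid$N / 2)
    stop(sprintf("Fourier order K = %d aliases on a grid of N = %d samples (need K < N/2)",
                 K, grid$N))
  invisible(TRUE)
}

#' Fourier basis row at one sample
#'
#' The row vector of the `K` cosine values followed by the `K` sine values at
#' phase `2*pi*n/N`: `[cos(2*pi*k*n/N), k = 1..K, sin(2*pi*k*n/N), k = 1..K]`.
#' This cosine-block-then-sine-block ordering is used for every coefficient
#' vector in the package.
#'
#' @param n sample index in `1..N`.
#' @param grid a [cycle_grid()].
#' @param K expansion order.
#' @return numeric vector of length `2K`.
#' @export
basis_row <- function(n, grid, K) {
  check_order(grid, K)
  if (n < 1 || n > grid$N) stop("basis_row: sample index out of range")
  ph <- grid$phase[n] * seq_len(K)
  c(cos(ph), sin(ph))
}

#' Fourier design matrix over a cycle grid
#'
#' @param grid a [cycle_grid()].
#' @param K expansion order.
#' @param dc if `TRUE`, prepend an intercept column of ones.
#' @return an `N x 2K` (or `N x (2K+1)`) matrix; rows are [basis_row()] values.
#' @export
fourier_basis <- function(grid, K, dc = FALSE) {
  check_order(grid, K)
  ph <- outer(grid$phase, seq_len(K))        # N x K
  B <- cbind(cos(ph), sin(ph))
  if (dc) B <- cbind(1, B)
  B
}

#' Least-squares Fourier fit of a periodic signal
#'
#' Ordinary least-squares projection of a one-cycle signal onto the truncated
#' Fourier basis. On the uniform grid the basis is orthogonal, so this equals
#' DFT truncation, but non-power-of-two `N` needs no special casing. The fit
#' interpolates exactly when the signal is band-limited to order `K`.
#'
#' @param x numeric vector of length `N`, or an `N x m` matrix fitted
#'   column-wise.
#' @param grid a [cycle_grid()].
#' @param K expansion order, `K < N/2`.
#' @param dc if `TRUE`, also estimate a constant (mean) term.
#' @return a list with `coef` (a `2K x m` matrix, cosine block then sine
#'   block), `dc` (length-`m` numeric, zero when `dc = FALSE`), `K`, and
#'   `residual` (the projection residual, same shape as `x`).
#' @export
fourier_fit <- function(x, grid, K, dc = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != grid$N)
    stop("fourier_fit: signal length does not match grid N")
  if (grid$N < 2 * K + 1 + as.integer(dc))
    stop("fourier_fit: grid too short for requested order (need N >= 2K+1+dc)")
  B <- fourier_basis(grid, K, dc = dc)
  # orthogonal design: normal equations are diagonal (N for DC, N/2 per harmonic)
  ctc <- c(if (dc) grid$N, rep(grid$N / 2, 2 * K))
  beta <- crossprod(B, x) / ctc
  fitvals <- B %*% beta
  if (dc) {
    list(coef = beta[-1, , drop = FALSE], dc = as.numeric(beta[1, ]),
         K = K, residual = x - fitvals)
  } else {
    list(coef = beta, dc = numeric(ncol(x)), K = K, residual = x - fitvals)
  }
}

#' Evaluate a truncated Fourier series on a cycle grid
#'
#' @param coef `2K x m` coefficient matrix (or length-`2K` vector).
#' @param grid a [cycle_grid()].
#' @param dc constant term(s), recycled across columns; default 0.
#' @return `N x m` matrix (or length-`N` vector for vector input).
#' @export
fourier_eval <- function(coef, grid, dc = 0) {
  vec <- is.null(dim(coef))
  coef <- as.matrix(coef)
  K <- nrow(coef) / 2
  if (K != floor(K)) stop("fourier_eval: coefficient length must be even (2K)")
  check_order(grid, K)
  out <- fourier_basis(grid, K) %*% coef
  out <- sweep(out, 2, rep_len(dc, ncol(out)), `+`)
  if (vec) drop(out) else out
}

#' Two-dimensional STA Fourier coefficients
#'
#' Order-`K` sine/cosine coefficients of a zero-mean periodic planar signal,
#' the form in which per-marker soft tissue artifact is represented in its
#' link's landmark frame. There is deliberately no constant term: a constant
#' marker offset is indistinguishable from a shifted landmark and is absorbed
#' into the landmark definition.
#'
#' @param qx,qy numeric vectors of length `2K` (cosine block then sine block),
#'   in meters.
#' @return object of class `"sta_coeffs"`.
#' @export
sta_coeffs <- function(qx, qy) {
  qx <- as.numeric(qx); qy <- as.numeric(qy)
  if (length(qx) != length(qy) || length(qx) %% 2 != 0)
    stop("sta_coeffs: qx and qy must have equal, even length (2K)")
  structure(list(K = length(qx) / 2, qx = qx, qy = qy), class = "sta_coeffs")
}

#' @export
print.sta_coeffs <- function(x, ...) {
  cat(sprintf("<sta_coeffs> K = %d, |q| = %.4g m\n", x$K,
              sqrt(sum(x$qx^2 + x$qy^2))))
  invisible(x)
}

#' Evaluate an STA coefficient pair into an N x 2 displacement series
#'
#' @param coeffs an [sta_coeffs()] object.
#' @param grid a [cycle_grid()].
#' @return `N x 2` matrix of displacements (meters); zero mean over the cycle.
#' @export
eval_sta <- function(coeffs, grid) {
  fourier_eval(cbind(coeffs$qx, coeffs$qy), grid)
}

#' Fit an STA coefficient pair to a zero-mean planar series
#'
#' @param xy `N x 2` matrix.
#' @param grid a [cycle_grid()].
#' @param K expansion order.
#' @return an [sta_coeffs()] object (any mean is dropped, not represented).
#' @export
fit_sta <- function(xy, grid, K) {
  f <- fourier_fit(scale(xy, scale = FALSE), grid, K, dc = FALSE)
  sta_coeffs(f$coef[, 1], f$coef[, 2])
}
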