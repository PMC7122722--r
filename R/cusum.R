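#' Standardized one-step-ahead recursive residuals
#'
#' For each step r > k the model is fitted on observations `1..r-1` and the
#' prediction error at step r is standardized by its forecast variance factor:
#' `w_r = (y_r - x_r' b_{r-1}) / sqrt(1 + x_r' (X'X)_{r-1}^{-1} x_r)`.
#' Computed by recursive least-squares updating.
#'
#' @param X Design matrix (full column rank on its first `k` rows).
#' @param y Response vector.
#' @return Numeric vector of `nrow(X) - ncol(X)` recursive residuals.
#' @export
recursive_residuals <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2) stop("too few observations for recursive residuals", call. = FALSE)
  X0 <- X[1:k, , drop = FALSE]
  if (qr(X0)$rank < k) {
    stop("rank-deficient recursive updates at step ", k, call. = FALSE)
  }
  M <- solve(crossprod(X0))
  b <- M %*% crossprod(X0, y[1:k])
  w <- numeric(n - k)
  for (r in (k + 1):n) {
    xr <- X[r, ]
    f <- 1 + drop(t(xr) %*% M %*% xr)
    err <- y[r] - drop(xr %*% b)
    w[r - k] <- err / sqrt(f)
    Mx <- M %*% xr
    b <- b + Mx * (err / f)
    M <- M - tcrossprod(Mx) / f
  }
  w
}

#' CUSUM and CUSUMSQ parameter-stability tests
#'
#' Cumulative sums of (squared) standardized recursive residuals. Under a
#' stable model the CUSUM path stays inside the 5% straight-line bounds
#' `+/- 0.948 (sqrt(T - k) + 2 (r - k)/sqrt(T - k))` and the CUSUMSQ path,
#' which rises from 0 to exactly 1, stays within `+/- c0` of the diagonal
#' reference line `(r - k)/(T - k)`, with `c0` taken from the embedded 5%
#' critical-offset table (interpolated in `T - k`).
#'
#' @param fit An `ecm_fit` (or any list with `$X` and `$y`).
#' @return A `cusum_test`: data frames `cusum` and `cusumsq` (step, value,
#'   lower, upper) plus the within-bounds flags.
#' @export
cusum_test <- function(fit) {
  w <- recursive_residuals(fit$X, fit$y)
  m <- length(w)
  k <- ncol(fit$X)
  sigma_w <- sqrt(sum((w - mean(w))^2) / (m - 1))
  path <- cumsum(w) / sigma_w
  r <- seq_len(m)
  bound <- 0.948 * (sqrt(m) + 2 * r / sqrt(m))
  cusum <- data.frame(step = r + k, value = path, lower = -bound, upper = bound)

  sq <- cumsum(w^2) / sum(w^2)
  center <- r / m
  c0 <- cusumsq_critical_offset(m)
  cusumsq <- data.frame(step = r + k, value = sq,
                        lower = center - c0, upper = center + c0)

  structure(list(cusum = cusum, cusumsq = cusumsq,
                 cusum_within = all(abs(path) <= bound),
                 cusumsq_within = all(abs(sq - center) <= c0),
                 sigma_w = sigma_w, n_recursive = m),
            class = "cusum_test")
}

#' @export
print.cusum_test <- function(x, ...) {
  cat(sprintf("Recursive-residual stability (%d steps):\n", x$n_recursive))
  cat(sprintf("  CUSUM within 5%% bounds:   %s\n", x$cusum_within))
  cat(sprintf("  CUSUMSQ within 5%% bounds: %s (terminal value %.3f)\n",
              x$cusumsq_within, x$cusumsq$value[x$n_recursive]))
  invisible(x)
}
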