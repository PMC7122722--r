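#' VAR lag-order selection
#'
#' Fits a k-variate vector autoregression at every lag `0..max_lag` on a
#' common estimation sample (the first `max_lag` rows are held out so every
#' candidate is scored on identical data) and reports the standard selection
#' criteria: Gaussian log-likelihood, the sequential modified likelihood-ratio
#' test, the final prediction error, and the Akaike, Schwarz and Hannan-Quinn
#' information criteria. The Schwarz choice is taken as the operative lag
#' order for the ARDL stages.
#'
#' With `T` common-sample observations, `k` variables, residual covariance
#' `Sigma(p)` and `n_par = k (k p + 1)` coefficients:
#' `AIC = -2 LogL/T + 2 n_par/T`, `SBC = -2 LogL/T + n_par log(T)/T`,
#' `HQ = -2 LogL/T + 2 n_par log(log T)/T`,
#' `FPE = ((T + p k + 1)/(T - p k - 1))^k det(Sigma)`, and the sequential LR
#' statistic `(T - c)(log det Sigma(p-1) - log det Sigma(p))` with
#' small-sample correction `c = k p + 1` (parameters per equation of the
#' larger model), each test at 5% against chi-square with `k^2` degrees of
#' freedom.
#'
#' @param ds A `fire_ts` (typically log-transformed).
#' @param max_lag Largest lag tried (>= 1).
#' @param variables Variables to include; default all series.
#' @return A `lag_order_table`: one row per lag with all criteria, the
#'   per-criterion selected lag, and the chosen (Schwarz) lag.
#' @export
var_lag_selection <- function(ds, max_lag = 3, variables = NULL) {
  stopifnot(inherits(ds, "fire_ts"))
  if (max_lag < 1) stop("'max_lag' must be at least 1", call. = FALSE)
  vars <- if (is.null(variables)) setdiff(names(ds), "date") else variables
  Y <- as.matrix(as.data.frame(ds)[vars])
  k <- ncol(Y)
  n_total <- nrow(Y)
  Tn <- n_total - max_lag
  if (n_total <= k * max_lag + 10) stop("too few observations for 'max_lag'", call. = FALSE)

  sample_idx <- (max_lag + 1):n_total
  fit_var <- function(p) {
    X <- matrix(1, length(sample_idx), 1)
    if (p > 0) {
      for (j in seq_len(p)) X <- cbind(X, Y[sample_idx - j, , drop = FALSE])
    }
    B <- qr.coef(qr(X), Y[sample_idx, , drop = FALSE])
    B[is.na(B)] <- 0
    E <- Y[sample_idx, , drop = FALSE] - X %*% B
    Sigma <- crossprod(E) / Tn
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (!all(is.finite(ev)) || min(ev) <= 1e-12 * max(ev)) {
      stop("singular residual covariance at lag ", p, call. = FALSE)
    }
    det(Sigma)
  }

  dets <- vapply(0:max_lag, fit_var, numeric(1))
  logl <- -(Tn * k / 2) * (1 + log(2 * pi)) - (Tn / 2) * log(dets)
  n_par <- k * (k * (0:max_lag) + 1)
  aic <- -2 * logl / Tn + 2 * n_par / Tn
  sbc <- -2 * logl / Tn + n_par * log(Tn) / Tn
  hq  <- -2 * logl / Tn + 2 * n_par * log(log(Tn)) / Tn
  fpe <- ((Tn + (0:max_lag) * k + 1) / (Tn - (0:max_lag) * k - 1))^k * dets

  lr <- rep(NA_real_, max_lag + 1)
  lr_p <- rep(NA_real_, max_lag + 1)
  for (p in seq_len(max_lag)) {
    cc <- k * p + 1
    lr[p + 1] <- (Tn - cc) * (log(dets[p]) - log(dets[p + 1]))
    lr_p[p + 1] <- stats::pchisq(lr[p + 1], df = k^2, lower.tail = FALSE)
  }

  tab <- data.frame(lag = 0:max_lag, logl = logl, lr = lr, fpe = fpe,
                    aic = aic, sbc = sbc, hq = hq)
  sig <- which(lr_p < 0.05)
  selected <- c(
    lr  = if (length(sig)) max(sig) - 1L else 0L,
    fpe = which.min(fpe) - 1L,
    aic = which.min(aic) - 1L,
    sbc = which.min(sbc) - 1L,
    hq  = which.min(hq) - 1L
  )
  structure(list(table = tab, selected = selected,
                 chosen = unname(selected[["sbc"]]),
                 n_common = Tn, k = k, variables = vars),
            class = "lag_order_table")
}

#' @export
print.lag_order_table <- function(x, ...) {
  cat(sprintf("VAR lag selection (%d variables, common sample T = %d)\n",
              x$k, x$n_common))
  tab <- x$table
  marks <- matrix("", nrow(tab), 5,
                  dimnames = list(NULL, c("lr", "fpe", "aic", "sbc", "hq")))
  for (cr in colnames(marks)) marks[x$selected[[cr]] + 1, cr] <- "*"
  out <- data.frame(lag = tab$lag,
                    LogL = sprintf("%.2f", tab$logl),
                    LR = ifelse(is.na(tab$lr), "NA",
                                paste0(sprintf("%.2f", tab$lr), marks[, "lr"])),
                    FPE = paste0(sprintf("%.3e", tab$fpe), marks[, "fpe"]),
                    AIC = paste0(sprintf("%.3f", tab$aic), marks[, "aic"]),
                    SBC = paste0(sprintf("%.3f", tab$sbc), marks[, "sbc"]),
                    HQ = paste0(sprintf("%.3f", tab$hq), marks[, "hq"]))
  print(out, row.names = FALSE)
  cat(sprintf("Chosen lag (Schwarz): %d\n", x$chosen))
  invisible(x)
}
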