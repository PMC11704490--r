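#' Baroreflex sensitivity from an ARX spectral gain
#'
#' Fits, by least squares, the autoregressive-with-exogenous-input model
#' \deqn{RR_k = \sum_{i=1}^{N} a_i RR_{k-i} + \sum_{j=0}^{N} b_j sBP_{k-j} + e_k}
#' on mean-removed beat series, then evaluates the model spectra on the LF
#' band (0.04-0.15 Hz, beat-domain frequencies at the mean beat period). The
#' reported index is the plain PSD ratio
#' \deqn{\alpha_{LF} = P_{RR}(LF) / P_{BP}(LF)}
#' averaged over the band, where \eqn{P_{RR}} is the ARX output spectrum
#' (transfer-function gain applied to the sBP spectrum plus the filtered
#' innovation) and \eqn{P_{BP}} an autoregressive spectral estimate of the
#' sBP series. Note this ratio has units ms^2/mmHg^2; the conventional
#' alpha-index is its square root, reported alongside when
#' `alphaSqrt = TRUE`. A fit whose AR polynomial is unstable (roots on or
#' inside the unit circle of the inverse polynomial) is reported missing with
#' a diagnostic.
#'
#' @param rr numeric RR intervals (ms) or an [IntervalSeries-class] with
#'   paired sBP.
#' @param sbp numeric systolic pressures (mmHg), same length as `rr`.
#' @param order model order N (default 8, shared by both sums; `b` starts at
#'   lag 0).
#' @param lfBand LF band in Hz.
#' @param alphaSqrt also report the square-root variant.
#' @return List with `alpha_lf`, `alpha_lf_sqrt` (if requested), `a`, `b`,
#'   `sigma2`, `stable`, `reason`.
#' @export
arxBrs <- function(rr, sbp = NULL, order = 8, lfBand = c(0.04, 0.15),
                   alphaSqrt = TRUE) {
  if (methods::is(rr, "IntervalSeries")) {
    sbp <- pairedSbp(rr)
    rr <- intervalValues(rr)
  }
  stopifnot(length(rr) == length(sbp))
  miss <- function(reason)
    list(alpha_lf = NA_real_, alpha_lf_sqrt = NA_real_, a = NULL, b = NULL,
         sigma2 = NA_real_, stable = FALSE, reason = reason)
  n <- length(rr)
  if (n < 10 * order) return(miss("series shorter than 10x model order"))
  if (stats::sd(sbp) == 0)
    stopWith("autonomiq_input_error", "degenerate input: sBP has zero variance")
  dtbar <- mean(rr) / 1000             # mean beat period, s
  y <- rr - mean(rr)
  u <- sbp - mean(sbp)
  rows <- (order + 1):n
  X <- cbind(
    vapply(seq_len(order), function(i) y[rows - i], numeric(length(rows))),
    vapply(0:order, function(j) u[rows - j], numeric(length(rows))))
  fit <- stats::lm.fit(X, y[rows])
  co <- fit$coefficients
  co[is.na(co)] <- 0
  a <- co[seq_len(order)]
  b <- co[order + 1 + 0:order]
  sigma2 <- mean(fit$residuals^2)
  # stability: roots of z^N - a1 z^{N-1} - ... - aN inside the unit circle
  roots <- polyroot(c(rev(-a), 1))
  stable <- all(Mod(roots) < 1 - 1e-8)
  if (!stable) {
    out <- miss("unstable AR polynomial")
    out$a <- a; out$b <- b
    return(out)
  }
  freq <- seq(lfBand[1], lfBand[2], length.out = 50)
  z <- exp(-1i * 2 * pi * freq * dtbar)
  A <- 1 - vapply(seq_along(freq), function(i) sum(a * z[i]^(seq_len(order))),
                  complex(1))
  B <- vapply(seq_along(freq), function(i) sum(b * z[i]^(0:order)), complex(1))
  # AR spectral estimate of the sBP input
  arU <- stats::ar(u, aic = FALSE, order.max = order, method = "yule-walker")
  Au <- 1 - vapply(seq_along(freq), function(i)
    sum(arU$ar * z[i]^(seq_len(length(arU$ar)))), complex(1))
  pBP <- (arU$var.pred * dtbar) / Mod(Au)^2
  pRR <- (Mod(B)^2 * pBP + sigma2 * dtbar) / Mod(A)^2
  alpha <- mean(pRR / pBP)
  list(alpha_lf = alpha,
       alpha_lf_sqrt = if (alphaSqrt) sqrt(alpha) else NA_real_,
       a = a, b = b, sigma2 = sigma2, stable = TRUE, reason = NA_character_)
}
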