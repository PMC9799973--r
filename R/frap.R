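#' @include AllClasses.R
NULL

#' Normalize a raw FRAP trace to full scale
#'
#' Full-scale normalization: y(t) = (I(t) - I_bleach) / (I_pre - I_bleach),
#' where I_pre is the mean of the pre-bleach frames and I_bleach the first
#' post-bleach frame, so the pre-bleach level maps to 1 and the first
#' post-bleach frame to 0 exactly. Under this convention the fitted
#' amplitude is directly the mobile fraction. Time zero is the first
#' post-bleach frame.
#'
#' @param raw raw intensities, one per frame (pre- then post-bleach).
#' @param nPre number of pre-bleach frames at the start of \code{raw}.
#' @param dt frame interval in seconds.
#' @return a [FrapTrace-class].
#' @export
normalizeTrace <- function(raw, nPre, dt = 0.1) {
  nPre <- as.integer(nPre)
  stopifnot(nPre >= 1L, length(raw) > nPre)
  pre <- mean(raw[seq_len(nPre)])
  bleach <- raw[nPre + 1L]
  if (pre <= bleach)
    stop("no bleach detected: pre-bleach mean does not exceed the first post-bleach frame")
  post <- raw[(nPre + 1L):length(raw)]
  new("FrapTrace",
      times = (seq_along(post) - 1) * dt,
      values = (post - bleach) / (pre - bleach),
      nPre = nPre, prebleachMean = pre, bleachValue = bleach)
}

#' Fit the single-exponential recovery model
#'
#' Nonlinear least squares for y = a (1 - e^{-b t}) with a in [0, 1.5] and
#' b > 0. Initialization: a0 from the mean of the last 10% of points, b0
#' from the time the trace first reaches half of a0. Traces with no
#' measurable recovery are rejected with an informative error rather than
#' returning an unidentifiable rate.
#'
#' @param trace a [FrapTrace-class] with at least 10 post-bleach points.
#' @return a [FrapFit-class].
#' @export
fitRecovery <- function(trace) {
  t <- trace@times; y <- trace@values
  stopifnot(length(t) >= 10)
  nTail <- max(2L, ceiling(0.1 * length(y)))
  a0 <- mean(utils::tail(y, nTail))
  if (!is.finite(a0) || a0 < 0.02)
    stop(sprintf(paste0(
      "recovery amplitude indistinguishable from zero (plateau estimate ",
      "%.4f over the last %d points); the rate is unidentifiable"),
      a0, nTail))
  a0 <- min(max(a0, 0.05), 1.5)
  iHalf <- which(y >= a0 / 2)[1]
  tHalf0 <- if (!is.na(iHalf) && t[iHalf] > 0) t[iHalf] else max(t) / 4
  b0 <- log(2) / tHalf0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-b * t)),
                      start = list(a = a0, b = b0),
                      lower = c(0, 1e-8), upper = c(1.5, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "recovery fit failed (start a0 = %.3f, b0 = %.3f, n = %d): %s",
        a0, b0, length(y), conditionMessage(e))))
  cf <- stats::coef(fit)
  if (cf[["b"]] <= 1e-8)
    stop("recovery fit collapsed to zero rate; trace carries no kinetics")
  new("FrapFit", a = cf[["a"]], b = cf[["b"]],
      tHalf = log(2) / cf[["b"]],
      mobileFraction = min(cf[["a"]], 1.1),
      residualRms = sqrt(mean(stats::resid(fit)^2)))
}

#' Recovery half-time
#'
#' @param fit a [FrapFit-class].
#' @return ln(2) / b in seconds.
#' @export
halfTime <- function(fit) log(2) / fit@b

#' Mobile fraction of the bleached pool
#'
#' For a full-scale-normalized trace the recovery plateau \code{a} is the
#' mobile fraction; an amplitude of 0.5 corresponds to only half the
#' bleached pool exchanging.
#'
#' @param fit a [FrapFit-class].
#' @return the mobile fraction.
#' @export
mobileFraction <- function(fit) fit@mobileFraction

#' Average per-embryo recovery fits for a condition
#'
#' Coefficients are averaged across embryos (a-bar, b-bar) and the
#' condition curve y(t) = a-bar (1 - e^{-b-bar t}) is evaluated. Note that
#' the curve of mean coefficients is not the mean of the individual
#' curves when rates are heterogeneous.
#'
#' @param fits list of [FrapFit-class].
#' @param times times (s) at which to evaluate the average curve.
#' @return list with \code{a}, \code{b}, \code{tHalf}, and a data.frame
#'   \code{curve} (time, value).
#' @export
averageFits <- function(fits, times = seq(0, 17.4, by = 0.1)) {
  stopifnot(length(fits) >= 1)
  aBar <- mean(vapply(fits, recoveryAmplitude, numeric(1)))
  bBar <- mean(vapply(fits, recoveryRate, numeric(1)))
  list(a = aBar, b = bBar, tHalf = log(2) / bBar,
       curve = data.frame(time = times,
                          value = aBar * (1 - exp(-bBar * times))))
}
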