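#' Fit a biexponential decay by nonlinear least squares
#'
#' Fits `y = A1 * exp(-k1 * t) + A2 * exp(-k2 * t)` to positive series
#' such as the temporal decline of the cohort coefficient `FaS`.
#' Starting values come from classical curve peeling: the slow tail is fit
#' as a single exponential on the log scale, peeled off, and the early
#' residual fit as the fast phase. The refined fit uses
#' Levenberg-Marquardt least squares with nonnegativity bounds; the
#' convention `k1 > k2 >= 0` is enforced by swapping the phases after
#' convergence.
#'
#' @param day numeric vector of times (days).
#' @param value positive response values, same length as `day`.
#' @param tail_fraction fraction of the latest points used for the slow
#'   phase during peeling (default 0.5).
#' @return list with `A1`, `k1`, `A2`, `k2`, `r_squared`, `fitted`, and
#'   `start` (the peeling initializer).
#' @export
#' @examples
#' t <- 0:29
#' y <- 1.2 * exp(-0.9 * t) + 0.6 * exp(-0.05 * t)
#' fit_biexponential(t, y)$k1
fit_biexponential <- function(day, value, tail_fraction = 0.5) {
  day <- as.numeric(day); value <- as.numeric(value)
  if (length(day) != length(value) || length(day) < 5L) {
    stop("need >= 5 (day, value) pairs", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("values must be positive", call. = FALSE)
  }
  o <- order(day)
  day <- day[o]; value <- value[o]

  start <- peel_biexponential(day, value, tail_fraction)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ A1 * exp(-k1 * day) + A2 * exp(-k2 * day),
      start = start,
      lower = c(A1 = 0, k1 = 0, A2 = 0, k2 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) {
      stop(sprintf(
        paste0("biexponential fit did not converge (%s); peeling ",
               "initializer was A1=%.4g k1=%.4g A2=%.4g k2=%.4g"),
        conditionMessage(e), start$A1, start$k1, start$A2, start$k2),
        call. = FALSE)
    })

  p <- as.list(stats::coef(fit))
  if (p$k1 < p$k2) {                 # phase labels: k1 is the fast one
    p <- list(A1 = p$A2, k1 = p$k2, A2 = p$A1, k2 = p$k1)
  }
  fitted <- p$A1 * exp(-p$k1 * day) + p$A2 * exp(-p$k2 * day)
  ss_res <- sum((value - fitted)^2)
  ss_tot <- sum((value - mean(value))^2)
  list(A1 = p$A1, k1 = p$k1, A2 = p$A2, k2 = p$k2,
       r_squared = 1 - ss_res / ss_tot, fitted = fitted, start = start)
}

# Curve peeling: log-linear fit of the tail gives the slow phase; the
# positive part of the residual gives the fast phase.
peel_biexponential <- function(day, value, tail_fraction) {
  n <- length(day)
  n_tail <- max(3L, ceiling(n * tail_fraction))
  tail_idx <- seq.int(n - n_tail + 1L, n)
  slow <- stats::lm(log(value[tail_idx]) ~ day[tail_idx])
  k2 <- max(0, -unname(stats::coef(slow)[2]))
  A2 <- exp(unname(stats::coef(slow)[1]))

  resid <- value - A2 * exp(-k2 * day)
  pos <- which(resid > 0 & seq_len(n) < min(tail_idx))
  if (length(pos) >= 2L) {
    fast <- stats::lm(log(resid[pos]) ~ day[pos])
    k1 <- max(k2 * 2, -unname(stats::coef(fast)[2]))
    A1 <- exp(unname(stats::coef(fast)[1]))
  } else {
    # tail already explains everything; seed a nominal fast phase
    k1 <- max(1, 10 * k2)
    A1 <- max(value[1] - A2, 0.1 * A2)
  }
  list(A1 = A1, k1 = k1, A2 = A2, k2 = k2)
}
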