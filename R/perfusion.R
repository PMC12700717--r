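# CEUS destruction-replenishment kinetics. The refill model is the
# mono-exponential I(t) = A (1 - exp(-beta t)); its plateau A is the
# regional blood volume (RBV), A * beta the regional blood flow (RBF),
# 1/beta the inverse refill rate, and the refilling time RT is the time to
# reach 90% of plateau, ln(10)/beta.

#' Fit the refill model to a time-intensity curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with analytic
#' initialization: `A0 = max(I)` and `beta0` from a log-linear fit of
#' `1 - I/A0`. Non-convergence or a non-positive rate estimate yields an
#' explicit fit-failure result, never a silent `NaN`.
#'
#' @param tic A list with numeric `t` (seconds, strictly increasing, at
#'   least 10 points) and `intensity`.
#' @return A list of class `perfusion_fit`: `converged`, and when
#'   converged `A` (RBV), `beta`, `beta_inv`, `RBF = A * beta`,
#'   `RT = log(10)/beta`, `RSS`, `R2`.
#' @export
fit_refill <- function(tic) {
  t <- tic$t; y <- tic$intensity
  if (length(t) < 10) stopf("need at least 10 time points, got %d", length(t))
  if (any(!is.finite(t)) || any(!is.finite(y))) stopf("non-finite TIC values")
  if (diff(range(y)) <= 0) stopf("intensity range must be positive")
  fail <- function(reason)
    structure(list(converged = FALSE, reason = reason),
              class = "perfusion_fit")
  A0 <- max(y)
  frac <- 1 - y / (A0 * 1.01)
  ok <- frac > 1e-8
  beta0 <- if (sum(ok) >= 2) {
    b <- -stats::coef(stats::lm(log(frac[ok]) ~ 0 + t[ok]))[[1]]
    if (is.finite(b) && b > 0) b else 1 / stats::median(t)
  } else 1 / stats::median(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-beta * t)),
                      start = list(A = A0, beta = beta0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("no convergence"))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["beta"]] <= 0 || cf[["A"]] <= 0)
    return(fail("non-positive parameter estimate"))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(converged = TRUE, A = cf[["A"]], beta = cf[["beta"]],
                 beta_inv = 1 / cf[["beta"]],
                 RBF = cf[["A"]] * cf[["beta"]],
                 RT = log(10) / cf[["beta"]],
                 RSS = rss, R2 = if (tss > 0) 1 - rss / tss else NA_real_),
            class = "perfusion_fit")
}

#' Tabulate the four perfusion features per subject
#'
#' Fits [fit_refill()] to each subject's curve and returns the four
#' microvascular perfusion features; failed fits are flagged (`converged =
#' FALSE`, feature columns `NA`) so downstream correlation can exclude
#' them.
#'
#' @param tics List of per-subject curves (each with `subject_id`, `t`,
#'   `intensity`), e.g. from [gen_tics()] or [read_tics()].
#' @return Data frame: `subject_id`, `converged`, `RBV`, `RBF`, `beta_inv`,
#'   `RT`.
#' @export
perfusion_table <- function(tics) {
  if (!length(tics)) stopf("need at least one subject")
  rows <- lapply(tics, function(tc) {
    f <- tryCatch(fit_refill(tc), error = function(e)
      structure(list(converged = FALSE, reason = conditionMessage(e)),
                class = "perfusion_fit"))
    if (f$converged)
      data.frame(subject_id = tc$subject_id, converged = TRUE, RBV = f$A,
                 RBF = f$RBF, beta_inv = f$beta_inv, RT = f$RT,
                 stringsAsFactors = FALSE)
    else
      data.frame(subject_id = tc$subject_id, converged = FALSE,
                 RBV = NA_real_, RBF = NA_real_, beta_inv = NA_real_,
                 RT = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$converged)) stopf("all perfusion fits failed")
  rownames(out) <- NULL
  out
}
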