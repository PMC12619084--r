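#' Extra sum-of-squares F test for nested curve fits
#'
#' Tests whether two stimulus-response datasets are adequately described
#' by one shared curve or require separate fits per group: the model is
#' fitted once to the pooled data (residual sum of squares
#' \eqn{SS_{pooled}}, df \eqn{n - k}) and separately to each group
#' (\eqn{SS_{sep} = SS_A + SS_B}, df \eqn{n - 2k}), and
#' \deqn{F = \frac{(SS_{pooled} - SS_{sep}) / (df_{pooled} - df_{sep})}
#'                {SS_{sep} / df_{sep}}}
#' is referred to the F distribution.
#'
#' Models: `"sigmoid3"`, the 3-parameter logistic
#' \eqn{y = y_{max} / (1 + e^{-(x - x_{50})/k})} fitted by
#' Levenberg-Marquardt least squares; `"quadratic"`, an ordinary
#' quadratic polynomial fitted by [lm()].
#'
#' @param a,b Data frames (one per group) with columns `stimulus` and
#'   `response`.
#' @param model `"sigmoid3"` or `"quadratic"`.
#' @param start Optional named starting values for the sigmoid fit
#'   (`ymax`, `x50`, `slope`); self-derived otherwise.
#' @return An object of class `extra_ss_ftest`: `F`, `df_num`, `df_den`,
#'   `p`, `ss_pooled`, `ss_separate`, `model`, `n`.
#' @examples
#' x <- rep(seq(0, 100, by = 20), each = 3)
#' a <- data.frame(stimulus = x,
#'                 response = 50 / (1 + exp(-(x - 40) / 10)) + rnorm(length(x)))
#' b <- data.frame(stimulus = x,
#'                 response = 15 / (1 + exp(-(x - 40) / 10)) + rnorm(length(x)))
#' extra_ss_f_test(a, b, model = "sigmoid3")
#' @export
extra_ss_f_test <- function(a, b, model = c("sigmoid3", "quadratic"),
                            start = NULL) {
  model <- match.arg(model)
  for (d in list(a, b))
    if (!is.data.frame(d) || !all(c("stimulus", "response") %in% names(d)))
      stop_srseize("each group needs columns 'stimulus' and 'response'")
  pooled <- rbind(a[c("stimulus", "response")], b[c("stimulus", "response")])
  k <- 3L  # both models have 3 parameters
  n <- nrow(pooled)
  if (nrow(a) <= k || nrow(b) <= k)
    stop_srseize("need more points than parameters in each group")
  ss <- function(d) curve_fit_ss(d, model, start)
  ss_pooled <- ss(pooled)
  ss_sep <- ss(a) + ss(b)
  df_pooled <- n - k
  df_sep <- n - 2L * k
  if (df_sep <= 0) stop_srseize("too few points for separate fits")
  Fstat <- max(0, (ss_pooled - ss_sep) / (df_pooled - df_sep) /
                    (ss_sep / df_sep))
  structure(list(F = Fstat, df_num = df_pooled - df_sep, df_den = df_sep,
                 p = pf(Fstat, df_pooled - df_sep, df_sep,
                        lower.tail = FALSE),
                 ss_pooled = ss_pooled, ss_separate = ss_sep,
                 model = model, n = n),
            class = "extra_ss_ftest")
}

curve_fit_ss <- function(d, model, start = NULL) {
  if (model == "quadratic") {
    fit <- lm(response ~ stimulus + I(stimulus^2), data = d)
    return(sum(resid(fit)^2))
  }
  if (is.null(start)) {
    ymax0 <- max(d$response) * 1.05
    if (ymax0 <= 0) ymax0 <- 1
    half <- ymax0 / 2
    x50_0 <- d$stimulus[which.min(abs(d$response - half))]
    slope0 <- diff(range(d$stimulus)) / 5
    if (slope0 <= 0) slope0 <- 1
    start <- list(ymax = ymax0, x50 = x50_0, slope = slope0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ ymax / (1 + exp(-(stimulus - x50) / slope)),
      data = d, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_srseize("sigmoid fit failed: ", conditionMessage(e),
                   " (n=", nrow(d), ", start ymax=",
                   signif(start$ymax, 3), ")"))
  sum(resid(fit)^2)
}

#' @export
print.extra_ss_ftest <- function(x, ...) {
  cat(sprintf("Extra sum-of-squares F test (%s model)\n", x$model))
  cat(sprintf("  F(%d,%d) = %.4g, p = %.3g\n", x$df_num, x$df_den, x$F,
              x$p))
  cat(sprintf("  SS pooled %.4g, SS separate %.4g (n = %d)\n",
              x$ss_pooled, x$ss_separate, x$n))
  invisible(x)
}
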