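#' Replica-level percentile bootstrap confidence interval
#'
#' Resamples whole replicas (never frames: frames within a replica are
#' autocorrelated, so the replica is the exchangeable unit) with
#' replacement and returns a percentile confidence interval for a
#' statistic of the per-replica values.
#'
#' @param values numeric vector, one value per independent replica.
#' @param statistic function reducing a numeric vector to a scalar
#'   (default [mean]).
#' @param n_boot number of bootstrap resamples (default 20000).
#' @param level confidence level in (0, 1).
#' @param seed integer seed; the routine is deterministic for a fixed
#'   seed and does not disturb the caller's RNG state.
#' @param method `"percentile"` (default) or `"bca"`
#'   (bias-corrected and accelerated, jackknife acceleration).
#' @return object of class `bootstrap_result`: list with `estimate`,
#'   `ci_low`, `ci_high`, `n_boot`, `level`, `seed`, `method`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 20000L,
                         level = 0.95, seed = 0L,
                         method = c("percentile", "bca")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("bootstrap_ci() needs at least 2 replicas, got ", length(values))
  if (anyNA(values)) stop("bootstrap_ci(): NA values")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")

  est <- statistic(values)
  n <- length(values)
  stat_boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(idx, 1L, function(i) statistic(values[i]))
  })
  alpha <- (1 - level) / 2
  if (method == "percentile") {
    ci <- unname(stats::quantile(stat_boot, c(alpha, 1 - alpha), type = 7))
  } else {
    # BCa: bias correction from the bootstrap distribution, acceleration
    # from the jackknife skewness of the statistic.
    z0 <- stats::qnorm(mean(stat_boot < est))
    jack <- vapply(seq_len(n), function(i) statistic(values[-i]), 0)
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    a <- if (den == 0) 0 else num / den
    zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
    p_lo <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    p_hi <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
    if (!is.finite(p_lo)) p_lo <- alpha
    if (!is.finite(p_hi)) p_hi <- 1 - alpha
    ci <- unname(stats::quantile(stat_boot, c(p_lo, p_hi), type = 7))
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), level = level,
                 seed = as.integer(seed), method = method),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.6g  [%0.6g, %0.6g]  (%g%% %s bootstrap, %d resamples)\n",
              x$estimate, x$ci_low, x$ci_high, 100 * x$level, x$method,
              x$n_boot))
  invisible(x)
}

#' Coverage-factor confidence half-width
#'
#' Half-width of a confidence interval for the mean obtained by
#' multiplying the standard error of the mean by a Student-t coverage
#' factor with n - 1 degrees of freedom.
#'
#' @param values numeric vector (>= 2 values).
#' @param level confidence level.
#' @return half-width (same units as `values`).
#' @export
coverage_ci <- function(values, level = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("coverage_ci() needs at least 2 values")
  sem <- stats::sd(values) / sqrt(n)
  stats::qt(1 - (1 - level) / 2, df = n - 1) * sem
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
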