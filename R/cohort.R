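#' Fit the 1D-diffusion effect-time trend to silence-condition records
#'
#' Under pure diffusion from a constant round-window source, the time for
#' the concentration at distance x to reach the threshold fraction theta
#' of the source is `t = x^2 / (4 D z^2)`, `z = erfc^-1(theta)`. This
#' one-parameter curve is fit to silence-condition effect times by least
#' squares in log-time space (multiplicative errors, consistent with the
#' dB treatment of residuals), which gives the closed form
#' `log D_eff = mean(log(x^2 / (4 z^2 t)))`. The fitted trend is the
#' normalization reference for all conditions.
#'
#' A free-exponent log-log regression `log t ~ log x` is also run as a
#' diagnostic (`exponent`); pure diffusion predicts slope 2.
#'
#' @param records data frame with columns `place_m` and `te_min` (a
#'   cohort of effect-time records, typically the silence condition)
#' @param threshold_frac effect threshold as a fraction of the source
#'   concentration (default 0.01)
#' @return an object of class `trend_model` with `D_eff_m2_s`,
#'   `exponent`, residual spread in dB, and `predict_min(x_m)`
#' @export
fit_diffusion_trend <- function(records, threshold_frac = 0.01) {
  req <- c("place_m", "te_min")
  if (!all(req %in% names(records)))
    stop("records must have columns place_m and te_min", call. = FALSE)
  ok <- is.finite(records$place_m) & is.finite(records$te_min) &
    records$te_min > 0
  x <- records$place_m[ok]; te_s <- records$te_min[ok] * 60
  if (length(x) < 3L) stop("need at least 3 usable records", call. = FALSE)
  if (diff(range(x)) <= 1e-3)
    stop("records must span more than 1 mm of places", call. = FALSE)
  z <- erfc_inv(threshold_frac)
  log_d <- mean(log(x^2 / (4 * z^2 * te_s)))
  D_eff <- exp(log_d)
  resid_db <- 20 * log10(te_s / (x^2 / (4 * D_eff * z^2)))
  expo <- unname(stats::coef(stats::lm(log(te_s) ~ log(x)))[2L])
  structure(list(D_eff_m2_s = D_eff, threshold_frac = threshold_frac,
                 n = length(x), sigma_db = stats::sd(resid_db),
                 exponent = expo,
                 predict_min = function(x_m) x_m^2 / (4 * D_eff * z^2) / 60),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat("<trend_model>\n")
  cat(sprintf("  D_eff = %.3g m^2/s (n = %d, residual sd %.2f dB)\n",
              x$D_eff_m2_s, x$n, x$sigma_db))
  cat(sprintf("  free-exponent fit of tE vs x: %.3f (diffusion predicts 2)\n",
              x$exponent))
  invisible(x)
}

#' Effect time in dB relative to the diffusion trend
#'
#' `tE in dB = 20 log10(tE / tTrend)`: 0 dB lies on the trend, negative
#' values mean faster-than-diffusion delivery.
#'
#' @param te_min observed effect time (minutes)
#' @param ttrend_min trend prediction at the same place (minutes)
#' @return dB value(s)
#' @export
effect_time_dB <- function(te_min, ttrend_min) {
  if (any(!is.finite(te_min) | te_min <= 0) ||
      any(!is.finite(ttrend_min) | ttrend_min <= 0))
    stop("effect times must be positive and finite", call. = FALSE)
  20 * log10(te_min / ttrend_min)
}

# Welch t-test tolerating the degenerate identical-sample case
safe_welch <- function(a, b) {
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12 && abs(mean(a) - mean(b)) < 1e-12)
    return(list(statistic = 0, p.value = 1))
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

group_summary <- function(v) {
  n <- length(v)
  m <- mean(v)
  if (n >= 2L && stats::sd(v) > 0) {
    half <- stats::qt(0.975, n - 1L) * stats::sd(v) / sqrt(n)
  } else half <- 0
  c(n = n, mean_db = m, ci_lo = m - half, ci_hi = m + half)
}

#' Stratified comparison of dB-normalized effect times
#'
#' Two-tailed Welch t-tests between two cohorts of effect-time records,
#' normalized to the diffusion trend, for three strata: the whole CF
#' range, low-CF places (CF < `cf_split_hz`), and high-CF places
#' (CF > `cf_split_hz`). Records at exactly the split frequency go to the
#' low stratum. Group means with 95% CIs are reported per stratum; a
#' stratum with fewer than 2 records in either group is marked not
#' computable.
#'
#' @param a,b data frames with columns `cf_hz`, `place_m`, `te_min`
#' @param trend a [fit_diffusion_trend()] model used for dB normalization
#' @param cf_split_hz stratification split (default 4500)
#' @return an object of class `comparison_result`: one row per stratum
#'   with group summaries, Welch t and p
#' @export
compare_groups <- function(a, b, trend, cf_split_hz = 4500) {
  stopifnot(inherits(trend, "trend_model"))
  db_of <- function(r) effect_time_dB(r$te_min, trend$predict_min(r$place_m))
  da <- db_of(a); db <- db_of(b)
  strata <- list(
    whole = list(rep(TRUE, nrow(a)), rep(TRUE, nrow(b))),
    low_cf = list(a$cf_hz <= cf_split_hz, b$cf_hz <= cf_split_hz),
    high_cf = list(a$cf_hz > cf_split_hz, b$cf_hz > cf_split_hz))
  rows <- lapply(names(strata), function(s) {
    sa <- da[strata[[s]][[1]]]; sb <- db[strata[[s]][[2]]]
    if (length(sa) < 2L || length(sb) < 2L) {
      return(data.frame(stratum = s, n_a = length(sa), n_b = length(sb),
                        mean_a_db = NA, ci_a_lo = NA, ci_a_hi = NA,
                        mean_b_db = NA, ci_b_lo = NA, ci_b_hi = NA,
                        t = NA, p = NA, computable = FALSE))
    }
    ga <- group_summary(sa); gb <- group_summary(sb)
    w <- safe_welch(sa, sb)
    data.frame(stratum = s, n_a = ga["n"], n_b = gb["n"],
               mean_a_db = ga["mean_db"], ci_a_lo = ga["ci_lo"],
               ci_a_hi = ga["ci_hi"],
               mean_b_db = gb["mean_db"], ci_b_lo = gb["ci_lo"],
               ci_b_hi = gb["ci_hi"],
               t = w$statistic, p = w$p.value, computable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Stratified Welch t-tests on dB-normalized effect times\n")
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3)
  for (cc in c("mean_a_db", "mean_b_db", "t")) df[[cc]] <- round(df[[cc]], 2)
  print(df[, c("stratum", "n_a", "n_b", "mean_a_db", "mean_b_db", "t", "p",
               "computable")])
  invisible(x)
}

#' Write / read effect-time record tables
#'
#' CSV round-trip of the shared record format (`animal_id`, `cf_hz`,
#' `place_m`, `condition`, `te_min`).
#'
#' @param records data frame of effect-time records
#' @param path CSV file path
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
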