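#' Renal resistive index from one Doppler spectrum
#'
#' `RRI = (SV - DV) / SV`, where `SV` is the peak systolic velocity and `DV`
#' the minimum diastolic velocity of an interlobular-artery spectrum (cm/s).
#' Scale-invariant: multiplying both velocities by `k > 0` leaves RRI
#' unchanged. Vectorized over paired inputs.
#'
#' @param sv peak systolic velocity, > 0.
#' @param dv minimum diastolic velocity, in `[0, sv]`.
#' @return RRI value(s) in `[0, 1]`.
#' @examples
#' rri(100, 30)   # 0.7
#' rri(87.5, 26.25)
#' @export
rri <- function(sv, dv) {
  if (length(sv) != length(dv))
    stop_invalid("`sv` and `dv` must have equal length")
  bad <- !is.finite(sv) | !is.finite(dv) | sv <= 0 | dv < 0 | dv > sv
  if (any(bad))
    stop_domain(sprintf(
      "invalid spectrum measurement(s) at position(s) %s: need sv > 0 and 0 <= dv <= sv",
      paste(which(bad), collapse = ", ")), "sonopcnn_invalid_measurement")
  (sv - dv) / sv
}

#' Daily RRI: average over consecutive spectra
#'
#' The per-day value is the arithmetic mean of per-spectrum RRIs over the
#' 4-6 consecutive similar spectra acquired at one examination. Counts
#' outside the configured bounds raise an error naming the count.
#'
#' @param sv,dv paired vectors of per-spectrum velocities.
#' @param min_spectra,max_spectra allowed number of spectra (defaults 4 and 6).
#' @return mean RRI for the day.
#' @examples
#' rri_daily(rep(100, 4), rep(30, 4))  # 0.7
#' @export
rri_daily <- function(sv, dv, min_spectra = 4L, max_spectra = 6L) {
  n <- length(sv)
  if (n < min_spectra)
    stop_domain(sprintf("insufficient spectra: got %d, need at least %d",
                        n, min_spectra), "sonopcnn_insufficient_spectra")
  if (n > max_spectra)
    stop_domain(sprintf("too many spectra: got %d, allowed at most %d",
                        n, max_spectra), "sonopcnn_insufficient_spectra")
  mean(rri(sv, dv))
}

#' Aggregate multi-rater Doppler-ultrasound perfusion scores
#'
#' The 0-3 semiquantitative DU score (0 = no detectable vessels, 1 = a few
#' hilar vessels, 2 = interlobular vessels in the parenchyma, 3 = arcuate
#' artery level visible) is assigned independently by several raters per
#' patient-day; the consensus is the median across raters, rounded half up
#' to an integer score.
#'
#' @param scores data.frame with columns `patient_id`, `day`, `rater_id`,
#'   `score` (integer in 0..3).
#' @return data.frame with one row per patient-day: `patient_id`, `day`,
#'   `score`.
#' @examples
#' x <- data.frame(patient_id = 1, day = 1, rater_id = 1:3, score = c(2, 2, 3))
#' aggregate_du(x)$score  # 2
#' @export
aggregate_du <- function(scores) {
  need <- c("patient_id", "day", "rater_id", "score")
  if (!all(need %in% names(scores)))
    stop_invalid(paste("`scores` must have columns", paste(need, collapse = ", ")))
  if (nrow(scores) < 1L) stop_invalid("no ratings supplied")
  if (any(!scores$score %in% 0:3))
    stop_invalid("DU scores must be integers in {0, 1, 2, 3}")
  agg <- stats::aggregate(score ~ patient_id + day, data = scores,
                          FUN = function(v) round_half_up(stats::median(v)))
  agg$score <- as.integer(agg$score)
  agg[order(agg$patient_id, agg$day), , drop = FALSE]
}

#' Within-patient slope of RRI over ICU days
#'
#' Estimates the common per-day drift of RRI in a longitudinal cohort by
#' within-patient centering: day and RRI are demeaned within each patient,
#' absorbing patient-specific intercepts (the random-intercept structure of
#' a mixed model), and the pooled least-squares slope is fit to the centered
#' data. The standard error uses the pooled residual variance with
#' `n - n_patients - 1` degrees of freedom; the 95% CI is the normal
#' approximation.
#'
#' @param records data.frame with columns `patient_id`, `day`, `rri`.
#' @param conf confidence level (default 0.95).
#' @return list of class `slope_fit`: `slope` (per day), `intercept` (grand
#'   mean RRI at day 0), `se`, `ci` (length 2), `n`, `n_patients`, `df`.
#' @examples
#' d <- expand.grid(patient_id = 1:3, day = 1:5)
#' d$rri <- 0.6 + 0.01 * d$patient_id + 0.0135 * d$day
#' fit_time_slope(d)$slope  # 0.0135 exactly
#' @export
fit_time_slope <- function(records, conf = 0.95) {
  need <- c("patient_id", "day", "rri")
  if (!all(need %in% names(records)))
    stop_invalid(paste("`records` must have columns", paste(need, collapse = ", ")))
  pid <- as.factor(records$patient_id)
  if (nlevels(pid) < 2L)
    stop_domain("need at least 2 patients", "sonopcnn_degenerate_design")
  day <- as.numeric(records$day)
  y <- as.numeric(records$rri)
  xt <- day - stats::ave(day, pid)
  yt <- y - stats::ave(y, pid)
  sxx <- sum(xt^2)
  if (sxx <= 0)
    stop_domain("degenerate design: no within-patient day variation",
                "sonopcnn_degenerate_design")
  slope <- sum(xt * yt) / sxx
  resid <- yt - slope * xt
  n <- length(y)
  df <- n - nlevels(pid) - 1L
  if (df < 1L)
    stop_domain("degenerate design: not enough observations per patient",
                "sonopcnn_degenerate_design")
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(day),
                 se = se,
                 ci = c(slope - z * se, slope + z * se),
                 n = n, n_patients = nlevels(pid), df = df),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("RRI time slope: %.5f per day (se %.5f, 95%% CI %.5f to %.5f)\n",
              x$slope, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  %d observations, %d patients\n", x$n, x$n_patients))
  invisible(x)
}

#' ROC curve and AUC of RRI for AKI diagnosis
#'
#' Sweeps thresholds over the observed RRI values (rule: predict positive
#' when `rri >= t`; `+Inf`/`-Inf` sentinels included), computes sensitivity
#' and specificity at each threshold, the AUC by the trapezoid rule, and the
#' optimal cutoff by Youden's J. The trapezoid AUC is cross-checked
#' internally against the tie-corrected rank (Mann-Whitney) statistic
#' `(concordant + 0.5 * ties) / (n_pos * n_neg)`.
#'
#' @param records data.frame with columns `rri` and `aki` (1 = AKI positive,
#'   0 = negative); optionally `day`.
#' @param day if given and `records` has a `day` column, restrict to that day.
#' @param direction `"greater"` (default; higher RRI indicates AKI) or
#'   `"less"`.
#' @return list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @examples
#' d <- data.frame(rri = c(0.7, 0.8, 0.6, 0.6, 0.5), aki = c(1, 1, 1, 0, 0))
#' roc_auc(d)$auc  # (5 + 0.5) / 6
#' @export
roc_auc <- function(records, day = NULL, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  need <- c("rri", "aki")
  if (!all(need %in% names(records)))
    stop_invalid("`records` must have columns rri and aki")
  if (!is.null(day)) {
    if (!"day" %in% names(records))
      stop_invalid("`day` given but `records` has no day column")
    records <- records[records$day == day, , drop = FALSE]
  }
  lab <- records$aki
  if (any(!lab %in% c(0, 1)))
    stop_invalid("`aki` must be binary 0/1")
  score <- as.numeric(records$rri)
  if (direction == "less") score <- -score
  pos <- score[lab == 1]
  neg <- score[lab == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 < 1L || n0 < 1L)
    stop_domain(sprintf(
      "undefined AUC: need both classes (got %d positive, %d negative)",
      n1, n0), "sonopcnn_undefined_auc")

  # rank (Mann-Whitney) AUC with midranks for ties
  r <- rank(c(pos, neg))
  auc_rank <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  fpr <- 1 - spec
  auc_trap <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  stopifnot(abs(auc_trap - auc_rank) < 1e-10)  # internal cross-check

  finite <- is.finite(thr)
  j <- sens + spec - 1
  best <- which(finite)[which.max(j[finite])]
  cut <- thr[best]
  structure(list(thresholds = if (direction == "less") -thr else thr,
                 sensitivity = sens, specificity = spec,
                 auc = auc_rank,
                 youden_cutoff = if (direction == "less") -cut else cut,
                 youden_j = j[best],
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC of RRI for AKI: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  optimal cutoff (Youden's J = %.3f): RRI >= %.4f\n",
              x$youden_j, x$youden_cutoff))
  invisible(x)
}
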