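#' Specification of a synthetic kidney phantom
#'
#' Describes a low-contrast speckled renal ultrasound phantom: an elliptical
#' kidney (cortex) with concentric medulla and echogenic sinus regions on a
#' dark background, multiplied by Rayleigh-like unit-mean speckle, then
#' contrast-compressed into a narrow gray band to emulate the low dynamic
#' range of clinical ultrasound.
#'
#' @param height,width frame size in pixels.
#' @param center ellipse center `(row, col)`; default frame center.
#' @param axes semi-axes `(major, minor)` of the kidney ellipse in pixels.
#' @param rotation ellipse rotation in radians.
#' @param cortex_mean,medulla_mean,sinus_mean,background_mean region mean
#'   intensities before compression (medulla at 65% of the kidney extent,
#'   sinus at 35%).
#' @param speckle multiplicative speckle scale in `[0, 1]`: each pixel is
#'   multiplied by `1 + speckle * (r - 1)` with `r` unit-mean Rayleigh.
#'   0 disables noise; 1 is fully developed speckle.
#' @param compression fraction of the full gray range the output occupies
#'   (default 0.3, i.e. about 77 of 256 levels).
#' @param band_center gray level at the middle of the compressed band.
#' @param levels gray levels `G`.
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         center = NULL, axes = NULL, rotation = 0.35,
                         cortex_mean = 110, medulla_mean = 75,
                         sinus_mean = 150, background_mean = 40,
                         speckle = 0.5, compression = 0.3,
                         band_center = 100, levels = 256L, seed = 1L) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 8L || width < 8L)
    stop_param("phantom frame must be at least 8 x 8")
  center <- center %||% c(height / 2, width / 2)
  axes <- axes %||% c(0.40 * min(height, width), 0.26 * min(height, width))
  if (any(axes <= 0) ||
      center[1] - axes[1] < 1 || center[1] + axes[1] > height ||
      center[2] - axes[1] < 1 || center[2] + axes[1] > width)
    stop_domain("kidney ellipse does not fit inside the frame",
                "sonopcnn_invalid_spec")
  if (speckle < 0 || speckle > 1)
    stop_param("`speckle` must be in [0, 1]")
  if (compression <= 0 || compression > 1)
    stop_param("`compression` must be in (0, 1]")
  structure(list(height = height, width = width, center = center,
                 axes = axes, rotation = rotation,
                 cortex_mean = cortex_mean, medulla_mean = medulla_mean,
                 sinus_mean = sinus_mean, background_mean = background_mean,
                 speckle = speckle, compression = compression,
                 band_center = band_center, levels = as.integer(levels),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# unit-mean Rayleigh draws: sigma * sqrt(-2 log U) with sigma = sqrt(2/pi)
rrayleigh_unit <- function(n) sqrt(2 / pi) * sqrt(-2 * log(stats::runif(n)))

#' Generate a low-contrast speckled kidney phantom
#'
#' Deterministic given the spec (seed included). Region means are multiplied
#' by speckle noise, then the whole frame is affinely compressed into the
#' band `band_center +/- compression * (G - 1) / 2` and quantized with
#' round-half-up, producing a valid low-contrast [gray_image()].
#'
#' @param spec a [phantom_spec()].
#' @return a [gray_image()].
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 7))
#' diff(range(ph))  # narrow band: <= ~80 levels
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("`spec` must be a phantom_spec")
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    rr <- matrix(seq_len(h), h, w) - spec$center[1]
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) - spec$center[2]
    co <- cos(spec$rotation); si <- sin(spec$rotation)
    u <- (rr * co + cc * si) / spec$axes[1]
    v <- (-rr * si + cc * co) / spec$axes[2]
    d2 <- u^2 + v^2   # squared normalized elliptical radius
    base <- matrix(spec$background_mean, h, w)
    base[d2 <= 1] <- spec$cortex_mean
    base[d2 <= 0.65^2] <- spec$medulla_mean
    base[d2 <= 0.35^2] <- spec$sinus_mean
    if (spec$speckle > 0) {
      noise <- 1 + spec$speckle * (rrayleigh_unit(h * w) - 1)
      base <- base * pmax(matrix(noise, h, w), 0)
    }
    g <- spec$levels
    half <- spec$compression * (g - 1) / 2
    lo <- spec$band_center - half
    hi <- spec$band_center + half
    rngv <- max(base) - min(base)
    out <- if (rngv > 0) lo + (base - min(base)) / rngv * (hi - lo)
           else matrix(spec$band_center, h, w)
    gray_image(pmin(pmax(round_half_up(out), 0), g - 1), levels = g)
  })
}

#' Simulate consecutive Doppler spectra for one examination
#'
#' Draws `cycles` (systolic, diastolic) velocity pairs with Gaussian jitter
#' around the given means, rejection-resampled until `0 <= dv <= sv` and
#' `sv > 0` hold, emulating 4-6 consecutive similar spectra.
#'
#' @param sv_mean,dv_mean mean velocities (cm/s), `0 < dv_mean < sv_mean`.
#' @param cycles number of spectra (4-6 by default convention).
#' @param noise_sd Gaussian jitter sd (cm/s) applied to both velocities.
#' @param seed RNG seed.
#' @return data.frame with columns `sv`, `dv`.
#' @examples
#' sp <- make_doppler(100, 30, cycles = 4, noise_sd = 0, seed = 1)
#' rri_daily(sp$sv, sp$dv)  # 0.7
#' @export
make_doppler <- function(sv_mean = 100, dv_mean = 30, cycles = 5L,
                         noise_sd = 5, seed = 1L) {
  if (!(sv_mean > 0) || dv_mean < 0 || dv_mean >= sv_mean)
    stop_param("need 0 <= dv_mean < sv_mean and sv_mean > 0")
  if (noise_sd < 0) stop_param("`noise_sd` must be >= 0")
  withr::with_seed(as.integer(seed), {
    sv <- numeric(cycles)
    dv <- numeric(cycles)
    for (k in seq_len(cycles)) {
      repeat {
        s <- stats::rnorm(1, sv_mean, noise_sd)
        d <- stats::rnorm(1, dv_mean, noise_sd)
        if (s > 0 && d >= 0 && d <= s) break
      }
      sv[k] <- s
      dv[k] <- d
    }
    data.frame(sv = sv, dv = dv)
  })
}

#' Specification of a simulated longitudinal ICU cohort
#'
#' Describes RRI trajectories over consecutive ICU days with patient-level
#' random intercepts, a common daily drift, an additive AKI shift, and
#' Gaussian residual noise. Defaults mirror the clinical scale of a small
#' severe-sepsis cohort: 20 patients followed for 7 days, drift 0.0135 RRI
#' per day, baseline RRI 0.70.
#'
#' @param n_patients number of patients (>= 2).
#' @param days observation window in days (records at days `1..days`).
#' @param baseline_mean,between_sd mean and between-patient sd of the
#'   patient-level baseline RRI.
#' @param slope common RRI drift per ICU day.
#' @param residual_sd sd of the per-observation Gaussian noise.
#' @param aki_fraction fraction of patients labelled AKI-positive; must
#'   yield at least one patient in each class.
#' @param aki_effect additive RRI shift in AKI-positive patients.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20L, days = 7L,
                        baseline_mean = 0.70, between_sd = 0.05,
                        slope = 0.0135, residual_sd = 0.02,
                        aki_fraction = 0.5, aki_effect = 0.075,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop_param("`n_patients` must be >= 2")
  if (days < 1L) stop_param("`days` must be >= 1")
  if (between_sd < 0 || residual_sd < 0)
    stop_param("standard deviations must be >= 0")
  n_pos <- round_half_up(aki_fraction * n_patients)
  if (n_pos < 1L || n_pos >= n_patients)
    stop_domain(sprintf(
      "degenerate cohort: aki_fraction %.2f gives %d positives of %d patients",
      aki_fraction, n_pos, n_patients), "sonopcnn_degenerate_cohort")
  structure(list(n_patients = n_patients, days = as.integer(days),
                 baseline_mean = baseline_mean, between_sd = between_sd,
                 slope = slope, residual_sd = residual_sd,
                 aki_fraction = aki_fraction, n_pos = as.integer(n_pos),
                 aki_effect = aki_effect, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a longitudinal RRI cohort
#'
#' `rri(p, d) = clip(b_p + slope * d + aki_p * effect + eps, 0, 1)` with
#' `b_p ~ N(baseline_mean, between_sd)` and
#' `eps ~ N(0, residual_sd)`; AKI labels are assigned to a random subset of
#' the stated fraction. Deterministic given the spec.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `patient_id`, `day`, `rri`, `aki`.
#' @examples
#' coh <- make_cohort(cohort_spec(seed = 3))
#' fit_time_slope(coh)
#' @export
make_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop_invalid("`spec` must be a cohort_spec")
  withr::with_seed(spec$seed, {
    b <- stats::rnorm(spec$n_patients, spec$baseline_mean, spec$between_sd)
    aki <- integer(spec$n_patients)
    aki[sample.int(spec$n_patients, spec$n_pos)] <- 1L
    out <- expand.grid(day = seq_len(spec$days),
                       patient_id = seq_len(spec$n_patients))
    out <- out[, c("patient_id", "day")]
    eps <- stats::rnorm(nrow(out), 0, spec$residual_sd)
    val <- b[out$patient_id] + spec$slope * out$day +
      spec$aki_effect * aki[out$patient_id] + eps
    out$rri <- pmin(pmax(val, 0), 1)
    out$aki <- aki[out$patient_id]
    rownames(out) <- NULL
    out
  })
}
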