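#' Bi-exponential reference-region curve
#'
#' Models the cerebellar (reference) time-activity curve after a bolus
#' injection as `A * (exp(-lambda_slow * t) - exp(-lambda_fast * t))`:
#' a fast uptake phase followed by slow washout. Defaults peak around
#' 6–7 min and retain substantial activity through the end of a 55 min
#' acquisition, as typical for [11C]-labelled D1 ligands in reference
#' tissue.
#'
#' @param amplitude curve amplitude `A` (arbitrary activity units).
#' @param lambda_slow,lambda_fast washout/uptake rate constants (1/min),
#'   `0 < lambda_slow < lambda_fast`.
#' @return An exponential-mixture object of class `exp_mix` with fields
#'   `coef` and `rate`; `exp_mix_value()` evaluates it.
#' @export
reference_curve <- function(amplitude = 30, lambda_slow = 0.04, lambda_fast = 0.35) {
  stop_field(amplitude > 0, "amplitude", "must be > 0")
  stop_field(lambda_slow > 0 && lambda_fast > lambda_slow, "lambda_fast",
             "need 0 < lambda_slow < lambda_fast")
  exp_mix(c(amplitude, -amplitude), c(lambda_slow, lambda_fast))
}

exp_mix <- function(coef, rate) {
  stopifnot(length(coef) == length(rate), all(rate >= 0))
  structure(list(coef = coef, rate = rate), class = "exp_mix")
}

#' Evaluate an exponential mixture at time points
#' @param mix an `exp_mix` object.
#' @param t times (minutes).
#' @return `sum_i coef_i * exp(-rate_i * t)` at each `t`.
#' @keywords internal
#' @export
exp_mix_value <- function(mix, t) {
  drop(exp(-outer(t, mix$rate)) %*% mix$coef)
}

# exact frame averages of an exponential mixture over a schedule
exp_mix_frame_avg <- function(mix, schedule) {
  t0 <- schedule$start
  t1 <- schedule$start + schedule$duration
  avg <- numeric(nrow(schedule))
  for (k in seq_along(mix$coef)) {
    lam <- mix$rate[k]
    term <- if (lam < 1e-12) {
      rep(mix$coef[k], length(t0))
    } else {
      mix$coef[k] * (exp(-lam * t0) - exp(-lam * t1)) / (lam * (t1 - t0))
    }
    avg <- avg + term
  }
  avg
}

# SRTM solution as an exponential mixture, given a mixture reference input:
# C_T(t) = R1 C_ref(t) + (k2 - R1 k2a) [C_ref (*) exp(-k2a t)](t), k2a = k2 / dvr
srtm_mix <- function(ref_mix, dvr, r1, k2) {
  k2a <- k2 / dvr
  if (any(abs(k2a - ref_mix$rate) < 1e-9)) k2a <- k2a * (1 + 1e-7)
  conv_coef <- ref_mix$coef / (k2a - ref_mix$rate)
  gain <- k2 - r1 * k2a
  exp_mix(c(r1 * ref_mix$coef + gain * conv_coef, -gain * sum(conv_coef)),
          c(ref_mix$rate, k2a))
}

#' Simulate target and reference time-activity curves under SRTM
#'
#' Generates the reference curve and the simplified-reference-tissue-model
#' (SRTM) target curve for a given true distribution volume ratio, both in
#' closed form (the bolus reference is a sum of exponentials, so the SRTM
#' convolution is analytic). Frame values are the exact average activity
#' over each frame interval; optional Gaussian noise is scaled by
#' `1 / sqrt(duration)` so longer frames are less noisy. Negative noisy
#' activities are clipped at 0.
#'
#' @param dvr_true true distribution volume ratio (>= 1; `BP = dvr - 1`).
#' @param r1 SRTM delivery ratio `R1` (unitless).
#' @param k2 SRTM target-tissue clearance constant (1/min).
#' @param ref a [reference_curve()].
#' @param schedule a [frame_schedule()]; must extend past 18 min so the
#'   Logan window contains frames.
#' @param noise_sd noise SD as a fraction of the peak reference frame value
#'   (0 = noiseless).
#' @param seed integer seed for the noise.
#' @return A list with [tac()] elements `target` and `reference`.
#' @export
simulate_tac <- function(dvr_true, r1 = 1, k2 = 0.15, ref = reference_curve(),
                         schedule = pet_frame_schedule(), noise_sd = 0, seed = NULL) {
  stop_field(is.numeric(dvr_true) && length(dvr_true) == 1L && dvr_true >= 1,
             "dvr_true", "must be a single value >= 1")
  stop_field(r1 > 0, "r1", "must be > 0")
  stop_field(k2 > 0, "k2", "must be > 0")
  if (!inherits(schedule, "frame_schedule")) stop("`schedule` must be a frame_schedule", call. = FALSE)
  end <- max(schedule$start + schedule$duration)
  if (end <= 18) {
    stop("frame schedule must extend past the 18 min Logan window start", call. = FALSE)
  }
  ref_act <- exp_mix_frame_avg(ref, schedule)
  tgt_act <- exp_mix_frame_avg(srtm_mix(ref, dvr_true, r1, k2), schedule)
  if (noise_sd > 0) {
    scale <- noise_sd * max(ref_act)
    with_seed(seed, {
      w <- sqrt(mean(schedule$duration) / schedule$duration)
      ref_act <- pmax(ref_act + scale * w * stats::rnorm(nrow(schedule)), 0)
      tgt_act <- pmax(tgt_act + scale * w * stats::rnorm(nrow(schedule)), 0)
    })
  }
  list(target = tac(schedule, pmax(tgt_act, 0)),
       reference = tac(schedule, pmax(ref_act, 0)))
}
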