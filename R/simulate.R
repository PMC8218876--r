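#' Measurement model for synthetic experiments
#'
#' Bundles the instrument parameters of the synthetic-data generator: the
#' per-animal arbitrary-unit gain of the laser-Doppler probe, additive
#' Gaussian trace noise, the coefficient of variation of microsphere-derived
#' perfusion across animals, and the integer seed from which all randomness
#' flows.
#'
#' @param au_gain Arbitrary units per (ml/100 g/min); positive. Laser-Doppler
#'   flowmetry reports relative flow, so this gain differs between animals
#'   and cancels after calibration.
#' @param noise_sd_au Additive Gaussian noise SD on the arbitrary-unit scale
#'   (>= 0).
#' @param microsphere_cv Coefficient of variation of the lognormal dispersion
#'   of microsphere-derived flows across animals (>= 0).
#' @param seed Integer seed; identical seeds reproduce identical outputs.
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(au_gain = 1, noise_sd_au = 0,
                              microsphere_cv = 0, seed = 1L) {
  if (!is.numeric(au_gain) || au_gain <= 0)
    stop("`au_gain` must be positive")
  if (noise_sd_au < 0) stop("`noise_sd_au` must be >= 0")
  if (microsphere_cv < 0) stop("`microsphere_cv` must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer")
  structure(list(au_gain = au_gain, noise_sd_au = noise_sd_au,
                 microsphere_cv = microsphere_cv, seed = seed),
            class = "measurement_model")
}

#' Blood-pressure sweep protocol
#'
#' Describes how mean arterial pressure is swept during a flowmetry session:
#' the pressure range, the resting (baseline) pressure, the number of paired
#' samples, and the ordering. `descending_then_ascending` mimics a
#' phlebotomy-then-pressor session: pressures at or below baseline are
#' visited from baseline downwards, then the hypertensive pressures rising.
#'
#' @param bp_min,bp_max Sweep range (mmHg), defaults 40-190.
#' @param baseline_bp Resting pressure (mmHg), strictly inside the range.
#' @param n_points Number of samples (>= 2).
#' @param ordering `"descending_then_ascending"` or `"random"`.
#' @return An object of class `sweep_protocol`.
#' @export
sweep_protocol <- function(bp_min = 40, bp_max = 190, baseline_bp = 110,
                           n_points = 50,
                           ordering = c("descending_then_ascending",
                                        "random")) {
  ordering <- match.arg(ordering)
  if (!(bp_min < baseline_bp && baseline_bp < bp_max))
    stop("require bp_min < baseline_bp < bp_max")
  if (n_points < 2) stop("`n_points` must be >= 2")
  structure(list(bp_min = bp_min, bp_max = bp_max, baseline_bp = baseline_bp,
                 n_points = as.integer(n_points), ordering = ordering),
            class = "sweep_protocol")
}

# run code with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one laser-Doppler pressure-sweep trace
#'
#' Samples mean arterial pressure evenly across the protocol range (so the
#' trace spans `[bp_min, bp_max]` exactly), evaluates the true triphasic
#' model at each pressure, scales to arbitrary units by the animal's gain,
#' and adds Gaussian measurement noise. With `noise_sd_au = 0` every sample
#' lies exactly on `au_gain * evaluate_true_model(model, bp)`.
#'
#' @param model An [autoreg_model()].
#' @param meas A [measurement_model()]; its `seed` drives the noise and any
#'   random ordering.
#' @param protocol A [sweep_protocol()].
#' @param animal_id,group Identifiers attached to the returned trace.
#' @return A [flow_trace()] with `n_points` rows.
#' @export
simulate_trace <- function(model, meas, protocol,
                           animal_id = "sim1", group = "control") {
  stopifnot(inherits(model, "autoreg_model"),
            inherits(meas, "measurement_model"),
            inherits(protocol, "sweep_protocol"))
  bp <- seq(protocol$bp_min, protocol$bp_max,
            length.out = protocol$n_points)
  with_seed(meas$seed, {
    # visit hypotensive pressures from baseline downwards, then ascend
    idx <- if (protocol$ordering == "descending_then_ascending") {
      below <- which(bp <= protocol$baseline_bp)
      above <- which(bp > protocol$baseline_bp)
      c(below[order(bp[below], decreasing = TRUE)],
        above[order(bp[above])])
    } else {
      sample.int(length(bp))
    }
    bp <- bp[idx]
    cbf_true <- evaluate_true_model(model, bp)
    cbf_au <- meas$au_gain * cbf_true
    if (meas$noise_sd_au > 0)
      cbf_au <- cbf_au + stats::rnorm(length(bp), 0, meas$noise_sd_au)
    cbf_au <- pmax(cbf_au, 0)  # a flowmeter never reports negative flow
    flow_trace(animal_id = animal_id, group = group,
               map_mmHg = bp, cbf_au = cbf_au)
  })
}

#' Simulate a fluorescent-microsphere experiment
#'
#' Builds microsphere records whose fluorescence values are constructed by
#' inverting the blood-flow equation, so that [compute_blood_flow()] applied
#' to a noise-free record (`microsphere_cv = 0`) returns the generating true
#' flow exactly. With `microsphere_cv > 0` the per-animal flows are
#' lognormally dispersed around the truth with the stated coefficient of
#' variation (mean-preserving parameterisation), keeping flows strictly
#' positive.
#'
#' @param true_flows Named numeric vector of true tissue perfusion
#'   (ml/100 g/min), one element per tissue; must be non-empty and positive.
#' @param meas A [measurement_model()]; `microsphere_cv` and `seed` are used.
#' @param n_animals Number of animals (>= 1).
#' @param withdrawal_rate Reference blood withdrawal rate (ml/min).
#' @param tissue_weights Named numeric vector of tissue wet weights (mg),
#'   names matching `true_flows`.
#' @param group Group label attached to every record.
#' @param fluor_ref Reference-sample fluorescence intensity (a.u.); the
#'   tissue fluorescence is scaled against it.
#' @return A data frame of microsphere records with columns `animal_id`,
#'   `group`, `tissue`, `fluor_tissue`, `fluor_ref`,
#'   `withdrawal_rate_ml_min`, `tissue_weight_mg`.
#' @export
simulate_microsphere_experiment <- function(true_flows, meas, n_animals,
                                            withdrawal_rate,
                                            tissue_weights,
                                            group = "control",
                                            fluor_ref = 1000) {
  stopifnot(inherits(meas, "measurement_model"))
  if (length(true_flows) == 0)
    stop("`true_flows` must name at least one tissue")
  if (is.null(names(true_flows)) || any(!nzchar(names(true_flows))))
    stop("`true_flows` must be a named vector (tissue -> flow)")
  if (any(true_flows <= 0)) stop("true flows must be positive")
  if (withdrawal_rate <= 0) stop("`withdrawal_rate` must be positive (ml/min)")
  if (n_animals < 1) stop("`n_animals` must be >= 1")
  missing_w <- setdiff(names(true_flows), names(tissue_weights))
  if (length(missing_w))
    stop("missing tissue weights for: ", paste(missing_w, collapse = ", "))
  if (any(tissue_weights <= 0)) stop("tissue weights must be positive (mg)")

  tissues <- names(true_flows)
  with_seed(meas$seed, {
    rows <- expand.grid(tissue = tissues, animal = seq_len(n_animals),
                        stringsAsFactors = FALSE)
    flow <- true_flows[rows$tissue]
    if (meas$microsphere_cv > 0) {
      cv <- meas$microsphere_cv
      sdlog <- sqrt(log(1 + cv^2))
      flow <- stats::rlnorm(nrow(rows),
                            meanlog = log(flow) - sdlog^2 / 2,
                            sdlog = sdlog)
    }
    weight_g <- tissue_weights[rows$tissue] / 1000
    # invert: flow = (F_t / F_ref) * rate * 100 / weight_g
    ratio <- flow * weight_g / (100 * withdrawal_rate)
    data.frame(
      animal_id = sprintf("%s_%02d", group, rows$animal),
      group = group,
      tissue = rows$tissue,
      fluor_tissue = as.numeric(ratio * fluor_ref),
      fluor_ref = fluor_ref,
      withdrawal_rate_ml_min = withdrawal_rate,
      tissue_weight_mg = as.numeric(tissue_weights[rows$tissue]),
      stringsAsFactors = FALSE)
  })
}
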