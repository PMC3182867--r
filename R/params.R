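#' Individual motion parameters
#'
#' Run-and-tumble kinematics. An agent moves a fixed distance
#' `speed * time_step` every step and tumbles every `run_length` steps; the
#' tumble deflection is Gaussian with a variance that interpolates between
#' `tumble_sd_max^2` (no measured gain) and `tumble_sd_min^2` (strong gain)
#' through a logistic in the measured gradient:
#' \deqn{\sigma^2(g) = \sigma_{min}^2 +
#'   \frac{\sigma_{max}^2 - \sigma_{min}^2}{1 + e^{g / g_0}}.}
#' Heading noise of standard deviation `internal_noise_sd` is added on every
#' step.
#'
#' @param speed \eqn{v_0 > 0}, length/time.
#' @param time_step \eqn{dt > 0}, time.
#' @param run_length \eqn{\tau \ge 1}, integer steps between tumbles.
#' @param internal_noise_sd \eqn{\sigma_\eta \ge 0}, radians.
#' @param tumble_sd_min,tumble_sd_max Bounds of the tumble-angle standard
#'   deviation, radians; `0 < tumble_sd_min <= tumble_sd_max`.
#' @param gradient_scale \eqn{g_0 > 0}, concentration/length; sets how large a
#'   measured gradient must be before tumbles become directed.
#' @param gradient_mode How the tumble-bias gradient is measured. `"run"`
#'   (default): the concentration change accumulated since the agent's last
#'   tumble, per nominal run length `speed * time_step * run_length` — a
#'   fixed detection scale, so agents whose runs are short relative to the
#'   terrain relief cannot detect concentration changes, and agents with very
#'   long runs take large leaps; this is how swimming bacteria integrate
#'   attractant over a run. `"temporal"`: the concentration change over the
#'   last single step per unit path length. `"projected"`: the analytic
#'   spatial gradient projected onto the heading.
#' @param tumble_reference Reference direction a tumble deflects about:
#'   `"heading"` (default; the tumble overrides group influence for that
#'   step) or `"combined"` (the deflection is applied to the combined
#'   self/group direction, so neighbours still steer a tumbling agent).
#' @param tumble_phases `"staggered"` (default): tumble phases are randomised
#'   per agent at initialisation so the group does not reorient in lockstep;
#'   `"synchronous"`: all agents start at phase 0 and tumble together.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(speed = 0.1,
                          time_step = 1,
                          run_length = 5L,
                          internal_noise_sd = 0.1,
                          tumble_sd_min = 0.05,
                          tumble_sd_max = 2.5,
                          gradient_scale = 0.005,
                          gradient_mode = c("run", "temporal", "projected"),
                          tumble_reference = c("heading", "combined"),
                          tumble_phases = c("staggered", "synchronous")) {
  gradient_mode <- match.arg(gradient_mode)
  tumble_reference <- match.arg(tumble_reference)
  tumble_phases <- match.arg(tumble_phases)
  if (speed <= 0 || time_step <= 0 || gradient_scale <= 0)
    abort("speed, time_step and gradient_scale must be strictly positive",
          class = "swarmtaxis_config_error")
  if (run_length < 1 || run_length != round(run_length))
    abort("run_length must be a positive integer", class = "swarmtaxis_config_error")
  if (internal_noise_sd < 0)
    abort("internal_noise_sd must be non-negative", class = "swarmtaxis_config_error")
  if (tumble_sd_min <= 0 || tumble_sd_max < tumble_sd_min)
    abort("need 0 < tumble_sd_min <= tumble_sd_max", class = "swarmtaxis_config_error")
  structure(list(speed = speed, time_step = time_step,
                 run_length = as.integer(run_length),
                 internal_noise_sd = internal_noise_sd,
                 tumble_sd_min = tumble_sd_min, tumble_sd_max = tumble_sd_max,
                 gradient_scale = gradient_scale, gradient_mode = gradient_mode,
                 tumble_reference = tumble_reference,
                 tumble_phases = tumble_phases),
            class = "motion_params")
}

#' Zonal interaction radii
#'
#' Neighbours are classified into three half-open distance bands
#' (lower-inclusive): repulsion for `0 < d < repulsion`, velocity alignment
#' for `repulsion <= d < orientation`, attraction for
#' `orientation <= d < attraction`.
#'
#' @param repulsion,orientation,attraction Radii with
#'   `0 < repulsion < orientation < attraction`.
#' @param alignment_attraction_ratio Relative weight of the alignment term
#'   against the attraction term when both bands are occupied (default 1:
#'   equal unit weights).
#' @return An object of class `interaction_zones`.
#' @export
interaction_zones <- function(repulsion = 0.75, orientation = 4.5, attraction = 8,
                              alignment_attraction_ratio = 1) {
  if (!(repulsion > 0 && repulsion < orientation && orientation < attraction))
    abort("need 0 < repulsion < orientation < attraction",
          class = "swarmtaxis_config_error")
  if (alignment_attraction_ratio < 0)
    abort("alignment_attraction_ratio must be non-negative",
          class = "swarmtaxis_config_error")
  structure(list(repulsion = repulsion, orientation = orientation,
                 attraction = attraction,
                 alignment_attraction_ratio = alignment_attraction_ratio),
            class = "interaction_zones")
}

#' Interaction-weight policy
#'
#' The weight \eqn{w \in [0, 1]} mixes an agent's own heading with the
#' group-derived direction: the combined direction is
#' \eqn{w\,\hat u(\theta) + (1 - w)\,d_{group}}. Three policies:
#' * `independent` — no interactions at all (group direction is never used);
#' * `fixed` — constant weight `fixed_w` for all agents at all times;
#' * `adaptive` — a hard-limit two-state rule: after a step in which an
#'   agent's measured concentration increased it sets `w = w_high` (trust its
#'   own direction more), otherwise `w = w_low` (follow the group).
#'
#' @param mode One of `"adaptive"`, `"fixed"`, `"independent"`.
#' @param fixed_w Constant weight for the fixed policy.
#' @param w_low,w_high Two-state levels for the adaptive policy
#'   (`0 <= w_low < w_high <= 1`).
#' @param initial_w Weight assigned at initialisation; defaults to `fixed_w`
#'   (fixed), `w_high` (adaptive) or 1 (independent).
#' @return An object of class `weight_policy`.
#' @export
weight_policy <- function(mode = c("adaptive", "fixed", "independent"),
                          fixed_w = 0.5, w_low = 0, w_high = 0.5,
                          initial_w = NULL) {
  mode <- match.arg(mode)
  if (fixed_w < 0 || fixed_w > 1)
    abort("fixed_w must be in [0, 1]", class = "swarmtaxis_config_error")
  if (!(w_low >= 0 && w_low < w_high && w_high <= 1))
    abort("need 0 <= w_low < w_high <= 1", class = "swarmtaxis_config_error")
  if (is.null(initial_w))
    initial_w <- switch(mode, fixed = fixed_w, adaptive = w_high, independent = 1)
  if (initial_w < 0 || initial_w > 1)
    abort("initial_w must be in [0, 1]", class = "swarmtaxis_config_error")
  structure(list(mode = mode, fixed_w = fixed_w, w_low = w_low,
                 w_high = w_high, initial_w = initial_w),
            class = "weight_policy")
}
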