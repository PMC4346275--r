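#' Occluder geometry
#'
#' Describes the spatial window (in normalised amplitude units, target
#' amplitude = 1) within which a location is invisible. `softness = 0` gives a
#' hard window; `softness > 0` smooths each edge with a logistic of that
#' length-scale so that visibility is differentiable (needed by the
#' gradient-based inference engine).
#'
#' The default window `[-0.8, 0]` places the occluder between the midline and
#' the furthest 10% of the path from a trial that starts at +1; flip signs for
#' trials starting at -1.
#'
#' @param lower,upper Window edges in amplitude units (`lower < upper`).
#' @param softness Edge-smoothing length scale, amplitude units (>= 0).
#' @return An object of class `occluder_geometry`.
#' @examples
#' geom <- occluder_geometry(0, 0.8)
#' occluder_visibility(c(-0.5, 0.4, 0.9), geom)
#' @export
occluder_geometry <- function(lower = -0.8, upper = 0, softness = 0) {
  stopifnot(is.numeric(lower), is.numeric(upper), is.numeric(softness),
            length(lower) == 1, length(upper) == 1, length(softness) == 1,
            is.finite(lower), is.finite(upper), is.finite(softness))
  if (lower >= upper) stop("`lower` must be strictly below `upper`")
  if (softness < 0) stop("`softness` must be >= 0")
  structure(list(lower = lower, upper = upper, softness = softness),
            class = "occluder_geometry")
}

#' Visibility of a location given an occluder
#'
#' Returns O(x) in \[0, 1\]: 0 inside the occluder window, 1 outside (hard
#' window when `softness = 0`). With `softness > 0` the window is the product
#' of two logistic edges, monotone in the distance from the window.
#'
#' @param x Location(s), amplitude units.
#' @param geom An [occluder_geometry()].
#' @return Numeric vector of visibilities in \[0, 1\].
#' @export
occluder_visibility <- function(x, geom = occluder_geometry()) {
  stopifnot(inherits(geom, "occluder_geometry"), is.numeric(x))
  if (any(!is.finite(x))) stop("`x` must be finite")
  if (geom$softness == 0) {
    as.numeric(x < geom$lower | x > geom$upper)
  } else {
    # occlusion = product of two logistic edges; visibility is its complement
    occl <- stats::plogis((x - geom$lower) / geom$softness) *
      stats::plogis((geom$upper - x) / geom$softness)
    1 - occl
  }
}

#' Joint visibility of attractor and target
#'
#' Visibility of the inclusive disjunction of the attracting location `v` and
#' the target location `xt`: 1 if either is visible. Using the disjunction in
#' the kinetic couplings means changes in coupling anticipate the emergence of
#' the target from the occluder, because the attracting location leads it.
#'
#' @param v Attracting-location position(s), amplitude units.
#' @param xt Target position(s), amplitude units.
#' @inheritParams occluder_visibility
#' @return Numeric vector, `pmax(O(v), O(xt))`.
#' @export
joint_visibility <- function(v, xt, geom = occluder_geometry()) {
  pmax(occluder_visibility(v, geom), occluder_visibility(xt, geom))
}

#' Sensory geometry of the visual channel array
#'
#' An odd number of Gaussian receptive fields centred on `channel_centres`
#' (amplitude units, centre of gaze at 0), each of width `field_width`.
#' Defaults: 17 channels at -8..8, width 1.
#'
#' @param channel_centres Strictly increasing numeric vector with a centre at
#'   0 and an odd count.
#' @param field_width Receptive-field width, amplitude units.
#' @return An object of class `sensory_geometry`.
#' @export
sensory_geometry <- function(channel_centres = -8:8, field_width = 1) {
  stopifnot(is.numeric(channel_centres), all(is.finite(channel_centres)),
            all(diff(channel_centres) > 0))
  if (length(channel_centres) %% 2 != 1 || !any(channel_centres == 0))
    stop("`channel_centres` must have an odd count with a centre at 0")
  stopifnot(is.numeric(field_width), field_width > 0)
  structure(list(channel_centres = as.numeric(channel_centres),
                 field_width = field_width),
            class = "sensory_geometry")
}

#' Kinetic coupling / viscosity parameters
#'
#' theta1/theta4: occluder-independent and -dependent attraction of gaze to the
#' invisible attracting location; theta3/theta5: same for the target;
#' theta2/theta6: viscosity of eye and target motion (fixed across
#' experimental conditions). Defaults are the prior expectations
#' (1/4, 1/2, 1/2, 1/32, 1/32, 1/4).
#'
#' @param theta1,theta2,theta3,theta4,theta5,theta6 Dimensionless coefficients.
#' @return Object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(theta1 = 1 / 4, theta2 = 1 / 2, theta3 = 1 / 2,
                               theta4 = 1 / 32, theta5 = 1 / 32,
                               theta6 = 1 / 4) {
  th <- c(theta1 = theta1, theta2 = theta2, theta3 = theta3,
          theta4 = theta4, theta5 = theta5, theta6 = theta6)
  stopifnot(all(is.finite(th)))
  structure(as.list(th), class = "kinetic_parameters")
}

#' Prior beliefs about the attracting location
#'
#' The subject believes a fictive location v(t) = amplitude * cos(2*pi*t +
#' phase_lead) attracts the target (and gaze); `t` is in cycle fractions.
#' `phase_lead` > 0 puts the attractor ahead of the target, which is what
#' licenses anticipatory pursuit through occlusion. Both are positive and are
#' estimated on a log scale by the DCM.
#'
#' @param amplitude Amplitude units (> 0); prior expectation 1.
#' @param phase_lead Radians (> 0); prior expectation 2*pi/32.
#' @return Object of class `prior_belief_parameters`.
#' @export
prior_belief_parameters <- function(amplitude = 1, phase_lead = 2 * pi / 32) {
  stopifnot(is.finite(amplitude), amplitude > 0,
            is.finite(phase_lead), phase_lead > 0)
  structure(list(amplitude = amplitude, phase_lead = phase_lead),
            class = "prior_belief_parameters")
}

#' Subjective log precisions
#'
#' Natural-log precisions of the random fluctuations assumed by the subject's
#' generative model: sensory input, motion of hidden states, and the hidden
#' cause. A log precision of 4 implies a standard deviation exp(-2) = 0.135
#' amplitude units (see [precision_sd()]).
#'
#' @param log_prec_sensory,log_prec_states,log_prec_cause Log precisions.
#' @return Object of class `precision_parameters`.
#' @export
precision_parameters <- function(log_prec_sensory = 4, log_prec_states = 4,
                                 log_prec_cause = 4) {
  p <- list(log_prec_sensory = log_prec_sensory,
            log_prec_states = log_prec_states,
            log_prec_cause = log_prec_cause)
  stopifnot(all(vapply(p, is.finite, logical(1))))
  structure(p, class = "precision_parameters")
}

#' Standard deviation implied by a log precision
#'
#' @param log_prec Natural-log precision(s).
#' @return `exp(-log_prec / 2)`.
#' @examples
#' precision_sd(4) # 0.135
#' @export
precision_sd <- function(log_prec) exp(-log_prec / 2)

#' Full subjective parameter set
#'
#' Bundles kinetic, prior-belief and precision parameters. Serialises to and
#' from a flat named vector with fixed order theta1..theta8, lnPi_s, lnPi_x,
#' lnPi_v via [as_param_vector()] / [param_set_from_vector()]. The default is
#' the prior expectation of every parameter.
#'
#' @param kinetic A [kinetic_parameters()].
#' @param prior_beliefs A [prior_belief_parameters()].
#' @param precisions A [precision_parameters()].
#' @return Object of class `full_parameter_set`.
#' @export
full_parameter_set <- function(kinetic = kinetic_parameters(),
                               prior_beliefs = prior_belief_parameters(),
                               precisions = precision_parameters()) {
  stopifnot(inherits(kinetic, "kinetic_parameters"),
            inherits(prior_beliefs, "prior_belief_parameters"),
            inherits(precisions, "precision_parameters"))
  structure(list(kinetic = kinetic, prior_beliefs = prior_beliefs,
                 precisions = precisions),
            class = "full_parameter_set")
}

#' @rdname full_parameter_set
#' @param p A `full_parameter_set`.
#' @export
as_param_vector <- function(p) {
  stopifnot(inherits(p, "full_parameter_set"))
  c(theta1 = p$kinetic$theta1, theta2 = p$kinetic$theta2,
    theta3 = p$kinetic$theta3, theta4 = p$kinetic$theta4,
    theta5 = p$kinetic$theta5, theta6 = p$kinetic$theta6,
    theta7 = p$prior_beliefs$amplitude, theta8 = p$prior_beliefs$phase_lead,
    lnPi_s = p$precisions$log_prec_sensory,
    lnPi_x = p$precisions$log_prec_states,
    lnPi_v = p$precisions$log_prec_cause)
}

#' @rdname full_parameter_set
#' @param v Named (or correctly ordered) numeric vector of length 11.
#' @export
param_set_from_vector <- function(v) {
  stopifnot(is.numeric(v), length(v) == 11)
  nm <- param_names()
  if (!is.null(names(v))) v <- v[nm]
  full_parameter_set(
    kinetic = kinetic_parameters(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]], v[[6]]),
    prior_beliefs = prior_belief_parameters(v[[7]], v[[8]]),
    precisions = precision_parameters(v[[9]], v[[10]], v[[11]])
  )
}

#' Canonical parameter names
#' @return Character vector: theta1..theta8, lnPi_s, lnPi_x, lnPi_v.
#' @export
param_names <- function() {
  c(paste0("theta", 1:8), "lnPi_s", "lnPi_x", "lnPi_v")
}

#' Occlusion-dependent coupling strengths
#'
#' kappa_v = theta1 - theta4 * O and kappa_t = theta3 + theta5 * O, with O the
#' joint visibility of attractor and target. Under the default priors the pull
#' towards the attracting location is stronger when occluded and the pull
#' towards the target is stronger when visible.
#'
#' @param vis Visibility in \[0, 1\].
#' @param k A [kinetic_parameters()].
#' @return List with `kappa_v` and `kappa_t` (vectorised over `vis`).
#' @export
coupling_strengths <- function(vis, k = kinetic_parameters()) {
  stopifnot(inherits(k, "kinetic_parameters"), is.numeric(vis),
            all(vis >= 0 & vis <= 1))
  list(kappa_v = k$theta1 - k$theta4 * vis,
       kappa_t = k$theta3 + k$theta5 * vis)
}

#' Sensory mapping of the pursuit model
#'
#' Maps eye position `xo` and target position `xt` to the two sensory
#' modalities: proprioception (the oculomotor angle itself) and an array of
#' visual channels with Gaussian receptive fields in retinal coordinates,
#' gated by the visibility of the target:
#' channel i = O(xt) * exp(-((r_i + xo - xt) / w)^2).
#'
#' @param xo Eye position, amplitude units.
#' @param xt Target position, amplitude units.
#' @param sg A [sensory_geometry()].
#' @inheritParams occluder_visibility
#' @return List with `proprio` (scalar) and `visual` (one value per channel).
#' @export
sensory_prediction <- function(xo, xt, sg = sensory_geometry(),
                               geom = occluder_geometry()) {
  stopifnot(is.finite(xo), is.finite(xt), inherits(sg, "sensory_geometry"))
  o <- occluder_visibility(xt, geom)
  z <- (sg$channel_centres + xo - xt) / sg$field_width
  list(proprio = xo, visual = o * exp(-z^2))
}

#' Equations of motion of the subjective model's hidden states
#'
#' Hidden states are (eye position, eye velocity, target position, target
#' velocity). Eye acceleration is a visibility-weighted pull towards the
#' attracting location and the target minus viscous drag; target acceleration
#' is a pull of fixed gain 1/4 towards the attracting location minus viscous
#' drag. Time is measured in integration bins.
#'
#' @param x Numeric length-4 state `(eye_pos, eye_vel, target_pos, target_vel)`.
#' @param v Attracting-location position, amplitude units.
#' @param p A [full_parameter_set()].
#' @inheritParams occluder_visibility
#' @return Numeric length-4 time derivative.
#' @export
model_flow <- function(x, v, p = full_parameter_set(),
                       geom = occluder_geometry()) {
  stopifnot(inherits(p, "full_parameter_set"), length(x) == 4,
            all(is.finite(x)), is.finite(v))
  k <- p$kinetic
  vis <- joint_visibility(v, x[3], geom)
  kap <- coupling_strengths(vis, k)
  c(x[2],
    kap$kappa_v * (v - x[1]) + kap$kappa_t * (x[3] - x[1]) - k$theta2 * x[2],
    x[4],
    (v - x[3]) / 4 - k$theta6 * x[4])
}

#' Deterministic trajectory of the attracting location
#'
#' v(t) = amplitude * cos(2*pi*t + phase_lead), with `t` in cycle fractions.
#'
#' @param t Time(s) in cycle fractions (>= 0).
#' @param pb A [prior_belief_parameters()].
#' @return Attracting-location position(s), amplitude units.
#' @export
attractor_prior <- function(t, pb = prior_belief_parameters()) {
  stopifnot(inherits(pb, "prior_belief_parameters"), all(t >= 0))
  pb$amplitude * cos(2 * pi * t + pb$phase_lead)
}

#' Oculomotor plant dynamics (generative process)
#'
#' The real eye: position integrates velocity; velocity is driven by action and
#' decays with a time constant of one integration bin.
#'
#' @param eye Numeric length-2 `(eye_pos, eye_vel)`.
#' @param a Action (force on the oculomotor plant).
#' @return Numeric length-2 derivative `(eye_vel, a - eye_vel)`.
#' @export
process_flow <- function(eye, a) {
  stopifnot(length(eye) == 2, all(is.finite(eye)), is.finite(a))
  c(eye[2], a - eye[2])
}
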