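# Toy reproduction of the orientation-steering protocol: a rigid helix
# driven by a moving harmonic orientation restraint over a pull phase
# (default 20 ns), then released for a relaxation phase (default 70 ns).
# The restraint is harmonic in the relative rotation angle,
# U = 1/2 k theta_dev^2, consistent with the printed force-constant
# conversion 5000 kcal/(mol rad^2) ~ 1.52 kcal/(mol deg^2), and the
# dynamics is a single-angle overdamped Langevin process along the geodesic
# toward the moving target.

#' Steering schedule for the toy pull/relax protocol
#'
#' @param q_target target orientation as a [unit_quaternion()], or a single
#'   target angle in degrees (rotated about a fixed default axis).
#' @param pull_ns duration of the pulling phase (default 20 ns): the target
#'   orientation ramps linearly in angle from identity to `q_target`.
#' @param relax_ns duration of the restraint-free relaxation (default 70 ns).
#' @param dt_ns integration time step (default 0.01 ns).
#' @return object of class `steering_schedule`.
#' @export
steering_schedule <- function(q_target, pull_ns = 20, relax_ns = 70,
                              dt_ns = 0.01) {
  if (is.numeric(q_target) && length(q_target) == 1L)
    q_target <- axis_angle_quaternion(q_target, c(0, 0, 1))
  q_target <- unit_quaternion(q_target)
  if (pull_ns <= 0 || relax_ns < 0 || dt_ns <= 0)
    stop("durations must be positive (relax may be zero)")
  structure(list(q_target = q_target,
                 target_angle = quaternion_angle(q_target),
                 pull_ns = pull_ns, relax_ns = relax_ns, dt_ns = dt_ns),
            class = "steering_schedule")
}

#' Target angle of the moving restraint at time t
#'
#' Linear ramp over the pull phase, held at the final target afterwards.
#'
#' @param schedule a [steering_schedule()].
#' @param t time in ns (vectorized).
#' @return target angle(s) in degrees.
#' @export
schedule_target_angle <- function(schedule, t) {
  schedule$target_angle * pmin(pmax(t, 0) / schedule$pull_ns, 1)
}

#' Harmonic orientation-restraint energy
#'
#' `U = 1/2 k theta_dev^2` with `theta_dev` the rotation angle of the
#' relative quaternion between current and target orientations.
#'
#' @param q_current,q_target [unit_quaternion()] orientations.
#' @param k force constant in kcal/(mol deg^2); the engine value
#'   5000 kcal/(mol rad^2) corresponds to about 1.52 kcal/(mol deg^2).
#' @return energy in kcal/mol.
#' @export
restraint_energy <- function(q_current, q_target,
                             k = 5000 * (pi / 180)^2) {
  if (k < 0) stop("force constant must be non-negative")
  dev <- quaternion_angle(quat_multiply(unit_quaternion(q_target),
                                        quat_conjugate(unit_quaternion(q_current))))
  0.5 * k * dev^2
}

#' Simulate the pull/relax protocol for a rigid helix orientation
#'
#' Overdamped rotational Brownian dynamics on the restraint's angle
#' coordinate: during the pull phase
#' `d theta = (k / friction) (theta_target(t) - theta) dt + sqrt(2 D dt) xi`,
#' and during the relaxation phase the force term is dropped (free diffusion).
#' At zero diffusion the process has a closed-form steady tracking lag
#' `friction * v / k` behind a ramp of velocity `v`.
#'
#' @param schedule a [steering_schedule()].
#' @param k force constant, kcal/(mol deg^2).
#' @param friction rotational friction, kcal ns/(mol deg^2).
#' @param diffusion angular diffusivity D in deg^2/ns (0 = deterministic).
#' @param seed integer RNG seed; identical seeds give bitwise-identical
#'   series.
#' @return data.frame with columns `time` (ns), `theta` (deg, angle from the
#'   start orientation), `theta_dev` (deg, deviation from the moving target;
#'   NA during the relaxation phase), `phase` ("pull"/"relax").
#' @export
simulate_pull <- function(schedule, k = 5000 * (pi / 180)^2,
                          friction = 0.05, diffusion = 0, seed = 1) {
  stopifnot(inherits(schedule, "steering_schedule"))
  if (friction <= 0) stop("friction must be positive")
  if (k < 0) stop("force constant must be non-negative")
  dt <- schedule$dt_ns
  if (k * dt / friction > 0.5)
    stop("unstable integration: k * dt / friction = ",
         format(k * dt / friction), " > 0.5; reduce dt or stiffness")
  times <- seq(0, schedule$pull_ns + schedule$relax_ns, by = dt)
  n <- length(times)
  theta <- numeric(n)
  target <- schedule_target_angle(schedule, times)
  in_pull <- times <= schedule$pull_ns
  with_seed(seed, {
    noise <- if (diffusion > 0) stats::rnorm(n - 1, 0, sqrt(2 * diffusion * dt))
             else numeric(n - 1)
    for (i in seq_len(n - 1)) {
      drift <- if (in_pull[i]) (k / friction) * (target[i] - theta[i]) * dt else 0
      theta[i + 1] <- theta[i] + drift + noise[i]
    }
  })
  data.frame(time = times, theta = theta,
             theta_dev = ifelse(in_pull, target - theta, NA_real_),
             phase = ifelse(in_pull, "pull", "relax"))
}
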