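#' Integration run settings
#'
#' Settings for a fixed-step integration measured in forcing periods.
#' The step `dt` must divide the forcing period `2 / omega` exactly so
#' that stroboscopic samples fall on grid points; this is validated
#' against the forcing at run time.
#'
#' Defaults: `dt = 0.001` (2000 steps per period at `omega = 1`),
#' 500 transient periods discarded, 200 periods recorded, initial state
#' `(0.1, 0.1)`. Long transients matter near period-doubling points,
#' where settling is slow; a two-dimensional system makes them cheap.
#'
#' @param dt Integration step (time units), positive.
#' @param t0 Start time.
#' @param transient_periods Whole forcing periods discarded before
#'   recording (integer, >= 0).
#' @param record_periods Whole forcing periods recorded (integer, >= 1).
#' @param initial_state Numeric length-2 `c(R, J)`.
#' @param overflow_guard Integration aborts with an error if `|R|` or
#'   `|J|` exceeds this bound; the model is bounded in the regimes of
#'   interest, so divergence signals a mis-set parameter.
#' @return An object of class `run_settings`.
#' @export
run_settings <- function(dt = 0.001, t0 = 0, transient_periods = 500L,
                         record_periods = 200L,
                         initial_state = c(0.1, 0.1),
                         overflow_guard = 1e6) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a finite numeric scalar > 0")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("'t0' must be a finite numeric scalar")
  transient_periods <- as.integer(transient_periods)
  record_periods <- as.integer(record_periods)
  if (is.na(transient_periods) || transient_periods < 0L)
    stop("'transient_periods' must be an integer >= 0")
  if (is.na(record_periods) || record_periods < 1L)
    stop("'record_periods' must be an integer >= 1")
  if (!is.numeric(initial_state) || length(initial_state) != 2L ||
      any(!is.finite(initial_state)))
    stop("'initial_state' must be a finite numeric vector c(R, J)")
  if (!is.numeric(overflow_guard) || overflow_guard <= 0)
    stop("'overflow_guard' must be > 0")
  structure(list(dt = dt, t0 = t0,
                 transient_periods = transient_periods,
                 record_periods = record_periods,
                 initial_state = as.numeric(initial_state),
                 overflow_guard = overflow_guard),
            class = "run_settings")
}

# steps per forcing period; errors unless dt divides the period exactly
steps_per_period <- function(f, s) {
  period <- forcing_period(f)
  spp <- round(period / s$dt)
  if (spp < 1 || abs(spp * s$dt - period) > 1e-9 * period)
    stop("forcing period ", period, " must be an integer multiple of dt = ",
         s$dt, " (exact strobing)")
  as.integer(spp)
}

target_code <- function(target) {
  match(target, c("romeo", "juliet", "both")) - 1L
}

#' Integrate the forced love model
#'
#' Classical fixed-step 4th-order Runge-Kutta applied to the model's
#' vector field. The first `transient_periods` forcing periods are
#' discarded; the following `record_periods` periods are returned,
#' sampled at every step. Runs are deterministic: identical inputs give
#' bit-identical outputs.
#'
#' @param p A [love_params()] object.
#' @param f A [forcing_spec()] object.
#' @param s A [run_settings()] object.
#' @return An object of class `love_trajectory`: a list with `times`,
#'   `R`, `J` (equal-length numeric vectors, constant spacing `dt`) and
#'   the `settings`, `params`, `forcing` used.
#' @examples
#' traj <- integrate_love(love_params(a = -5.41), scenario("P_eq_N"),
#'                        run_settings(transient_periods = 50L,
#'                                     record_periods = 10L))
#' range(traj$R)
#' @export
integrate_love <- function(p, f, s = run_settings()) {
  stopifnot(inherits(p, "love_params"), inherits(f, "forcing_spec"),
            inherits(s, "run_settings"))
  spp <- steps_per_period(f, s)
  res <- .rk4_integrate_cpp(p$a, p$b, p$c, p$d, f$A, f$B, f$omega,
                            target_code(f$target),
                            s$initial_state[1], s$initial_state[2],
                            s$t0, s$dt,
                            as.numeric(s$transient_periods) * spp,
                            as.numeric(s$record_periods) * spp,
                            s$overflow_guard)
  structure(list(times = res$times, R = res$R, J = res$J,
                 settings = s, params = p, forcing = f),
            class = "love_trajectory")
}

#' @export
print.love_trajectory <- function(x, ...) {
  cat(sprintf("love model trajectory: %d samples, t in [%g, %g], dt = %g\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$settings$dt))
  cat(sprintf("  R in [%.4g, %.4g], J in [%.4g, %.4g]\n",
              min(x$R), max(x$R), min(x$J), max(x$J)))
  invisible(x)
}

#' @export
plot.love_trajectory <- function(x, which = c("phase", "series"), ...) {
  which <- match.arg(which)
  if (which == "phase") {
    graphics::plot(x$R, x$J, type = "l", xlab = "R", ylab = "J",
                   main = "phase portrait", ...)
  } else {
    graphics::plot(x$times, x$R, type = "l", xlab = "t", ylab = "level",
                   main = "time series", ...)
    graphics::lines(x$times, x$J, col = 2)
    graphics::legend("topright", legend = c("R", "J"), col = 1:2, lty = 1)
  }
  invisible(x)
}

#' Stroboscopic Poincare section of a trajectory
#'
#' Samples the recorded trajectory once per forcing period, at times
#' `t_start + phase + k * period` for `k = 0, ..., record_periods - 1`.
#' A period-n orbit yields n distinct strobe points.
#'
#' @param traj A [integrate_love()] trajectory.
#' @param phase Strobe phase offset in `[0, period)`; must be an integer
#'   multiple of `dt`.
#' @return An object of class `poincare_section` with fields `k`
#'   (strobe index), `t`, `R`, `J`, `period_of_strobe`, `phase`.
#' @export
strobe <- function(traj, phase = 0) {
  stopifnot(inherits(traj, "love_trajectory"))
  s <- traj$settings
  spp <- steps_per_period(traj$forcing, s)
  period <- forcing_period(traj$forcing)
  if (!is.numeric(phase) || length(phase) != 1L || !is.finite(phase) ||
      phase < 0 || phase >= period)
    stop("'phase' must lie in [0, period)")
  off <- round(phase / s$dt)
  if (abs(off * s$dt - phase) > 1e-9 * max(phase, s$dt))
    stop("'phase' must be an integer multiple of dt")
  n <- s$record_periods
  if (n < 1L) stop("empty recording window")
  idx <- off + (0:(n - 1L)) * spp + 1L
  structure(list(k = 0:(n - 1L), t = traj$times[idx],
                 R = traj$R[idx], J = traj$J[idx],
                 period_of_strobe = period, phase = phase),
            class = "poincare_section")
}

#' @export
print.poincare_section <- function(x, ...) {
  cat(sprintf("Poincare section: %d strobe points (period %g, phase %g)\n",
              length(x$k), x$period_of_strobe, x$phase))
  invisible(x)
}

#' @export
plot.poincare_section <- function(x, ...) {
  graphics::plot(x$R, x$J, pch = 20, xlab = "R", ylab = "J",
                 main = "Poincare map", ...)
  invisible(x)
}

#' Trajectory and Poincare-section CSV round trip
#'
#' `write_trajectory()` writes `t,R,J` rows at full double precision
#' (17 significant digits, enough for exact round trip);
#' `read_trajectory()` reads them back. `write_section()` writes a
#' Poincare section as `k,t,R,J`.
#'
#' @param traj A trajectory from [integrate_love()].
#' @param path File path.
#' @return `read_trajectory()` returns a data.frame with columns
#'   `t`, `R`, `J`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "love_trajectory"))
  df <- data.frame(t = sprintf("%.17g", traj$times),
                   R = sprintf("%.17g", traj$R),
                   J = sprintf("%.17g", traj$J))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' @rdname write_trajectory
#' @param sec A [strobe()] section.
#' @export
write_section <- function(sec, path) {
  stopifnot(inherits(sec, "poincare_section"))
  df <- data.frame(k = sec$k,
                   t = sprintf("%.17g", sec$t),
                   R = sprintf("%.17g", sec$R),
                   J = sprintf("%.17g", sec$J))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
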