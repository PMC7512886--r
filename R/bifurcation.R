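#' Default parameter grid for bifurcation sweeps
#'
#' 400 uniform points on `[-6, -2.01]`: inside the saddle region
#' `a < -2` (with `b = -2`, `c = 1`, `d = 1`) and fine enough to
#' resolve the period-doubling cascade.
#'
#' @return Increasing numeric vector.
#' @export
default_a_grid <- function() seq(-6, -2.01, length.out = 400)

#' Bifurcation sweep over the self-feeling coefficient a
#'
#' For each value of `a` (ascending) integrates the model, strobes the
#' trajectory, detects the orbit period, and estimates the maximal
#' Lyapunov exponent. With `continuation = TRUE` (the default, and
#' usual bifurcation-diagram practice) the final state at one grid
#' point seeds the initial state at the next, shortening transients
#' and following the attractor branch. A diverging grid point is
#' recorded as missing (`NA` section/exponent), not fatal; the next
#' point restarts from the settings' initial state.
#'
#' @param a_grid Sorted increasing numeric vector of `a` values.
#' @param f A [forcing_spec()], typically from [scenario()].
#' @param s A [run_settings()]. The sweep default uses shorter
#'   transients than a standalone run because continuation keeps the
#'   state near the attractor.
#' @param p_base Base parameters supplying `b`, `c`, `d`.
#' @param continuation Seed each grid point with the previous final
#'   state.
#' @param lyap_periods Accumulation length for the per-point exponent.
#' @param rel_tol Clustering tolerance for period detection.
#' @return An object of class `bifurcation_scan`: `a_values`,
#'   `sections` (list of [strobe()] sections, `NULL` where diverged),
#'   `periods` (integer, `NA` = aperiodic/unresolved/diverged),
#'   `lyapunovs`, `scenario`, `settings`, `continuation`.
#' @export
sweep_bifurcation <- function(a_grid, f = scenario("P_eq_N"),
                              s = run_settings(transient_periods = 200L,
                                               record_periods = 100L),
                              p_base = love_params(),
                              continuation = TRUE,
                              lyap_periods = 400L,
                              rel_tol = 1e-3) {
  stopifnot(inherits(f, "forcing_spec"), inherits(s, "run_settings"),
            inherits(p_base, "love_params"))
  if (!is.numeric(a_grid) || length(a_grid) == 0L || is.unsorted(a_grid))
    stop("'a_grid' must be a nonempty increasing numeric vector")
  n <- length(a_grid)
  sections <- vector("list", n)
  periods <- rep(NA_integer_, n)
  lyapunovs <- rep(NA_real_, n)
  state <- s$initial_state
  for (i in seq_len(n)) {
    p <- love_params(a = a_grid[i], b = p_base$b, c = p_base$c, d = p_base$d)
    si <- s
    si$initial_state <- state
    ok <- tryCatch({
      traj <- integrate_love(p, f, si)
      sec <- strobe(traj)
      sections[[i]] <- sec
      periods[i] <- suppressWarnings(detect_period(sec, rel_tol = rel_tol))
      lyapunovs[i] <- max_lyapunov(p, f, si, n_periods = lyap_periods)$value
      if (continuation)
        state <- c(traj$R[length(traj$R)], traj$J[length(traj$J)])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) state <- s$initial_state  # restart after divergence
  }
  structure(list(a_values = a_grid, sections = sections, periods = periods,
                 lyapunovs = lyapunovs, scenario = f, settings = s,
                 continuation = continuation),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  np <- sum(!is.na(x$periods))
  cat(sprintf("bifurcation scan: %d values of a in [%g, %g]\n",
              length(x$a_values), min(x$a_values), max(x$a_values)))
  cat(sprintf("  %d periodic points, %d aperiodic/unresolved; lambda in [%.4g, %.4g]\n",
              np, length(x$a_values) - np,
              min(x$lyapunovs, na.rm = TRUE), max(x$lyapunovs, na.rm = TRUE)))
  invisible(x)
}

#' Long-format view of a bifurcation scan
#'
#' One row per strobe point: columns `a`, `k`, `R`, `J`, `lambda`.
#'
#' @param x A [sweep_bifurcation()] scan.
#' @param ... Unused.
#' @export
as.data.frame.bifurcation_scan <- function(x, ...) {
  rows <- lapply(seq_along(x$a_values), function(i) {
    sec <- x$sections[[i]]
    if (is.null(sec)) return(NULL)
    data.frame(a = x$a_values[i], k = sec$k, R = sec$R, J = sec$J,
               lambda = x$lyapunovs[i])
  })
  do.call(rbind, rows)
}

#' @rdname as.data.frame.bifurcation_scan
#' @param scan A scan object.
#' @param path Output CSV path.
#' @export
write_scan <- function(scan, path) {
  df <- as.data.frame(scan)
  df$R <- sprintf("%.17g", df$R)
  df$J <- sprintf("%.17g", df$J)
  df$lambda <- sprintf("%.17g", df$lambda)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.bifurcation_scan <- function(x, ordinate = c("R", "J"), ...) {
  ordinate <- match.arg(ordinate)
  df <- as.data.frame(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(df$a, df[[ordinate]], pch = ".", xlab = "a",
                 ylab = paste("strobed", ordinate),
                 main = "bifurcation diagram", ...)
  graphics::plot(x$a_values, x$lyapunovs, type = "l", xlab = "a",
                 ylab = expression(lambda), main = "maximal Lyapunov exponent")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Locate period-doubling transitions in a sweep
#'
#' Scans consecutive grid intervals for changes of the detected period
#' from n to 2n (the doubling cascade) and for entries into the
#' aperiodic regime (period n to aperiodic, reported with
#' `period_after = NA`).
#'
#' @param scan A [sweep_bifurcation()] scan, or any list with numeric
#'   `a_values` and integer `periods` (NA = aperiodic).
#' @return A data.frame with columns `a_lo`, `a_hi`, `period_before`,
#'   `period_after`; zero rows when no transition lies in range.
#' @export
doubling_points <- function(scan) {
  a <- scan$a_values
  per <- scan$periods
  if (length(a) != length(per)) stop("a_values and periods lengths differ")
  out <- data.frame(a_lo = numeric(0), a_hi = numeric(0),
                    period_before = integer(0), period_after = integer(0))
  for (i in seq_len(length(a) - 1L)) {
    p1 <- per[i]; p2 <- per[i + 1L]
    if (is.na(p1)) next
    if (!is.na(p2) && p2 == 2L * p1) {
      out <- rbind(out, data.frame(a_lo = a[i], a_hi = a[i + 1L],
                                   period_before = p1, period_after = p2))
    } else if (is.na(p2)) {
      out <- rbind(out, data.frame(a_lo = a[i], a_hi = a[i + 1L],
                                   period_before = p1,
                                   period_after = NA_integer_))
    }
  }
  out
}
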