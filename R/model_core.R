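#' @useDynLib lovechaos, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft dist hclust cutree runif
#' @importFrom utils write.table read.csv modifyList
NULL

#' Romantic-style coefficients of the love model
#'
#' Bundles the four coefficients of the coupled love/hate equations.
#' `a` and `b` describe Romeo (response to his own feelings and to
#' Juliet's), `c` and `d` describe Juliet (response to Romeo's feelings
#' and to her own). In the linear model
#' \deqn{dR/dt = aR + bJ, \quad dJ/dt = cR + dJ}
#' the origin is a saddle point exactly when \eqn{ad < bc}; that is the
#' regime in which sustained love/hate dynamics (and, with forcing,
#' chaos) occur.
#'
#' @param a,b,c,d Finite numeric scalars. Defaults fix `b = -2`, `c = 1`,
#'   `d = 1`, the reference configuration in which `a < -2` gives a
#'   saddle.
#' @return An object of class `love_params`.
#' @examples
#' p <- love_params(a = -5.41)
#' saddle_condition(p)
#' @export
love_params <- function(a = -5.41, b = -2, c = 1, d = 1) {
  for (nm in c("a", "b", "c", "d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "love_params")
}

#' @export
print.love_params <- function(x, ...) {
  cat(sprintf("love model parameters: a = %g, b = %g, c = %g, d = %g\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  saddle condition ad < bc: %s (ad = %g, bc = %g)\n",
              saddle_condition(x), x$a * x$d, x$b * x$c))
  invisible(x)
}

#' Saddle condition for the linear love model
#'
#' `TRUE` when `ad < bc`, i.e. the origin of the linearized system is a
#' saddle point (negative determinant).
#'
#' @param p A [love_params()] object.
#' @return Logical scalar.
#' @export
saddle_condition <- function(p) {
  stopifnot(inherits(p, "love_params"))
  p$a * p$d < p$b * p$c
}

#' Sinusoidal advice forcing
#'
#' The external environment ("advice from a third party") enters the
#' model additively as \eqn{y(t) = A \sin(\omega \pi t) + B}. `A + B`
#' is the positive magnitude of advice and `-A + B` the negative
#' magnitude.
#'
#' Note the convention: `omega` is the coefficient of \eqn{\pi t} inside
#' the sine, so the instantaneous angular frequency is `omega * pi` and
#' the forcing period is `2 / omega` time units (NOT `2 * pi / omega`).
#'
#' @param A Amplitude, non-negative.
#' @param B Offset (sign encodes whether positive or negative advice
#'   dominates).
#' @param omega Frequency parameter, positive; period is `2 / omega`.
#' @param target Which equation receives the forcing: `"romeo"`
#'   (default; Juliet's equation then has zero forcing), `"juliet"`, or
#'   `"both"`.
#' @return An object of class `forcing_spec`.
#' @seealso [scenario()] for the three reference advice scenarios,
#'   [forcing_value()] to evaluate \eqn{y(t)}.
#' @examples
#' f <- forcing_spec(A = 5, B = 0)
#' forcing_period(f)       # 2 time units
#' positive_magnitude(f)   # A + B = 5
#' @export
forcing_spec <- function(A = 5, B = 0, omega = 1, target = c("romeo", "juliet", "both")) {
  target <- match.arg(target)
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A < 0)
    stop("'A' must be a finite numeric scalar >= 0")
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B))
    stop("'B' must be a finite numeric scalar")
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("'omega' must be a finite numeric scalar > 0")
  structure(list(A = as.numeric(A), B = as.numeric(B),
                 omega = as.numeric(omega), target = target),
            class = "forcing_spec")
}

#' @export
print.forcing_spec <- function(x, ...) {
  cat(sprintf("forcing y(t) = %g sin(%g pi t) %+g  [period %g, target %s]\n",
              x$A, x$omega, x$B, forcing_period(x), x$target))
  cat(sprintf("  positive magnitude A + B = %g, negative magnitude -A + B = %g\n",
              positive_magnitude(x), negative_magnitude(x)))
  invisible(x)
}

#' @rdname forcing_spec
#' @param f A `forcing_spec` object.
#' @export
forcing_period <- function(f) {
  stopifnot(inherits(f, "forcing_spec"))
  2 / f$omega
}

#' @rdname forcing_spec
#' @export
positive_magnitude <- function(f) {
  stopifnot(inherits(f, "forcing_spec"))
  f$A + f$B
}

#' @rdname forcing_spec
#' @export
negative_magnitude <- function(f) {
  stopifnot(inherits(f, "forcing_spec"))
  -f$A + f$B
}

#' Evaluate the advice forcing at given times
#'
#' Computes \eqn{y(t) = A \sin(\omega \pi t) + B}.
#'
#' @param t Numeric vector of times (finite).
#' @param f A [forcing_spec()] object.
#' @return Numeric vector of forcing values, same length as `t`.
#' @examples
#' forcing_value(0.5, forcing_spec(A = 5, B = 0))  # 5
#' @export
forcing_value <- function(t, f) {
  stopifnot(inherits(f, "forcing_spec"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric")
  f$A * sin(f$omega * pi * t) + f$B
}

#' The three reference advice scenarios
#'
#' Presets for the balance between positive (`A + B`) and negative
#' (`-A + B`) advice:
#' \describe{
#'   \item{`P_eq_N`}{equal amounts, \eqn{y(t) = 5\sin(\pi t)} (`A = 5, B = 0`)}
#'   \item{`P_gt_N`}{positive dominates, \eqn{y(t) = 6\sin(\pi t) + 1} (`A = 6, B = 1`)}
#'   \item{`P_lt_N`}{negative dominates, \eqn{y(t) = 6\sin(\pi t) - 1} (`A = 6, B = -1`)}
#' }
#' All three target Romeo's equation only.
#'
#' @param name One of `"P_eq_N"`, `"P_gt_N"`, `"P_lt_N"`.
#' @return A [forcing_spec()] object.
#' @export
scenario <- function(name = c("P_eq_N", "P_gt_N", "P_lt_N")) {
  name <- match.arg(name)
  switch(name,
         P_eq_N = forcing_spec(A = 5, B = 0,  omega = 1, target = "romeo"),
         P_gt_N = forcing_spec(A = 6, B = 1,  omega = 1, target = "romeo"),
         P_lt_N = forcing_spec(A = 6, B = -1, omega = 1, target = "romeo"))
}

#' @export
scenario_names <- function() c("P_eq_N", "P_gt_N", "P_lt_N")

#' Vector field of the forced love model
#'
#' Right-hand side of
#' \deqn{dR/dt = aR + bJ(1-|J|) + y(t),\quad dJ/dt = cR(1-|R|) + dJ + f(t)}
#' where the forcing enters the equation(s) selected by the spec's
#' `target` (by default only Romeo's; Juliet's equation then receives
#' zero forcing).
#'
#' @param t Time (finite scalar).
#' @param state Numeric length-2 vector `c(R, J)`.
#' @param p A [love_params()] object.
#' @param f A [forcing_spec()] object.
#' @return Named numeric vector `c(dR = ..., dJ = ...)`.
#' @export
vector_field <- function(t, state, p, f) {
  stopifnot(inherits(p, "love_params"), inherits(f, "forcing_spec"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("'t' must be a finite numeric scalar")
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("'state' must be a finite numeric vector c(R, J)")
  R <- state[[1]]; J <- state[[2]]
  y <- forcing_value(t, f)
  dR <- p$a * R + p$b * J * (1 - abs(J)) +
    if (f$target %in% c("romeo", "both")) y else 0
  dJ <- p$c * R * (1 - abs(R)) + p$d * J +
    if (f$target %in% c("juliet", "both")) y else 0
  c(dR = dR, dJ = dJ)
}

#' State Jacobian of the love model
#'
#' Analytic Jacobian of the vector field with respect to `(R, J)`:
#' \deqn{\begin{pmatrix} a & b(1-2|J|) \\ c(1-2|R|) & d \end{pmatrix}}
#' The derivative of \eqn{x(1-|x|)} is \eqn{1-2|x|}; the one-sided
#' limits agree at `x = 0` (only the second derivative is kinked), so
#' the formula is used everywhere. The additive forcing does not enter.
#'
#' @param state Numeric length-2 vector `c(R, J)`.
#' @param p A [love_params()] object.
#' @return A 2x2 numeric matrix.
#' @export
love_jacobian <- function(state, p) {
  stopifnot(inherits(p, "love_params"))
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("'state' must be a finite numeric vector c(R, J)")
  R <- state[[1]]; J <- state[[2]]
  matrix(c(p$a, p$c * (1 - 2 * abs(R)),
           p$b * (1 - 2 * abs(J)), p$d),
         nrow = 2, ncol = 2)
}

#' Classify the fixed point at the origin of the linear love model
#'
#' Reports two classifications of the origin of the linearization
#' `[[a, b], [c, d]]`:
#' \itemize{
#'   \item `paper_label`: the coarse dichotomy `"saddle"` (iff
#'     `ad < bc`, i.e. negative determinant) vs `"non_saddle"`. This is
#'     the condition used to pick the parameter regime of interest.
#'   \item `spectral_label`: the full classification from the
#'     eigenvalues (`saddle`, `stable_node`, `stable_spiral`,
#'     `unstable_node`, `unstable_spiral`, `center`, `degenerate`).
#' }
#' The two are reported side by side because "not a saddle" implies
#' stability only when the trace `a + d` is also negative; with
#' `d = 1` and `a < -2` that holds, but not for general parameters.
#'
#' @param p A [love_params()] object.
#' @return An object of class `fixed_point_report` with fields
#'   `determinant` (`ad - bc`), `trace` (`a + d`), `eigenvalues`
#'   (complex pair), `paper_label`, `spectral_label`.
#' @examples
#' classify_fixed_point(love_params(a = -5.41))  # saddle
#' @export
classify_fixed_point <- function(p) {
  stopifnot(inherits(p, "love_params"))
  det_ <- p$a * p$d - p$b * p$c
  tr_ <- p$a + p$d
  ev <- eigen(matrix(c(p$a, p$c, p$b, p$d), 2, 2), only.values = TRUE)$values
  ev <- as.complex(ev)
  # order by real part, descending
  ev <- ev[order(-Re(ev), -Im(ev))]
  disc <- tr_^2 - 4 * det_
  spectral <-
    if (det_ < 0) "saddle"
    else if (det_ == 0) "degenerate"
    else if (tr_ == 0) "center"
    else if (tr_ < 0 && disc >= 0) "stable_node"
    else if (tr_ < 0) "stable_spiral"
    else if (disc >= 0) "unstable_node"
    else "unstable_spiral"
  structure(list(determinant = det_, trace = tr_, eigenvalues = ev,
                 paper_label = if (det_ < 0) "saddle" else "non_saddle",
                 spectral_label = spectral, params = p),
            class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat("fixed point (0, 0) of the linearized love model\n")
  cat(sprintf("  determinant ad - bc = %g, trace a + d = %g\n",
              x$determinant, x$trace))
  cat(sprintf("  eigenvalues: %s, %s\n",
              format(x$eigenvalues[1]), format(x$eigenvalues[2])))
  cat(sprintf("  saddle dichotomy (ad < bc): %s; spectral class: %s\n",
              x$paper_label, x$spectral_label))
  invisible(x)
}
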