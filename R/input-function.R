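#' Tri-exponential plasma input function
#'
#' Parameterizes an arterial plasma concentration curve of the common
#' "linear rise times a fast exponential plus two slower washout
#' exponentials" form,
#' `C_p(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) + A3 exp(-l3 t)`,
#' clipped at zero. The input function exists only to drive the simulators:
#' the reference-tissue quantification itself never sees plasma data.
#'
#' @param A1 rise slope (kBq/mL/min), `> 0`.
#' @param A2,A3 washout amplitudes (kBq/mL), `>= 0`.
#' @param lambda1,lambda2,lambda3 decay constants (1/min), strictly
#'   decreasing and positive.
#' @return A `feng_input_params` object.
#' @export
feng_input_params <- function(A1 = 800, A2 = 20, A3 = 10,
                              lambda1 = 4, lambda2 = 0.5, lambda3 = 0.01) {
  stopifnot(is.numeric(A1), is.numeric(A2), is.numeric(A3))
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 > 0)) {
    stop("decay constants must satisfy lambda1 > lambda2 > lambda3 > 0")
  }
  if (A1 <= 0) stop("A1 must be positive")
  if (A2 < 0 || A3 < 0) stop("A2 and A3 must be nonnegative")
  structure(list(A1 = A1, A2 = A2, A3 = A3,
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "feng_input_params")
}

#' Evaluate the plasma input function
#'
#' @param params a [feng_input_params()].
#' @param times nonnegative times (minutes).
#' @return Plasma concentration (kBq/mL) at `times`, clipped at zero.
#' @examples
#' feng_input(feng_input_params(), c(0, 0.25, 1, 60))
#' @export
feng_input <- function(params, times) {
  stopifnot(inherits(params, "feng_input_params"), is.numeric(times))
  if (any(times < 0)) stop("times must be nonnegative")
  p <- params
  cp <- (p$A1 * times - p$A2 - p$A3) * exp(-p$lambda1 * times) +
    p$A2 * exp(-p$lambda2 * times) +
    p$A3 * exp(-p$lambda3 * times)
  pmax(cp, 0)
}
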