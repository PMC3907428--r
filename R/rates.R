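# Hodgkin-Huxley style voltage-dependent rate functions in the canonical
# Beeler-Reuter coefficient form, including removable-singularity handling.

#' Voltage-dependent rate specification
#'
#' All gate opening/closing rates of the membrane model share the canonical
#' form
#' \deqn{rate(V) = \frac{C_1 e^{C_2 (V+C_3)} + C_4 (V+C_5)}{e^{C_6 (V+C_3)} + C_7}}
#' in ms^-1 with `V` in mV.  Some members of this family have a removable
#' singularity where numerator and denominator vanish together; for those,
#' `singular_V` and the analytic (L'Hopital) limit `singular_limit` must be
#' supplied, and [evaluate_rate()] returns the stored limit within a small
#' half-width of `singular_V`.
#'
#' @param C1,C2,C3,C4,C5,C6,C7 coefficients of the canonical form.
#' @param singular_V optional potential (mV) of a removable singularity.
#' @param singular_limit analytic limit (ms^-1) at `singular_V`.
#' @return an object of class `cw_rate_spec`.
#' @examples
#' # sodium activation opening rate (Drouhard-Roberge form)
#' am <- rate_spec(C3 = 42.65, C4 = -0.9, C5 = 42.65, C6 = -0.22, C7 = -1,
#'                 singular_V = -42.65, singular_limit = 0.9 / 0.22)
#' evaluate_rate(c(-80, -42.65, 0), am)
#' @export
rate_spec <- function(C1 = 0, C2 = 0, C3 = 0, C4 = 0, C5 = 0, C6 = 0, C7 = 0,
                      singular_V = NULL, singular_limit = NULL) {
  co <- c(C1 = unname(C1), C2 = unname(C2), C3 = unname(C3),
          C4 = unname(C4), C5 = unname(C5), C6 = unname(C6),
          C7 = unname(C7))
  if (any(!is.finite(co)))
    stop("rate_spec coefficients must be finite")
  if (xor(is.null(singular_V), is.null(singular_limit)))
    stop("singular_V and singular_limit must be supplied together")
  structure(list(C = co, singular_V = singular_V,
                 singular_limit = singular_limit),
            class = "cw_rate_spec")
}

# half-width around singular_V inside which the analytic limit is returned
.cw_singular_halfwidth <- 1e-6

#' Evaluate a rate function
#'
#' @param V membrane potential(s), mV; must be finite.
#' @param spec a [rate_spec()].
#' @return rate value(s), ms^-1.
#' @export
evaluate_rate <- function(V, spec) {
  stopifnot(inherits(spec, "cw_rate_spec"))
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be finite numeric")
  co <- spec$C
  x <- V + co[["C3"]]
  num <- co[["C1"]] * exp(co[["C2"]] * x) + co[["C4"]] * (V + co[["C5"]])
  den <- exp(co[["C6"]] * x) + co[["C7"]]
  out <- num / den
  if (!is.null(spec$singular_V)) {
    near <- abs(V - spec$singular_V) < .cw_singular_halfwidth
    out[near] <- spec$singular_limit
  }
  out
}

#' Gate steady state and time constant
#'
#' Standard Hodgkin-Huxley identities `g_inf = alpha / (alpha + beta)` and
#' `tau = 1 / (alpha + beta)`.
#'
#' @param alpha,beta opening and closing rates, ms^-1 (non-negative;
#'   `alpha + beta` must be positive).
#' @return list with `g_inf` (dimensionless, in \[0, 1\]) and `tau` (ms).
#' @export
gate_steady_state <- function(alpha, beta) {
  if (any(alpha < 0) || any(beta < 0))
    stop("rates must be non-negative")
  s <- alpha + beta
  if (any(s == 0))
    stop("degenerate rates: alpha + beta must be positive")
  list(g_inf = alpha / s, tau = 1 / s)
}

#' @export
print.cw_rate_spec <- function(x, ...) {
  co <- x$C
  cat("rate(V) = (", co[["C1"]], "*exp(", co[["C2"]], "*(V+", co[["C3"]],
      ")) + ", co[["C4"]], "*(V+", co[["C5"]], ")) / (exp(", co[["C6"]],
      "*(V+", co[["C3"]], ")) + ", co[["C7"]], ")\n", sep = "")
  if (!is.null(x$singular_V))
    cat("removable singularity at V =", x$singular_V, "mV, limit",
        x$singular_limit, "ms^-1\n")
  invisible(x)
}
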