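#' Generation parameters for random interaction matrices
#'
#' Bundles the parameters controlling random community generation: the
#' number of species `n`, the proportion `P` of interacting pairs that are
#' mutualistic (+/+), the connectance `C` (probability that an unordered
#' species pair interacts at all), the interaction-variability scale
#' `sigma` (magnitudes are drawn as `sigma * |N(0,1)|`, a half-normal with
#' mean `sigma * sqrt(2/pi)`), the mean interaction strength `m` used by
#' the uniform and Gaussian generators, the type of the non-mutualistic
#' background pairs, and an optional RNG seed.
#'
#' @param n Integer species count, at least 2.
#' @param P Proportion of interacting pairs assigned mutualistic type, in
#'   `[0, 1]`.
#' @param C Connectance in `[0, 1]`: each unordered pair is retained with
#'   probability `C`; non-retained pairs have both coefficients exactly 0.
#' @param sigma Non-negative half-normal scale of interaction magnitudes
#'   (dimensionless per-capita effects).
#' @param m Mean interaction strength used by [generate_uniform()] and
#'   [generate_gaussian()]; ignored by [generate_chen_cohen()].
#' @param background Type given to retained non-mutualistic pairs: one of
#'   `"exploitative"` (+/-, orientation uniform at random),
#'   `"competitive"` (-/-), or `"random"` (each coefficient gets an
#'   independent uniform sign, so the background has mean zero).
#' @param seed Optional integer seed; when supplied, generation is
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return An object of class `"gen_params"` (a named list).
#' @seealso [generate_chen_cohen()]
#' @examples
#' gen_params(n = 100, P = 0.5, C = 0.7, sigma = 0.02, seed = 1)
#' @export
gen_params <- function(n, P = 0, C = 1, sigma = 0.02, m = 0,
                       background = c("exploitative", "competitive", "random"),
                       seed = NULL) {
  background <- match.arg(background)
  check_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop_lvcomm(sprintf("`%s` must be a finite numeric scalar.", nm),
                  "lvcomm_parameter_error")
    }
  }
  check_scalar(n, "n"); check_scalar(P, "P"); check_scalar(C, "C")
  check_scalar(sigma, "sigma"); check_scalar(m, "m")
  if (n < 2 || n != round(n)) {
    stop_lvcomm("`n` must be an integer >= 2.", "lvcomm_parameter_error")
  }
  if (P < 0 || P > 1) stop_lvcomm("`P` must lie in [0, 1].", "lvcomm_parameter_error")
  if (C < 0 || C > 1) stop_lvcomm("`C` must lie in [0, 1].", "lvcomm_parameter_error")
  if (sigma < 0) stop_lvcomm("`sigma` must be >= 0.", "lvcomm_parameter_error")
  if (!is.null(seed)) {
    check_scalar(seed, "seed")
    seed <- as.integer(seed)
  }
  structure(
    list(n = as.integer(n), P = P, C = C, sigma = sigma, m = m,
         background = background, seed = seed),
    class = "gen_params"
  )
}

#' @export
print.gen_params <- function(x, ...) {
  cat("<gen_params>",
      sprintf("n = %d, P = %g, C = %g, sigma = %g, m = %g", x$n, x$P, x$C,
              x$sigma, x$m),
      sprintf("background = %s, seed = %s", x$background,
              if (is.null(x$seed)) "none" else format(x$seed)),
      sep = "\n")
  invisible(x)
}
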