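#' Solve for the interior Lotka-Volterra equilibrium
#'
#' Setting the time derivatives of the Lotka-Volterra system to zero gives
#' the linear system `A N* = -r`; this solves it directly and flags
#' feasibility (all equilibrium densities strictly positive), the
#' criterion for a viable community.
#'
#' @param A An `"interaction_matrix"` or a square matrix.
#' @param r Growth-rate vector; defaults to all +1, the scaling under
#'   which `N*` is a right eigenvector of the community matrix.
#' @return An object of class `"lv_equilibrium"`: `Nstar`, `r`,
#'   `feasible`, `Nmin`, `Nmean`, the solve residual
#'   `max |A N* + r|`, and the matrix `A`.
#' @details A singular (or numerically singular) `A` means no unique
#'   interior equilibrium — the blow-up regime — and raises an error of
#'   class `"lvcomm_singular_error"`. A reciprocal condition number below
#'   1e-12 triggers a warning.
#' @examples
#' eq <- solve_equilibrium(generate_uniform(n = 2, m = 0.5))
#' eq$Nstar  # the regular-model value 1 / (1 - (n-1) m) = 2
#' @export
solve_equilibrium <- function(A, r = NULL) {
  M <- as_lv_matrix(A)
  n <- nrow(M)
  r <- r %||% rep(1, n)
  if (length(r) != n) {
    stop_lvcomm("`r` must have one entry per species.", "lvcomm_shape_error")
  }
  rc <- tryCatch(rcond(M), error = function(e) 0)
  if (rc == 0) {
    stop_lvcomm("`A` is singular: blow-up / no unique equilibrium.",
                "lvcomm_singular_error")
  }
  if (rc < 1e-12) {
    rlang::warn(sprintf(
      "`A` is ill-conditioned (rcond = %.3g); equilibrium may be unreliable.",
      rc))
  }
  Nstar <- tryCatch(drop(solve(M, -r)), error = function(e) {
    stop_lvcomm("`A` is singular: blow-up / no unique equilibrium.",
                "lvcomm_singular_error")
  })
  structure(
    list(Nstar = Nstar, r = r, feasible = all(Nstar > 0),
         Nmin = min(Nstar), Nmean = mean(Nstar),
         residual = max(abs(M %*% Nstar + r)), A = M),
    class = "lv_equilibrium"
  )
}

#' @export
print.lv_equilibrium <- function(x, ...) {
  cat(sprintf("<lv_equilibrium> n = %d, %s\n", length(x$Nstar),
              if (x$feasible) "feasible" else "NOT feasible"),
      sprintf("  min N* = %.4g, mean N* = %.4g, residual = %.2g\n",
              x$Nmin, x$Nmean, x$residual), sep = "")
  invisible(x)
}

#' @method tidy lv_equilibrium
#' @export
tidy.lv_equilibrium <- function(x, ...) {
  tibble::tibble(species = seq_along(x$Nstar), Nstar = x$Nstar, r = x$r)
}

#' @method glance lv_equilibrium
#' @export
glance.lv_equilibrium <- function(x, ...) {
  tibble::tibble(n = length(x$Nstar), feasible = x$feasible, Nmin = x$Nmin,
                 Nmean = x$Nmean, residual = x$residual)
}

#' Mean-field equilibrium density of the uniform model
#'
#' For the uniform skeleton (every interacting pair at strength `m`,
#' connectance `C`, mutualistic proportion `P`) the equilibrium density is
#' `1 / (1 - (n - 1) m C P)`; with `C = P = 1` this is the regular-model
#' value `1 / (1 - (n - 1) m)`. It is the zeroth-order prediction for the
#' mean density of random communities, with `m` taken as the mean of a
#' nonzero mutualistic entry (`sigma * sqrt(2/pi)` for the half-normal
#' generator; see [half_normal_mean()]).
#'
#' @param n Species count.
#' @param m Mean interaction strength.
#' @param C,P Connectance and mutualistic proportion.
#' @return The predicted density (a scalar).
#' @examples
#' mean_field_Nstar(n = 2, m = 0.5)  # 2
#' @export
mean_field_Nstar <- function(n, m, C = 1, P = 1) {
  q <- (n - 1) * m * C * P
  if (q >= 1) {
    stop_lvcomm(sprintf(
      "(n - 1) m C P = %.4g >= 1: blow-up, feasibility lost.", q),
      "lvcomm_blowup_error")
  }
  1 / (1 - q)
}

#' Mutualistic blow-up bound on interaction strength
#'
#' The regular model (all pairs mutualistic at strength `m`, `C = P = 1`)
#' is feasible only for `m < 1/(n - 1)`; at equality the interaction
#' matrix is singular and densities blow up.
#'
#' @param n Species count (>= 2).
#' @return `1 / (n - 1)`.
#' @export
blowup_bound <- function(n) {
  if (n < 2) stop_lvcomm("`n` must be >= 2.", "lvcomm_parameter_error")
  1 / (n - 1)
}

#' Mean of the half-normal interaction magnitude
#'
#' `E(sigma * |N(0,1)|) = sigma * sqrt(2/pi)`, the effective mean strength
#' of a nonzero mutualistic coefficient under [generate_chen_cohen()].
#'
#' @param sigma Half-normal scale.
#' @return `sigma * sqrt(2/pi)`.
#' @export
half_normal_mean <- function(sigma) sigma * sqrt(2 / pi)

#' May's stability condition for large random communities
#'
#' Evaluates `n sigma^2 / (1 + m)^2` and whether it is below 1, the
#' classical complexity-stability threshold that the feasibility
#' requirement of weakly, variably interacting communities resembles.
#'
#' @param n Species count.
#' @param sigma Interaction variability.
#' @param m Mean interaction strength (must differ from -1).
#' @return A list with `value` and logical `holds`.
#' @examples
#' may_condition(n = 100, sigma = 0.02, m = 0)
#' @export
may_condition <- function(n, sigma, m = 0) {
  if (sigma < 0) stop_lvcomm("`sigma` must be >= 0.", "lvcomm_parameter_error")
  if (m == -1) {
    stop_lvcomm("`m = -1` makes the condition undefined.",
                "lvcomm_parameter_error")
  }
  value <- n * sigma^2 / (1 + m)^2
  list(value = value, holds = value < 1)
}

#' Monte-Carlo probability that a random community is feasible
#'
#' Generates `reps` replicate matrices under `params` and reports the
#' fraction whose interior equilibrium (with `r = 1`) is feasible,
#' together with the binomial standard error. Draws whose matrix is
#' singular count as infeasible.
#'
#' @param params A [gen_params()] object (its `seed` field is ignored in
#'   favour of `seed` here).
#' @param reps Number of replicate matrices (>= 1).
#' @param seed Optional seed for the whole experiment.
#' @return A one-row tibble: `p_feasible`, `se`, `n_feasible`, `reps`.
#' @examples
#' feasibility_probability(gen_params(n = 20, P = 0.5, C = 0.7,
#'                                    sigma = 0.02), reps = 50, seed = 1)
#' @export
feasibility_probability <- function(params, reps, seed = NULL) {
  stopifnot(inherits(params, "gen_params"), reps >= 1)
  inner <- params
  inner$seed <- NULL
  with_seed_if(seed, {
    ok <- vapply(seq_len(reps), function(k) {
      x <- generate_chen_cohen(inner)
      tryCatch(solve_equilibrium(x)$feasible, error = function(e) FALSE)
    }, logical(1))
    p <- mean(ok)
    tibble::tibble(p_feasible = p, se = sqrt(p * (1 - p) / reps),
                   n_feasible = sum(ok), reps = as.integer(reps))
  })
}
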