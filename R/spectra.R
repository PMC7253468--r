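#' Community (Jacobian) matrix S = DA
#'
#' The Jacobian of the Lotka-Volterra system at a feasible interior
#' equilibrium is `S = D A` with `D = diag(N*)`: row `i` of `A` scaled by
#' the equilibrium density of species `i`. Its spectrum, not that of `A`
#' alone, governs local stability and return rates.
#'
#' @param A An `"interaction_matrix"` or square matrix.
#' @param Nstar Equilibrium density vector (length `n`), or an
#'   `"lv_equilibrium"` in place of both arguments.
#' @return The `n x n` community matrix.
#' @examples
#' eq <- solve_equilibrium(generate_uniform(n = 3, m = 0.1))
#' S <- community_matrix(eq$A, eq$Nstar)
#' max(abs(S %*% eq$Nstar + eq$Nstar))  # S N* = -N* when r = 1
#' @export
community_matrix <- function(A, Nstar = NULL) {
  if (inherits(A, "lv_equilibrium")) {
    Nstar <- A$Nstar
    A <- A$A
  }
  M <- as_lv_matrix(A)
  if (is.null(Nstar) || length(Nstar) != nrow(M)) {
    stop_lvcomm("`Nstar` must match the dimension of `A`.",
                "lvcomm_shape_error")
  }
  as.numeric(Nstar) * M
}

#' Spectrum of the community matrix with bulk/outlier decomposition
#'
#' Computes the full eigendecomposition of `S`, the leading eigenvalue
#' `Lambda = max Re(lambda_i)` (negative iff locally stable, with |Lambda|
#' the resilience index), and — when `Nstar` is supplied — identifies the
#' outlier eigenvalue as the one whose eigenvector is best aligned with
#' `N*` (maximal cosine similarity). For `r = 1` that outlier is exactly
#' -1, since `S N* = -N*`. The remaining `n - 1` eigenvalues form the
#' random-matrix bulk; `bulk_center` is their mean, which tracks the
#' negated mean density `-<N*>`.
#'
#' Alignment, rather than proximity to -1, keeps the outlier label
#' correct when the bulk overlaps -1 at low mutualism.
#'
#' @param S Community matrix (or any square matrix).
#' @param Nstar Optional equilibrium vector used to identify the outlier.
#' @return An object of class `"spectral_summary"`: complex `eigenvalues`
#'   (sorted by decreasing real part), `Lambda`, `outlier`,
#'   `outlier_index`, `bulk_center` (complex), `bulk_center_re`,
#'   `locally_stable`, `n`.
#' @examples
#' eq <- solve_equilibrium(generate_chen_cohen(
#'   gen_params(n = 20, P = 0.6, C = 0.7, sigma = 0.02, seed = 1)))
#' sp <- community_spectrum(community_matrix(eq), eq$Nstar)
#' sp$Lambda
#' @export
community_spectrum <- function(S, Nstar = NULL) {
  S <- as_lv_matrix(S)
  n <- nrow(S)
  es <- eigen(S)
  ord <- order(Re(es$values), decreasing = TRUE)
  values <- es$values[ord]
  vectors <- es$vectors[, ord, drop = FALSE]
  Lambda <- max(Re(values))

  outlier <- NA_complex_
  outlier_index <- NA_integer_
  bulk <- values
  if (!is.null(Nstar)) {
    if (length(Nstar) != n) {
      stop_lvcomm("`Nstar` must match the dimension of `S`.",
                  "lvcomm_shape_error")
    }
    align <- vapply(seq_len(n), function(k) {
      v <- vectors[, k]
      Mod(sum(Conj(v) * Nstar)) / (sqrt(sum(Mod(v)^2)) * sqrt(sum(Nstar^2)))
    }, numeric(1))
    outlier_index <- which.max(align)
    outlier <- values[outlier_index]
    bulk <- values[-outlier_index]
  }
  bulk_center <- mean(bulk)
  structure(
    list(eigenvalues = values, Lambda = Lambda, outlier = outlier,
         outlier_index = outlier_index, bulk_center = bulk_center,
         bulk_center_re = Re(bulk_center), locally_stable = Lambda < 0,
         n = n),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> n = %d, Lambda = %.6g (%s)\n", x$n,
              x$Lambda,
              if (x$locally_stable) "locally stable" else "unstable"))
  if (!is.na(x$outlier_index)) {
    cat(sprintf("  outlier = %.6g%+.2gi, bulk centre = %.6g%+.2gi\n",
                Re(x$outlier), Im(x$outlier), Re(x$bulk_center),
                Im(x$bulk_center)))
  }
  invisible(x)
}

#' @method tidy spectral_summary
#' @export
tidy.spectral_summary <- function(x, ...) {
  k <- seq_along(x$eigenvalues)
  tibble::tibble(
    re = Re(x$eigenvalues), im = Im(x$eigenvalues),
    is_outlier = if (is.na(x$outlier_index)) rep(FALSE, length(k))
                 else k == x$outlier_index
  )
}

#' @method glance spectral_summary
#' @export
glance.spectral_summary <- function(x, ...) {
  tibble::tibble(n = x$n, Lambda = x$Lambda,
                 outlier_re = Re(x$outlier), outlier_im = Im(x$outlier),
                 bulk_center_re = Re(x$bulk_center),
                 bulk_center_im = Im(x$bulk_center),
                 locally_stable = x$locally_stable)
}

#' Minimum-density approximation to the leading eigenvalue
#'
#' For weakly interacting feasible communities the leading eigenvalue of
#' `S = DA` is well approximated by `max(-min(N*), -1)`: the least
#' abundant species sets the slowest return rate until its density
#' exceeds 1, after which the -1 outlier (the `N*` eigendirection) takes
#' over and resilience saturates.
#'
#' @param Nstar Feasible equilibrium density vector.
#' @return The approximate leading eigenvalue.
#' @examples
#' lambda_approx(c(0.5, 2, 3))  # -0.5
#' lambda_approx(c(2, 3, 4))    # -1
#' @export
lambda_approx <- function(Nstar) {
  if (length(Nstar) == 0) {
    stop_lvcomm("`Nstar` must be non-empty.", "lvcomm_shape_error")
  }
  max(-min(Nstar), -1)
}

#' Density-proportional eigenvalue predictions
#'
#' Under weak interactions the community-matrix eigenvalues are
#' approximately proportional to the equilibrium densities:
#' `lambda_i ~ -(1 + E(a_ij)) N_i*`, with the expectation taken over
#' nonzero off-diagonal coefficients. Returned per species, for
#' comparison with the sorted real parts of the true spectrum; rarer
#' species recover more slowly.
#'
#' @param A An `"interaction_matrix"` or square matrix.
#' @param Nstar Equilibrium density vector.
#' @return Numeric vector of predicted rates, one per species.
#' @export
eigen_density_relation <- function(A, Nstar) {
  M <- as_lv_matrix(A)
  off <- M[row(M) != col(M)]
  nz <- off[off != 0]
  Ebar <- if (length(nz) == 0) 0 else mean(nz)
  -(1 + Ebar) * as.numeric(Nstar)
}

#' Trace identity between eigenvalues and densities
#'
#' `trace(S) = sum(S_ii) = -sum(N_i*)` because the diagonal of `A` is -1,
#' so the mean eigenvalue of the community matrix equals the negated mean
#' density exactly: `<lambda_i> = <-N_i*>`. Returns the residual
#' `|mean(lambda_i) - mean(-N_i*)|`, which should be at machine precision
#' (< 1e-10) for any correctly built `S = DA`.
#'
#' @param S Community matrix built from `Nstar`.
#' @param Nstar Equilibrium density vector.
#' @return Non-negative residual (modulus of a complex difference).
#' @export
trace_identity_check <- function(S, Nstar) {
  S <- as_lv_matrix(S)
  ev <- eigen(S, only.values = TRUE)$values
  Mod(mean(ev) - mean(-as.numeric(Nstar)))
}

#' Plot a community spectrum in the complex plane
#'
#' @param object A `"spectral_summary"`.
#' @param ... Unused.
#' @return A ggplot: bulk eigenvalues as points, the outlier highlighted,
#'   with a reference line at Re = 0.
#' @method autoplot spectral_summary
#' @export
autoplot.spectral_summary <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_outlier,
                                     shape = .data$is_outlier)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "firebrick",
                                            `TRUE` = "black"),
                                 name = "outlier") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "outlier") +
    ggplot2::labs(x = expression(Re(lambda)), y = expression(Im(lambda))) +
    ggplot2::theme_minimal()
}
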