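## Draw one Chen-Cohen community and solve it; NULL equilibrium if the
## matrix is singular.
draw_community <- function(params) {
  x <- generate_chen_cohen(params)
  eq <- tryCatch(suppressWarnings(solve_equilibrium(x)),
                 lvcomm_singular_error = function(e) NULL)
  list(matrix = x, eq = eq)
}

#' Sweep the proportion of mutualistic pairs
#'
#' For each value of `P`, generates random communities with the given
#' background until `reps` feasible draws are collected (infeasible draws
#' are rejected and counted, never hidden), and records per-`P` averages
#' of the leading eigenvalue `Lambda` of `S = DA`, the minimum and mean
#' equilibrium densities, and the uniform-model mean-field prediction
#' `1 / (1 - (n-1) m_eff C P)` with `m_eff = sigma * sqrt(2/pi)`.
#'
#' Resilience rises with mutualism: `Lambda` falls as `-N*min` until the
#' minimum density passes 1, after which `Lambda` saturates at the -1
#' outlier. [crossing_P()] locates that saturation point.
#'
#' @param base A [gen_params()] object supplying `n`, `C`, `sigma` and the
#'   background; its `P` and `seed` fields are overridden.
#' @param P_grid Values of `P` to visit.
#' @param reps Feasible replicates required per grid point.
#' @param seed Optional seed making the whole sweep reproducible.
#' @param max_attempts Generation attempts allowed per grid point before
#'   the point is flagged `partial` (averages then use the feasible draws
#'   found so far).
#' @return A tibble of class `"lv_sweep"` with columns `P`, `n_feasible`,
#'   `n_attempts`, `feasible_fraction`, `Lambda_mean`, `Nmin_mean`,
#'   `Nmean_mean`, `mean_field` (NA beyond the blow-up point), `partial`.
#'   A per-attempt log (`P`, `attempt`, `feasible`, `Lambda`, `Nmin`,
#'   `Nmean`) is attached as attribute `"log"`.
#' @examples
#' base <- gen_params(n = 20, C = 0.7, sigma = 0.02)
#' sw <- sweep_P(base, P_grid = c(0.2, 0.6), reps = 5, seed = 1)
#' sw$Lambda_mean
#' @export
sweep_P <- function(base, P_grid = seq(0, 0.9, by = 0.02), reps = 50,
                    seed = NULL, max_attempts = 20 * reps) {
  stopifnot(inherits(base, "gen_params"), reps >= 1,
            all(P_grid >= 0 & P_grid <= 1))
  m_eff <- half_normal_mean(base$sigma)
  inner <- base
  inner$seed <- NULL
  log_rows <- list()
  rows <- with_seed_if(seed, {
    purrr::map(P_grid, function(P) {
      inner$P <- P
      lam <- nmin <- nmean <- numeric(0)
      attempts <- 0L
      while (length(lam) < reps && attempts < max_attempts) {
        attempts <- attempts + 1L
        d <- draw_community(inner)
        feas <- !is.null(d$eq) && d$eq$feasible
        if (feas) {
          sp <- community_spectrum(community_matrix(d$eq))
          lam <- c(lam, sp$Lambda)
          nmin <- c(nmin, d$eq$Nmin)
          nmean <- c(nmean, d$eq$Nmean)
        }
        log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
          P = P, attempt = attempts, feasible = feas,
          Lambda = if (feas) lam[length(lam)] else NA_real_,
          Nmin = if (feas) nmin[length(nmin)] else NA_real_,
          Nmean = if (feas) nmean[length(nmean)] else NA_real_)
      }
      mf <- tryCatch(mean_field_Nstar(base$n, m_eff, base$C, P),
                     lvcomm_blowup_error = function(e) NA_real_)
      tibble::tibble(
        P = P, n_feasible = length(lam), n_attempts = attempts,
        feasible_fraction = length(lam) / attempts,
        Lambda_mean = if (length(lam)) mean(lam) else NA_real_,
        Nmin_mean = if (length(nmin)) mean(nmin) else NA_real_,
        Nmean_mean = if (length(nmean)) mean(nmean) else NA_real_,
        mean_field = mf, partial = length(lam) < reps)
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "log") <- dplyr::bind_rows(log_rows)
  attr(out, "base") <- base
  attr(out, "reps") <- as.integer(reps)
  attr(out, "seed") <- seed
  class(out) <- c("lv_sweep", class(out))
  out
}

#' Locate where a sweep column crosses a level
#'
#' Linear interpolation between the grid points bracketing the first
#' upward crossing; by default the `P` at which the averaged minimum
#' equilibrium density reaches 1, the point where the leading eigenvalue
#' stops tracking `-N*min` and saturates at -1.
#'
#' @param sweep An `"lv_sweep"`.
#' @param level Crossing level (default 1).
#' @param column Sweep column to interrogate (default `"Nmin_mean"`).
#' @return Interpolated `P` (NA if the level is never reached).
#' @export
crossing_P <- function(sweep, level = 1, column = "Nmin_mean") {
  v <- sweep[[column]]
  P <- sweep$P
  ok <- !is.na(v)
  v <- v[ok]; P <- P[ok]
  above <- which(v >= level)
  if (length(above) == 0) return(NA_real_)
  k <- min(above)
  if (k == 1) return(P[1])
  P[k - 1] + (P[k] - P[k - 1]) * (level - v[k - 1]) / (v[k] - v[k - 1])
}

#' Plot a mutualism sweep
#'
#' @param object An `"lv_sweep"`.
#' @param ... Unused.
#' @return A ggplot of `Lambda`, `-N*min`, `-<N*>` and the negated
#'   mean-field prediction against `P`.
#' @method autoplot lv_sweep
#' @export
autoplot.lv_sweep <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::transmute(
      P = .data$P, Lambda = .data$Lambda_mean,
      `-N*min` = -.data$Nmin_mean, `-<N*>` = -.data$Nmean_mean,
      `mean field` = -.data$mean_field) |>
    tidyr::pivot_longer(-"P", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$P, y = .data$value,
                                    colour = .data$quantity)) +
    ggplot2::geom_hline(yintercept = -1, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "proportion of mutualistic pairs P", y = NULL) +
    ggplot2::theme_minimal()
}

#' Eigenvalue clouds of the community matrix across mutualism levels
#'
#' For each requested `P`, draws one feasible community, builds
#' `S = DA`, and exports the full complex spectrum with the
#' eigenvector-aligned outlier labelled. Increasing `P` shifts the
#' elliptical bulk left (its centre tracking `-<N*>`) and separates it
#' from the -1 outlier.
#'
#' @param base A [gen_params()] object (its `P` and `seed` overridden).
#' @param P_values Mutualism levels to draw.
#' @param seed Optional seed.
#' @param max_attempts Draw attempts per `P` before erroring.
#' @return A tibble of class `"lv_eigen_cloud"` with columns `P`, `re`,
#'   `im`, `is_outlier`; a per-`P` summary (`Lambda`, `bulk_center_re`,
#'   `bulk_center_im`, `Nmean`, `Nmin`, `trace_residual`, `n_reject`) is
#'   attached as attribute `"summary"`.
#' @export
eigen_cloud <- function(base, P_values = c(0, 0.2, 0.5, 0.8), seed = NULL,
                        max_attempts = 200) {
  stopifnot(inherits(base, "gen_params"))
  inner <- base
  inner$seed <- NULL
  with_seed_if(seed, {
    clouds <- list()
    summaries <- list()
    for (P in P_values) {
      inner$P <- P
      eq <- NULL
      attempts <- 0L
      while (is.null(eq) && attempts < max_attempts) {
        attempts <- attempts + 1L
        d <- draw_community(inner)
        if (!is.null(d$eq) && d$eq$feasible) eq <- d$eq
      }
      if (is.null(eq)) {
        stop_lvcomm(sprintf(
          "No feasible draw at P = %g within %d attempts.", P,
          max_attempts), "lvcomm_experiment_error")
      }
      S <- community_matrix(eq)
      sp <- community_spectrum(S, eq$Nstar)
      clouds[[length(clouds) + 1L]] <-
        dplyr::mutate(tidy(sp), P = P, .before = 1)
      summaries[[length(summaries) + 1L]] <- tibble::tibble(
        P = P, Lambda = sp$Lambda, outlier_re = Re(sp$outlier),
        bulk_center_re = Re(sp$bulk_center),
        bulk_center_im = Im(sp$bulk_center),
        Nmean = eq$Nmean, Nmin = eq$Nmin,
        trace_residual = trace_identity_check(S, eq$Nstar),
        n_reject = attempts - 1L)
    }
    out <- dplyr::bind_rows(clouds)
    attr(out, "summary") <- dplyr::bind_rows(summaries)
    attr(out, "base") <- base
    class(out) <- c("lv_eigen_cloud", class(out))
    out
  })
}

#' @method autoplot lv_eigen_cloud
#' @export
autoplot.lv_eigen_cloud <- function(object, ...) {
  summ <- attr(object, "summary")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_outlier),
                        size = 0.9) +
    ggplot2::geom_point(data = summ,
                        ggplot2::aes(x = -.data$Nmean, y = 0),
                        colour = "blue", shape = 19, size = 2,
                        inherit.aes = FALSE) +
    ggplot2::facet_wrap(~P, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "firebrick",
                                            `TRUE` = "black"),
                                 name = "outlier") +
    ggplot2::labs(x = expression(Re(lambda)), y = expression(Im(lambda))) +
    ggplot2::theme_minimal()
}

#' Pulse-recovery comparison of mutualistic and mean-zero communities
#'
#' Reproduces the paired perturbation experiment: ensembles of small
#' communities with Gaussian interactions, one purely mutualistic
#' (mean `m_mut`, all coefficients positive) and one mean-zero, each
#' replicated `n_seeds` times. One species is depressed by `depth`
#' density units and the nonlinear dynamics integrated; the per-run
#' return time into an `eps` band is recorded. Mutualists hold much
#' larger equilibrium densities, so the community matrix `S = DA`
#' contracts faster and their return times are shorter. Draws that are
#' infeasible, unstable, or whose perturbed species sits below `depth`
#' are redrawn and counted.
#'
#' @param n Species count per community.
#' @param depth Pulse depth in density units.
#' @param n_seeds Replicates per ensemble.
#' @param m_mut,m_zero Mean interaction strengths of the two ensembles.
#' @param sigma Interaction standard deviation.
#' @param species Index of the perturbed species.
#' @param eps Return-time band half-width.
#' @param t_end Integration horizon.
#' @param seed Optional seed.
#' @param max_attempts Redraw cap per run.
#' @return A tibble of class `"lv_pulse_experiment"`: `ensemble`, `run`,
#'   `Nmean`, `Nmin`, `Lambda`, `return_time`, `n_redraws`.
#'   `glance()` summarises mean return times per ensemble.
#' @export
pulse_recovery_experiment <- function(n = 10, depth = 0.4, n_seeds = 5,
                                      m_mut = 0.1, m_zero = 0,
                                      sigma = 0.05, species = 1,
                                      eps = 0.01, t_end = 40, seed = NULL,
                                      max_attempts = 200) {
  run_one <- function(m, positive_only, ensemble, run) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_lvcomm(sprintf(
          "No usable %s community within %d attempts.", ensemble,
          max_attempts), "lvcomm_experiment_error")
      }
      x <- generate_gaussian(n = n, m = m, sigma = sigma,
                             positive_only = positive_only)
      eq <- tryCatch(suppressWarnings(solve_equilibrium(x)),
                     lvcomm_singular_error = function(e) NULL)
      if (is.null(eq) || !eq$feasible) next
      sp <- community_spectrum(community_matrix(eq))
      if (sp$Lambda >= 0) next
      if (eq$Nstar[species] <= depth) next
      N0 <- pulse_perturb(eq$Nstar, species, depth)
      traj <- tryCatch(
        integrate_lv(x, N0 = N0, t_end = t_end),
        lvcomm_blowup_error = function(e) NULL)
      if (is.null(traj)) next
      rt <- return_time(traj, eq$Nstar, eps = eps)
      if (is.na(rt)) next
      return(tibble::tibble(ensemble = ensemble, run = run,
                            Nmean = eq$Nmean, Nmin = eq$Nmin,
                            Lambda = sp$Lambda, return_time = rt,
                            n_redraws = attempts - 1L))
    }
  }
  out <- with_seed_if(seed, dplyr::bind_rows(
    purrr::map(seq_len(n_seeds),
               ~run_one(m_mut, TRUE, "mutualistic", .x)),
    purrr::map(seq_len(n_seeds),
               ~run_one(m_zero, FALSE, "mean-zero", .x))
  ))
  attr(out, "depth") <- depth
  class(out) <- c("lv_pulse_experiment", class(out))
  out
}

#' @method glance lv_pulse_experiment
#' @export
glance.lv_pulse_experiment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$ensemble) |>
    dplyr::summarise(mean_return_time = mean(.data$return_time),
                     mean_Nmean = mean(.data$Nmean),
                     mean_Lambda = mean(.data$Lambda),
                     runs = dplyr::n(), .groups = "drop")
}

#' @method autoplot lv_pulse_experiment
#' @export
autoplot.lv_pulse_experiment <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$ensemble,
                               y = .data$return_time)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "return time") +
    ggplot2::theme_minimal()
}
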