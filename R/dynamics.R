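#' Integrate the Lotka-Volterra dynamics
#'
#' Solves `dN_i/dt = N_i (r_i + sum_j a_ij N_j)` on `[0, t_end]` with an
#' adaptive explicit Runge-Kutta integrator (deSolve's `ode45`; the
#' weak-interaction communities studied here are non-stiff), reporting the
#' solution on a regular grid. Densities that exceed `blowup_cap` (or go
#' non-finite) terminate the run with an error naming the first diverging
#' species.
#'
#' @param A An `"interaction_matrix"` or square matrix.
#' @param r Growth rates (default all +1).
#' @param N0 Non-negative initial densities.
#' @param t_end Final time (> 0, model time units).
#' @param n_steps Number of grid intervals for the dense output.
#' @param rtol,atol Relative / absolute integration tolerances.
#' @param blowup_cap Density above which the run is declared divergent.
#' @param method deSolve method name.
#' @return An object of class `"lv_trajectory"`: `times`, matrix `N`
#'   (rows = times, columns = species), plus `A`, `r`, `N0`.
#' @examples
#' traj <- integrate_lv(matrix(-1), N0 = 0.5, t_end = 5)
#' max(abs(traj$N[, 1] - 1 / (1 + exp(-traj$times))))  # logistic closed form
#' @export
integrate_lv <- function(A, r = NULL, N0, t_end, n_steps = 400,
                         rtol = 1e-8, atol = 1e-10, blowup_cap = 1e6,
                         method = "ode45") {
  M <- as_lv_matrix(A)
  n <- nrow(M)
  r <- r %||% rep(1, n)
  if (length(N0) != n || length(r) != n) {
    stop_lvcomm("`N0` and `r` must have one entry per species.",
                "lvcomm_shape_error")
  }
  if (any(N0 < 0)) {
    stop_lvcomm("Initial densities must be non-negative.",
                "lvcomm_parameter_error")
  }
  if (t_end <= 0) stop_lvcomm("`t_end` must be > 0.", "lvcomm_parameter_error")
  times <- seq(0, t_end, length.out = n_steps + 1)
  deriv <- function(t, N, parms) list(N * (r + drop(M %*% N)))
  out <- suppressWarnings(
    deSolve::ode(y = as.numeric(N0), times = times, func = deriv,
                 parms = NULL, method = method, rtol = rtol, atol = atol)
  )
  Nmat <- unname(as.matrix(out[, -1, drop = FALSE]))
  bad <- !is.finite(Nmat) | Nmat > blowup_cap
  if (any(bad) || nrow(Nmat) < length(times)) {
    if (any(bad)) {
      first_row <- min(which(rowSums(bad) > 0))
      sp <- min(which(bad[first_row, ]))
    } else {
      sp <- NA_integer_
    }
    stop_lvcomm(sprintf(
      "Trajectory blow-up: species %s exceeded the cap (%g).",
      ifelse(is.na(sp), "?", sp), blowup_cap), "lvcomm_blowup_error")
  }
  structure(
    list(times = times, N = Nmat, A = M, r = r, N0 = as.numeric(N0)),
    class = "lv_trajectory"
  )
}

#' @export
print.lv_trajectory <- function(x, ...) {
  cat(sprintf("<lv_trajectory> %d species, %d time points on [0, %g]\n",
              ncol(x$N), length(x$times), max(x$times)))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x An `"lv_trajectory"`.
#' @param Nstar Optional equilibrium vector; when given, a `deviation`
#'   column (`N - N*`) is added, the quantity plotted in
#'   perturbation-recovery figures.
#' @param ... Unused.
#' @return A tibble with `time`, `species`, `N` (and optionally
#'   `deviation`).
#' @method tidy lv_trajectory
#' @export
tidy.lv_trajectory <- function(x, Nstar = NULL, ...) {
  out <- tibble::tibble(
    time = rep(x$times, times = ncol(x$N)),
    species = rep(seq_len(ncol(x$N)), each = length(x$times)),
    N = as.vector(x$N)
  )
  if (!is.null(Nstar)) {
    out$deviation <- out$N - Nstar[out$species]
  }
  out
}

#' Plot trajectories as deviations from equilibrium
#'
#' @param object An `"lv_trajectory"`.
#' @param Nstar Optional equilibrium vector; if supplied the y-axis is the
#'   deviation `N - N*` (equilibrium drawn at zero), otherwise raw
#'   density.
#' @param ... Unused.
#' @return A ggplot with one line per species.
#' @method autoplot lv_trajectory
#' @export
autoplot.lv_trajectory <- function(object, Nstar = NULL, ...) {
  dat <- tidy(object, Nstar = Nstar)
  yvar <- if (is.null(Nstar)) "N" else "deviation"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data[[yvar]],
                                    group = .data$species)) +
    ggplot2::geom_hline(yintercept = if (is.null(Nstar)) NA else 0,
                        linetype = 2, colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time", y = if (is.null(Nstar)) "density N"
                                  else "deviation from equilibrium") +
    ggplot2::theme_minimal()
}

#' Pulse perturbation of an equilibrium
#'
#' Depresses the chosen species by `depth` density units from their
#' equilibrium values, the classical pulse disturbance after which the
#' unforced dynamics relax back.
#'
#' @param Nstar Equilibrium density vector.
#' @param species Indices of the perturbed species.
#' @param depth Depression in density units; must be strictly less than
#'   every perturbed species' equilibrium density.
#' @return The initial-condition vector, with the perturbed indices in
#'   attribute `"perturbed"`.
#' @examples
#' pulse_perturb(c(2, 2), species = 1, depth = 0.4)  # c(1.6, 2)
#' @export
pulse_perturb <- function(Nstar, species, depth) {
  species <- as.integer(species)
  if (any(species < 1 | species > length(Nstar))) {
    stop_lvcomm("`species` indices out of range.", "lvcomm_shape_error")
  }
  if (depth < 0) stop_lvcomm("`depth` must be >= 0.", "lvcomm_parameter_error")
  if (any(Nstar[species] <= depth)) {
    stop_lvcomm(
      "Infeasible pulse: `depth` must be < N* for every perturbed species.",
      "lvcomm_pulse_error")
  }
  N0 <- as.numeric(Nstar)
  N0[species] <- N0[species] - depth
  attr(N0, "perturbed") <- species
  N0
}

#' Return time to an equilibrium band
#'
#' The first sampled time after which every monitored species stays
#' within `eps` (absolute density units) of its equilibrium for the rest
#' of the trajectory. By default only the perturbed species (recorded by
#' [pulse_perturb()]) are monitored, matching per-species recovery plots.
#'
#' @param traj An `"lv_trajectory"`.
#' @param Nstar Equilibrium density vector.
#' @param eps Band half-width (default 0.01 density units).
#' @param species Species to monitor; defaults to the trajectory's
#'   perturbed set, or all species when none is recorded.
#' @return The return time (0 for an unperturbed trajectory). If the band
#'   is never permanently entered the result is `NA` with attribute
#'   `censored = TRUE` and a warning.
#' @export
return_time <- function(traj, Nstar, eps = 0.01, species = NULL) {
  stopifnot(inherits(traj, "lv_trajectory"))
  species <- species %||% attr(traj$N0, "perturbed") %||% seq_len(ncol(traj$N))
  dev <- abs(traj$N[, species, drop = FALSE] -
               rep(Nstar[species], each = length(traj$times)))
  worst <- apply(dev, 1, max)
  outside <- worst > eps
  if (!any(outside)) return(0)
  last_bad <- max(which(outside))
  if (last_bad == length(traj$times)) {
    rlang::warn("Trajectory never settled into the band; result censored.")
    return(structure(NA_real_, censored = TRUE))
  }
  traj$times[last_bad + 1]
}

## Log Euclidean distance to equilibrium, trimmed above the numerical
## noise floor; shared by the phase fit and the tail-rate estimate.
log_distance <- function(traj, Nstar, floor_frac = 1e-9) {
  d <- sqrt(rowSums((traj$N - rep(Nstar, each = length(traj$times)))^2))
  floor <- max(d[1] * floor_frac, 1e-13)
  keep <- d > floor
  ## stop at the first point below the floor: beyond it is solver noise
  if (any(!keep)) keep[min(which(!keep)):length(keep)] <- FALSE
  list(t = traj$times[keep], logd = log(d[keep]), d = d[keep])
}

#' Exponential decay rate of the distance to equilibrium
#'
#' Least-squares slope of `log ||N(t) - N*||` over a time window,
#' returned as a positive rate. With the default window (the final 40%
#' of usable points) it estimates the asymptotic rate, which for a small
#' pulse converges to `|Lambda|` of the community matrix.
#'
#' @param traj An `"lv_trajectory"`.
#' @param Nstar Equilibrium density vector.
#' @param t_min,t_max Optional time window; defaults to the tail.
#' @return Positive decay rate (per unit time).
#' @export
decay_rate <- function(traj, Nstar, t_min = NULL, t_max = NULL) {
  ld <- log_distance(traj, Nstar)
  if (length(ld$t) < 3) {
    stop_lvcomm("Too few points above the noise floor to fit a rate.",
                "lvcomm_fit_error")
  }
  t_min <- t_min %||% ld$t[ceiling(0.6 * length(ld$t))]
  t_max <- t_max %||% max(ld$t)
  sel <- ld$t >= t_min & ld$t <= t_max
  if (sum(sel) < 3) {
    stop_lvcomm("Fewer than 3 points in the requested window.",
                "lvcomm_fit_error")
  }
  -unname(coef(lm(ld$logd[sel] ~ ld$t[sel]))[2])
}

#' Two-phase recovery rates after a pulse
#'
#' After a sizeable pulse the distance to equilibrium typically decays in
#' two phases: a fast initial contraction governed by the large-magnitude
#' bulk eigenvalues, then a slow crawl along the outlier eigendirection at
#' rate `|Lambda|`. This fits `log ||N(t) - N*||` with the best
#' two-segment least-squares line (change point chosen by total SSE) and
#' reports both slopes as positive rates. When the two-segment fit barely
#' improves on a single line (or too few points are available) a
#' single-phase report is returned with both rates equal.
#'
#' @param traj An `"lv_trajectory"` started from a pulsed state.
#' @param Nstar Equilibrium density vector.
#' @param Lambda Optional leading eigenvalue for reference (phase-2 rate
#'   should approach `|Lambda|`).
#' @param bulk_center Optional bulk centre for reference (phase-1 rate
#'   should be of order `|Re(bulk_center)|`).
#' @param min_points Minimum points per segment.
#' @return An object of class `"recovery_report"`: `phase1_rate`,
#'   `phase2_rate`, `breakpoint` (time), `n_phases`, and the supplied
#'   references.
#' @export
recovery_phases <- function(traj, Nstar, Lambda = NULL, bulk_center = NULL,
                            min_points = 5) {
  ld <- log_distance(traj, Nstar)
  K <- length(ld$t)
  single_slope <- function(sel) -unname(coef(lm(ld$logd[sel] ~ ld$t[sel]))[2])
  make <- function(p1, p2, brk, phases) {
    structure(list(phase1_rate = p1, phase2_rate = p2, breakpoint = brk,
                   n_phases = phases, Lambda = Lambda,
                   bulk_center = bulk_center),
              class = "recovery_report")
  }
  if (K < 2 * min_points + 1) {
    r <- single_slope(seq_len(K))
    return(make(r, r, NA_real_, 1L))
  }
  sse <- function(sel) {
    f <- lm(ld$logd[sel] ~ ld$t[sel])
    sum(f$residuals^2)
  }
  cand <- seq(min_points, K - min_points)
  total <- vapply(cand, function(cp) {
    sse(seq_len(cp)) + sse(seq(cp + 1, K))
  }, numeric(1))
  cp <- cand[which.min(total)]
  sse1 <- sse(seq_len(K))
  p1 <- single_slope(seq_len(cp))
  p2 <- single_slope(seq(cp + 1, K))
  ## a genuine second phase must explain most of the single-line misfit
  ## and separate the two contraction rates
  same_rate <- abs(p1 - p2) < 0.1 * max(abs(p1), abs(p2))
  if (min(total) > 0.5 * sse1 || sse1 < 1e-8 || same_rate) {
    r <- single_slope(seq_len(K))
    return(make(r, r, NA_real_, 1L))
  }
  make(p1, p2, ld$t[cp], 2L)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d phase(s)\n", x$n_phases),
      sprintf("  phase 1 rate = %.4g, phase 2 rate = %.4g, break at t = %s\n",
              x$phase1_rate, x$phase2_rate,
              if (is.na(x$breakpoint)) "-" else format(x$breakpoint,
                                                       digits = 4)),
      sep = "")
  invisible(x)
}

#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(phase1_rate = x$phase1_rate, phase2_rate = x$phase2_rate,
                 breakpoint = x$breakpoint, n_phases = x$n_phases,
                 Lambda = x$Lambda %||% NA_real_,
                 bulk_center_re = if (is.null(x$bulk_center)) NA_real_
                                  else Re(x$bulk_center))
}
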