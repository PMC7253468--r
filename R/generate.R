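## Unordered pairs i < j in column-major (upper-triangle) order, matching
## which(upper.tri(.)): the fixed order underpins the reproducibility
## contract (same seed, same matrix) and the deterministic uniform model.
pair_index <- function(n) {
  j <- rep.int(seq_len(n), times = seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  list(i = i, j = j, np = (n * (n - 1L)) %/% 2L)
}

new_interaction_matrix <- function(A, params, pair_i, pair_j, pair_type) {
  structure(
    list(A = A, params = params,
         pairs = tibble::tibble(i = pair_i, j = pair_j, type = pair_type)),
    class = "interaction_matrix"
  )
}

## Label a pair by the realised signs of its two coefficients.
sign_pair_label <- function(aij, aji) {
  dplyr::case_when(
    aij == 0 & aji == 0 ~ "absent",
    aij > 0 & aji > 0 ~ "mutualistic",
    aij < 0 & aji < 0 ~ "competitive",
    .default = "exploitative"
  )
}

#' Generate a random interaction matrix with a set proportion of mutualists
#'
#' Draws an `n x n` Lotka-Volterra interaction matrix in which the
#' proportion of interacting pairs that are mutualistic (+/+) is
#' controlled directly, the remainder being "background" pairs of
#' exploitative (+/-), competitive (-/-) or random-sign type. Each
#' unordered species pair is retained with probability `C` (otherwise both
#' coefficients are zero); retained pairs are labelled mutualistic with
#' probability `P`; every nonzero magnitude is an independent half-normal
#' draw `sigma * |N(0,1)|`; signs follow the pair type, with the +/-
#' orientation of exploitative pairs chosen uniformly at random. The
#' diagonal (intraspecific regulation) is fixed at -1, the scaling under
#' which growth rates `r = 1` give the community its natural units.
#'
#' The two magnitudes of a pair are drawn independently; only their signs
#' are coupled by the pair type.
#'
#' @param params A [gen_params()] object; `m` is ignored here (the
#'   effective mean of a nonzero entry of mutualistic type is
#'   `sigma * sqrt(2/pi)`).
#'
#' @return An object of class `"interaction_matrix"`: a list with elements
#'   `A` (the matrix), `params`, and `pairs` (a tibble of unordered pairs
#'   `i < j` with their realised `type` in mutualistic / exploitative /
#'   competitive / absent).
#' @examples
#' x <- generate_chen_cohen(gen_params(n = 10, P = 0.5, C = 0.7,
#'                                     sigma = 0.02, seed = 1))
#' table(x$pairs$type)
#' @export
generate_chen_cohen <- function(params) {
  stopifnot(inherits(params, "gen_params"))
  with_seed_if(params$seed, {
    n <- params$n
    pr <- pair_index(n)
    np <- pr$np
    ## fixed draw order: retention, type, two magnitudes, two sign streams
    retained <- runif(np) < params$C
    mutual <- runif(np) < params$P
    mag_ij <- params$sigma * abs(rnorm(np))  # effect of j on i (upper, i < j)
    mag_ji <- params$sigma * abs(rnorm(np))
    orient <- sample(c(1, -1), np, replace = TRUE)
    sign2 <- sample(c(1, -1), np, replace = TRUE)

    s_ij <- rep(1, np)
    s_ji <- rep(1, np)
    bg <- !mutual
    if (params$background == "exploitative") {
      s_ij[bg] <- orient[bg]
      s_ji[bg] <- -orient[bg]
    } else if (params$background == "competitive") {
      s_ij[bg] <- -1
      s_ji[bg] <- -1
    } else {
      s_ij[bg] <- orient[bg]
      s_ji[bg] <- sign2[bg]
    }

    a_ij <- ifelse(retained, s_ij * mag_ij, 0)
    a_ji <- ifelse(retained, s_ji * mag_ji, 0)

    A <- matrix(0, n, n)
    A[cbind(pr$i, pr$j)] <- a_ij
    A[cbind(pr$j, pr$i)] <- a_ji
    diag(A) <- -1

    type <- dplyr::case_when(
      !retained ~ "absent",
      mutual ~ "mutualistic",
      params$background == "random" ~ sign_pair_label(a_ij, a_ji),
      .default = params$background
    )
    ## zero half-normal draws (probability 0) would break the sign labels
    type[retained & (a_ij == 0 | a_ji == 0)] <-
      sign_pair_label(a_ij, a_ji)[retained & (a_ij == 0 | a_ji == 0)]

    new_interaction_matrix(A, params, pr$i, pr$j, type)
  })
}

#' Deterministic uniform-model interaction matrix
#'
#' The "uniform model" skeleton: every interacting pair has both
#' coefficients equal to `+m` and the diagonal is -1. With `C = P = 1`
#' every off-diagonal entry equals `m` (the "regular model"), for which
#' the equilibrium has the closed form `1 / (1 - (n - 1) m)` and
#' feasibility requires `m < 1/(n - 1)`. For `C * P < 1` the first
#' `round(C * P * n(n-1)/2)` pairs in upper-triangle column-major order
#' are set, a deterministic stand-in for the expected interaction count.
#'
#' @param n Species count.
#' @param m Interaction strength assigned to each set pair.
#' @param C,P Connectance and mutualistic proportion; only their product
#'   matters here.
#' @return An `"interaction_matrix"`.
#' @examples
#' generate_uniform(n = 3, m = 0.1)$A
#' @export
generate_uniform <- function(n, m, C = 1, P = 1) {
  params <- gen_params(n = n, P = P, C = C, sigma = 0, m = m)
  pr <- pair_index(params$n)
  k <- round(C * P * pr$np)
  set <- seq_len(pr$np) <= k
  A <- matrix(0, n, n)
  A[cbind(pr$i[set], pr$j[set])] <- m
  A[cbind(pr$j[set], pr$i[set])] <- m
  diag(A) <- -1
  type <- ifelse(set & m != 0,
                 ifelse(m > 0, "mutualistic", "competitive"),
                 "absent")
  new_interaction_matrix(A, params, pr$i, pr$j, type)
}

#' Gaussian random interaction matrix
#'
#' Off-diagonal coefficients are independent normal draws with mean `m`
#' and standard deviation `sigma`; with `positive_only = TRUE` each draw
#' is redrawn until positive (truncation at zero), producing a purely
#' mutualistic community as in pulse-recovery comparisons. Pairs are
#' removed together with probability `1 - C`; the diagonal is -1.
#'
#' @param n Species count.
#' @param m Mean interaction strength (must be positive when
#'   `positive_only = TRUE`).
#' @param sigma Standard deviation of the draws.
#' @param C Connectance (pair-level retention probability).
#' @param positive_only Redraw non-positive coefficients, making all
#'   interspecific interactions mutualistic.
#' @param seed Optional integer seed.
#' @return An `"interaction_matrix"`; pair types are labelled from the
#'   realised signs.
#' @examples
#' x <- generate_gaussian(n = 10, m = 0.1, sigma = 0.05,
#'                        positive_only = TRUE, seed = 1)
#' all(x$A[upper.tri(x$A) | lower.tri(x$A)] > 0)
#' @export
generate_gaussian <- function(n, m, sigma, C = 1, positive_only = FALSE,
                              seed = NULL) {
  params <- gen_params(n = n, P = if (positive_only) 1 else 0, C = C,
                       sigma = sigma, m = m, background = "random",
                       seed = seed)
  if (positive_only && m <= 0) {
    stop_lvcomm("`positive_only = TRUE` requires `m > 0`.",
                "lvcomm_parameter_error")
  }
  with_seed_if(params$seed, {
    pr <- pair_index(params$n)
    np <- pr$np
    retained <- runif(np) < C
    draw <- function(k) {
      x <- rnorm(k, mean = m, sd = sigma)
      if (positive_only) {
        while (any(x <= 0)) {
          bad <- x <= 0
          x[bad] <- rnorm(sum(bad), mean = m, sd = sigma)
        }
      }
      x
    }
    a_ij <- ifelse(retained, draw(np), 0)
    a_ji <- ifelse(retained, draw(np), 0)
    A <- matrix(0, n, n)
    A[cbind(pr$i, pr$j)] <- a_ij
    A[cbind(pr$j, pr$i)] <- a_ji
    diag(A) <- -1
    new_interaction_matrix(A, params, pr$i, pr$j,
                           sign_pair_label(a_ij, a_ji))
  })
}

#' @export
print.interaction_matrix <- function(x, ...) {
  p <- x$params
  cat(sprintf("<interaction_matrix> %d x %d (%s background)\n", p$n, p$n,
              p$background))
  tab <- table(factor(x$pairs$type,
                      levels = c("mutualistic", "exploitative",
                                 "competitive", "absent")))
  cat("pairs:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy an interaction matrix into one row per species pair
#'
#' @param x An `"interaction_matrix"`.
#' @param ... Unused.
#' @return A tibble with columns `i`, `j` (`i < j`), `a_ij`, `a_ji`, `type`.
#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) {
  dplyr::mutate(x$pairs,
                a_ij = x$A[cbind(.data$i, .data$j)],
                a_ji = x$A[cbind(.data$j, .data$i)],
                .before = "type")
}

## Accept either an interaction_matrix or a bare square matrix.
as_lv_matrix <- function(A) {
  if (inherits(A, "interaction_matrix")) A <- A$A
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop_lvcomm("`A` must be a square matrix or an interaction_matrix.",
                "lvcomm_shape_error")
  }
  A
}

#' Write / read an interaction matrix as plain text
#'
#' The matrix is stored as whitespace-delimited dense rows; the generation
#' parameters travel in a JSON sidecar at `<path>.json`. On reading, pair
#' types are reconstructed from the realised signs.
#'
#' @param x An `"interaction_matrix"`.
#' @param path Output file for the matrix.
#' @return `write_interaction_matrix()` returns `path` invisibly;
#'   `read_interaction_matrix()` returns an `"interaction_matrix"`.
#' @export
write_interaction_matrix <- function(x, path) {
  stopifnot(inherits(x, "interaction_matrix"))
  utils::write.table(format(x$A, digits = 17, trim = TRUE, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  p <- x$params
  jsonlite::write_json(
    list(n = p$n, P = p$P, C = p$C, sigma = p$sigma, m = p$m,
         background = p$background, seed = p$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  A <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(A) <- NULL
  side <- paste0(path, ".json")
  params <- if (file.exists(side)) {
    p <- jsonlite::read_json(side, simplifyVector = TRUE)
    gen_params(n = p$n, P = p$P, C = p$C, sigma = p$sigma, m = p$m,
               background = p$background, seed = p$seed)
  } else {
    gen_params(n = nrow(A), P = 0, C = 1, sigma = 0)
  }
  pr <- pair_index(nrow(A))
  new_interaction_matrix(A, params, pr$i, pr$j,
                         sign_pair_label(A[cbind(pr$i, pr$j)],
                                         A[cbind(pr$j, pr$i)]))
}
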