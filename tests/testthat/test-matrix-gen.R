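test_that("parameter validation rejects invalid probabilities and scales", {
  expect_error(gen_params(n = 1), class = "lvcomm_parameter_error")
  expect_error(gen_params(n = 5, P = 1.2), class = "lvcomm_parameter_error")
  expect_error(gen_params(n = 5, C = -0.1), class = "lvcomm_parameter_error")
  expect_error(gen_params(n = 5, sigma = -1), class = "lvcomm_parameter_error")
  expect_error(generate_gaussian(n = 5, m = 0, sigma = 0.1,
                                 positive_only = TRUE),
               class = "lvcomm_parameter_error")
})

test_that("P = 1, C = 1 gives an all-positive off-diagonal; C = 0 gives -I", {
  x <- generate_chen_cohen(gen_params(n = 5, P = 1, C = 1, sigma = 0.02,
                                      seed = 11))
  expect_identical(diag(x$A), rep(-1, 5))
  expect_true(all(off_diag(x$A) > 0))
  expect_true(all(x$pairs$type == "mutualistic"))

  y <- generate_chen_cohen(gen_params(n = 5, P = 0.5, C = 0, sigma = 0.02,
                                      seed = 12))
  expect_identical(y$A, diag(-1, 5))
  expect_true(all(y$pairs$type == "absent"))
})

test_that("uniform generator matches its closed description", {
  u <- generate_uniform(n = 3, m = 0.1)
  expect_identical(diag(u$A), rep(-1, 3))
  expect_true(all(off_diag(u$A) == 0.1))
  expect_identical(generate_uniform(n = 3, m = 0)$A, diag(-1, 3))
})

test_that("gaussian generator: positivity flag, degenerate case, zero mean", {
  g <- generate_gaussian(n = 10, m = 0.1, sigma = 0.05, positive_only = TRUE,
                         seed = 21)
  expect_true(all(off_diag(g$A) > 0))
  expect_identical(generate_gaussian(n = 10, m = 0, sigma = 0, seed = 22)$A,
                   diag(-1, 10))
  # sample mean of off-diagonals near 0 within 3 standard errors
  withr::with_seed(23, {
    draws <- off_diag(generate_gaussian(n = 101, m = 0, sigma = 0.05)$A)
  })
  se <- 0.05 / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("nonzero magnitudes follow the half-normal with mean sigma*sqrt(2/pi)", {
  sigma <- 0.02
  withr::with_seed(31, {
    vals <- unlist(lapply(1:60, function(k) {
      A <- generate_chen_cohen(gen_params(n = 100, P = 0.5, C = 0.7,
                                          sigma = sigma))$A
      abs(off_diag(A)[off_diag(A) != 0])
    }))
  })
  expected <- sigma * sqrt(2 / pi)           # closed-form half-normal mean
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 4 * se)
})

test_that("sign pattern of every pair matches its recorded type", {
  for (bg in c("exploitative", "competitive", "random")) {
    x <- generate_chen_cohen(gen_params(n = 40, P = 0.4, C = 0.6,
                                        sigma = 0.02, background = bg,
                                        seed = 41))
    td <- tidy(x)
    expect_true(all(td$type[td$a_ij > 0 & td$a_ji > 0] == "mutualistic"))
    expect_true(all(td$type[td$a_ij < 0 & td$a_ji < 0] == "competitive"))
    expect_true(all(td$type[td$a_ij * td$a_ji < 0] == "exploitative"))
    expect_true(all(td$type[td$a_ij == 0 & td$a_ji == 0] == "absent"))
    expect_identical(diag(x$A), rep(-1, 40))
  }
  g <- generate_gaussian(n = 30, m = 0.05, sigma = 0.1, C = 0.5, seed = 42)
  tg <- tidy(g)
  expect_true(all((tg$type == "absent") == (tg$a_ij == 0 & tg$a_ji == 0)))
  expect_true(all(tg$type[tg$a_ij > 0 & tg$a_ji > 0] == "mutualistic"))
})

test_that("retention and mutualist fractions match C and P in expectation", {
  n <- 100; C <- 0.7; P <- 0.5; reps <- 500
  withr::with_seed(51, {
    counts <- vapply(seq_len(reps), function(k) {
      x <- generate_chen_cohen(gen_params(n = n, P = P, C = C, sigma = 0.02))
      retained <- x$pairs$type != "absent"
      c(retained = sum(retained),
        mutual = sum(x$pairs$type == "mutualistic"))
    }, numeric(2))
  })
  npairs <- n * (n - 1) / 2
  frac_retained <- sum(counts["retained", ]) / (reps * npairs)
  se_C <- sqrt(C * (1 - C) / (reps * npairs))
  expect_lt(abs(frac_retained - C), 3 * se_C)

  n_ret <- sum(counts["retained", ])
  frac_mutual <- sum(counts["mutual", ]) / n_ret
  se_P <- sqrt(P * (1 - P) / n_ret)
  expect_lt(abs(frac_mutual - P), 3 * se_P)
})

test_that("the same seed reproduces the matrix bit for bit", {
  p <- gen_params(n = 50, P = 0.3, C = 0.7, sigma = 0.02,
                  background = "random", seed = 99)
  expect_identical(generate_chen_cohen(p), generate_chen_cohen(p))
  expect_identical(generate_gaussian(n = 20, m = 0.1, sigma = 0.05,
                                     positive_only = TRUE, seed = 7),
                   generate_gaussian(n = 20, m = 0.1, sigma = 0.05,
                                     positive_only = TRUE, seed = 7))
  # a seeded call must not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
    generate_chen_cohen(p)
    after <- runif(1)
  })
  withr::with_seed(1, expected <- runif(2))
  expect_identical(c(before, after), expected)
})
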