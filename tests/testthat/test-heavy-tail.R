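test_that("pmf is normalized across all families and parameter sets", {
  specs <- list(
    dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004),
    dist_spec("truncated_powerlaw", alpha = 1.2, lam = 0.05),
    dist_spec("truncated_powerlaw", alpha = 0, lam = 0.3),
    dist_spec("powerlaw", alpha = 2.5),
    dist_spec("exponential", lam = 0.5),
    dist_spec("exponential", lam = 0.01),
    dist_spec("stretched_exponential", lam = 0.1, beta = 0.5),
    dist_spec("stretched_exponential", lam = 0.5, beta = 1.5),
    dist_spec("lognormal", mu = 1, sigma = 0.5),
    dist_spec("lognormal", mu = 2.5, sigma = 1.2)
  )
  for (s in specs) {
    # the pure power law needs a longer partial sum: its own tail beyond K
    # is ~ K^(1-alpha)/(alpha-1), which must sit below the tolerance
    K <- if (s$family == "powerlaw") 1e7 else 2e6
    mass <- sum(dist_pmf(s, 1:K))
    expect_equal(mass, 1, tolerance = 1e-10)
    expect_true(all(dist_pmf(s, 1:100) >= 0))
  }
  # finite support sums exactly
  u <- dist_spec("truncated_powerlaw", alpha = 0, lam = 0, support_max = 10)
  expect_equal(dist_pmf(u, 1:10), rep(0.1, 10), tolerance = 1e-12)
  expect_equal(sum(dist_pmf(dist_spec("exponential", lam = 0.5,
                                      support_max = 1000), 1:1000)),
               1, tolerance = 1e-10)
})

test_that("truncated power law pmf matches the closed-form ratio and decays monotonically", {
  s <- dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004)
  expect_equal(dist_pmf(s, 1) / dist_pmf(s, 2), 2^2.57 * exp(0.004),
               tolerance = 1e-10)
  for (par in list(c(0.5, 0), c(2, 0.01), c(3, 0.1))) {
    sp <- dist_spec("truncated_powerlaw", alpha = par[1],
                    lam = par[2], support_max = 500)
    p <- dist_pmf(sp, 1:500)
    expect_true(all(diff(p) < 0))
  }
})

test_that("log-pmf is consistent with pmf and finite deep in the tail", {
  specs <- list(
    dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004),
    dist_spec("lognormal", mu = 1, sigma = 0.5),
    dist_spec("exponential", lam = 0.2)
  )
  for (s in specs) {
    i <- 1:50
    expect_equal(dist_logpmf(s, i), log(dist_pmf(s, i)), tolerance = 1e-9)
  }
  tail_lp <- dist_logpmf(specs[[1]], 10000)
  expect_true(is.finite(tail_lp) && tail_lp < -20)
  # outside support: -Inf sentinel, pmf 0
  expect_identical(dist_logpmf(specs[[1]], 0), -Inf)
  u <- dist_spec("exponential", lam = 0.5, support_max = 10)
  expect_identical(dist_pmf(u, 11), 0)
  expect_identical(dist_logpmf(u, 11), -Inf)
})

test_that("invalid parameters are rejected", {
  expect_error(dist_spec("lognormal", mu = 1, sigma = -1), class = "spacerlaw_param_error")
  expect_error(dist_spec("exponential", lam = 0), class = "spacerlaw_param_error")
  expect_error(dist_spec("powerlaw", alpha = 0.9), class = "spacerlaw_param_error")
  expect_error(dist_spec("truncated_powerlaw", alpha = 0.5, lam = 0),
               class = "spacerlaw_param_error")
  expect_error(dist_spec("truncated_powerlaw", alpha = 2, lam = 0.1,
                         support_min = 0), class = "spacerlaw_param_error")
})

test_that("sampling is deterministic under seed and matches the pmf", {
  u <- dist_spec("truncated_powerlaw", alpha = 0, lam = 0, support_max = 10)
  x1 <- dist_rand(u, 1e5, seed = 11)
  x2 <- dist_rand(u, 1e5, seed = 11)
  expect_identical(x1, x2)
  # each class frequency within 5 binomial sigmas of 0.1
  freq <- tabulate(x1, 10) / 1e5
  sig <- sqrt(0.1 * 0.9 / 1e5)
  expect_true(all(abs(freq - 0.1) < 5 * sig))

  s <- dist_spec("truncated_powerlaw", alpha = 2.5, lam = 0.01)
  x <- dist_rand(s, 1e5, seed = 3)
  i <- 1:2e5
  mu_true <- sum(i * dist_pmf(s, i))
  var_true <- sum((i - mu_true)^2 * dist_pmf(s, i))
  expect_lt(abs(mean(x) - mu_true), 3 * sqrt(var_true / 1e5))
})

test_that("MLE recovers generating parameters and matches a grid-search oracle", {
  # grid-search oracle on data confined to {1..50}
  s <- dist_spec("truncated_powerlaw", alpha = 2.3, lam = 0.05)
  x <- dist_rand(s, 3000, seed = 5)
  x <- x[x <= 50]
  alphas <- seq(1.6, 3.0, by = 0.01)
  lams <- seq(0, 0.12, by = 0.002)
  slx <- sum(log(x)); sx <- sum(x); n <- length(x)
  ll <- outer(alphas, lams, function(a, l) {
    zz <- mapply(function(ai, li) oracle_tpl_norm(ai, li, K = 5000), a, l)
    -a * slx - l * sx - n * log(zz)
  })
  best <- arrayInd(which.max(ll), dim(ll))
  fit <- fit_heavy_tail(x, "truncated_powerlaw")
  expect_lt(abs(fit$spec$params$alpha - alphas[best[1]]), 0.02)
  expect_lt(abs(fit$spec$params$lam - lams[best[2]]), 0.004)
  expect_equal(fit$loglik,
               oracle_tpl_loglik(x, fit$spec$params$alpha, fit$spec$params$lam),
               tolerance = 1e-6)

  # exponent recovery is nearly unbiased across the alpha range
  for (a in c(1.5, 2.0, 2.5, 3.0)) {
    gen <- dist_spec("truncated_powerlaw", alpha = a, lam = 0.004)
    est <- vapply(1:3, function(sd) {
      xx <- dist_rand(gen, 1e5, seed = 100 * a + sd)
      suppressWarnings(fit_heavy_tail(xx, "truncated_powerlaw"))$spec$params$alpha
    }, numeric(1))
    expect_lt(abs(mean(est) - a), 0.02)
  }
})

test_that("fit metadata is coherent: loglik, CI, weighted fitting", {
  s <- dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004)
  x <- dist_rand(s, 2e4, seed = 9)
  fit <- fit_heavy_tail(x, "truncated_powerlaw")
  expect_equal(fit$loglik, sum(dist_logpmf(fit$spec, x)), tolerance = 1e-8)
  expect_true(fit$alpha_ci[1] < fit$spec$params$alpha &&
                fit$spec$params$alpha < fit$alpha_ci[2])
  # weighted fit on the tabulated sample equals the raw fit
  tab <- table(x)
  fit_w <- fit_heavy_tail(as.integer(names(tab)), "truncated_powerlaw",
                          weights = as.numeric(tab))
  expect_equal(fit_w$spec$params$alpha, fit$spec$params$alpha, tolerance = 1e-4)
  expect_equal(fit_w$loglik, fit$loglik, tolerance = 1e-6)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha", "lam"))
  expect_identical(glance(fit)$family, "truncated_powerlaw")
})

test_that("degenerate or insufficient data raise fit errors", {
  expect_error(fit_heavy_tail(rep(7L, 100), "truncated_powerlaw"),
               class = "spacerlaw_fit_error")
  expect_error(fit_heavy_tail(c(1L, 2L, 3L), "truncated_powerlaw"),
               class = "spacerlaw_fit_error")
})

test_that("the true family attains the best likelihood on its own data", {
  gen <- dist_spec("exponential", lam = 0.2)
  x <- dist_rand(gen, 2e4, seed = 21)
  ll <- vapply(c("exponential", "stretched_exponential", "lognormal",
                 "truncated_powerlaw"),
               function(f) suppressWarnings(fit_heavy_tail(x, f))$loglik,
               numeric(1))
  # allow the two-parameter supersets a small in-sample edge
  expect_true(all(ll["exponential"] >= ll - 3))
  expect_lt(abs(fit_heavy_tail(x, "exponential")$spec$params$lam - 0.2), 0.01)
})
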