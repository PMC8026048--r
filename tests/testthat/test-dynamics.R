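test_that("q and nu profiles evaluate the linear forms and stay monotone", {
  N <- 100
  expect_equal(q_of_i("linear", 1, N), 0)
  expect_equal(q_of_i("linear", N, N), (N - 1) / N)
  expect_equal(nu_of_i("linear", 1, N), 1)
  expect_equal(nu_of_i("linear", N, N), 1 / N)
  for (steep in c(0.01, 0.1, 1)) {
    q <- q_of_i("logistic", 1:N, N, mid = 37, steep = steep)
    expect_true(all(diff(q) >= 0))
    expect_true(all(q >= 0 & q <= 1))
  }
  for (w in c(10, 50, 200)) {
    nu <- nu_of_i("gaussian", 1:N, N, width = w)
    expect_true(all(diff(nu) < 0))
  }
  expect_error(q_of_i("linear", 0, N), class = "spacerlaw_param_error")
  expect_error(q_of_i("weird", 5, N), class = "spacerlaw_config_error")
})

test_that("geometric gain law has the right mass, mean and limits", {
  expect_equal(gain_pmf(1, 0:1), c(1 / 2, 1 / 4))
  expect_equal(gain_pmf(0, 0:3), c(1, 0, 0, 0))
  k <- 0:5000
  for (mu in c(0.1, 1, 10)) {
    expect_equal(sum(gain_pmf(mu, k)), 1, tolerance = 1e-12)
    expect_equal(sum(k * gain_pmf(mu, k)), mu, tolerance = 1e-9)
  }
  expect_error(gain_pmf(-1, 0), class = "spacerlaw_param_error")
})

test_that("dynamics_params enforces the model constraints", {
  expect_error(dynamics_params(s = 0.5, g = 0.4, h = 0.9),
               class = "spacerlaw_param_error")
  expect_error(dynamics_params(p = 1.2), class = "spacerlaw_param_error")
  expect_error(dynamics_params(S_L = 0), class = "spacerlaw_param_error")
  expect_error(dynamics_params(N = 1), class = "spacerlaw_param_error")
  # default coupling 100 mu_k = mu_m = mu_n
  p <- dynamics_params(mu_n = 14)
  expect_equal(p$mu_m, 14)
  expect_equal(p$mu_k, 0.14)
})

test_that("infection matrix reproduces hand-computed entries and stays substochastic", {
  # no encounters: identity
  p0 <- dynamics_params(N = 5, p = 0)
  expect_equal(infection_matrix(p0), diag(5))
  # direct evaluation: p=1, q=1, h=1, mu_n=1 -> A1[2,3] = P(mu=1, k=1) = 1/4
  p1 <- dynamics_params(N = 5, p = 1, h = 1, s = 0.4, g = 0.7, mu_n = 1,
                        mu_m = 1, mu_k = 0.01,
                        q_profile = "constant", q_const = 1)
  A1 <- infection_matrix(p1)
  expect_equal(A1[2, 3], 1 / 4)
  for (boundary in c("lethal", "absorb")) {
    pp <- dynamics_params(N = 40, mu_n = 2, boundary = boundary)
    A <- infection_matrix(pp)
    death <- 1 - rowSums(A)
    expect_true(all(death >= -1e-12 & death <= 1))
    expect_true(all(A >= 0))
  }
})

test_that("death probability does not increase with q when h >= g >= s", {
  qs <- seq(0, 1, by = 0.05)
  deaths <- vapply(qs, function(q) {
    pp <- dynamics_params(N = 60, p = 0.7, h = 0.9, g = 0.6, s = 0.3,
                          mu_n = 2, q_profile = "constant", q_const = q)
    1 - rowSums(infection_matrix(pp))[10]
  }, numeric(1))
  expect_true(all(diff(deaths) <= 1e-12))
})

test_that("replication scaling satisfies its defining balance", {
  nu <- rep(1, 10)
  f_full <- rep(10, 10)
  expect_equal(compute_scaling(f_full, nu, 100), 0)
  expect_equal(compute_scaling(f_full / 2, nu, 100), 1)
  f <- runif(10, 0, 5)
  nnu <- compute_scaling(f, nu, 100)
  expect_gte(nnu, 0)
  expect_equal(sum(f) + nnu * sum(nu * f), 100)
  expect_error(compute_scaling(rep(0, 10), nu, 100),
               class = "spacerlaw_extinction_error")
})

test_that("replication matrix has exact row sums and the expected limits", {
  pp <- dynamics_params(N = 30, S_L = 1 / 8)
  nu <- nu_of_i("linear", 1:30, 30)
  A2 <- replication_matrix(pp, 0)
  expect_equal(A2, diag(30))
  A2 <- replication_matrix(pp, 0.4)
  expect_equal(rowSums(A2), 1 + 0.4 * nu, tolerance = 1e-12)
  expect_true(all(A2 >= 0))
  # vanishing loss fraction: daughters keep all spacers (diagonal mass)
  pp0 <- dynamics_params(N = 30, S_L = 1e-9)
  A20 <- replication_matrix(pp0, 0.4)
  expect_equal(diag(A20), 1 + 0.4 * nu, tolerance = 1e-6)
})

test_that("one full iteration matches exhaustive enumeration on N = 6", {
  for (boundary in c("lethal", "absorb")) {
    pars <- dynamics_params(N = 6, p = 0.6, h = 0.9, g = 0.5, s = 0.3,
                            mu_n = 1.5, mu_m = 1.2, mu_k = 0.1, S_L = 0.2,
                            F_const = 600, boundary = boundary)
    f <- c(100, 150, 120, 90, 80, 60)
    A1 <- infection_matrix(pars)
    D <- spacerlaw:::replication_kernel(pars)
    nu <- nu_of_i("linear", 1:6, 6)
    fh <- as.numeric(f %*% A1)
    n_nu <- compute_scaling(fh, nu, pars$F_const)
    f1 <- fh + n_nu * as.numeric(fh %*% D)
    oracle <- oracle_dynamics_step(pars, f)
    expect_equal(n_nu, oracle$n_nu, tolerance = 1e-12)
    expect_equal(f1, oracle$f, tolerance = 1e-10)
    expect_equal(sum(f1), pars$F_const, tolerance = 1e-9)
  }
})

test_that("iteration conserves the population and converges on a small system", {
  pars <- dynamics_params(N = 50, tol = 1e-12, max_iter = 5000)
  res <- run_dynamics(pars)
  expect_true(res$converged)
  expect_lt(res$drift, 1e-9)
  expect_equal(sum(res$distribution), 1, tolerance = 1e-12)
  expect_true(all(res$distribution >= 0))
  # converged means one further iteration moves the distribution < tol
  f <- res$distribution * pars$F_const
  step <- oracle_dynamics_step(pars, f)
  expect_lt(sum(abs(step$f - f)) / pars$F_const, pars$tol * 10)
})

test_that("frozen dynamics (p = 0) are returned as a degenerate fixed point", {
  pars <- dynamics_params(N = 20, p = 0)
  res <- run_dynamics(pars)
  expect_true(res$degenerate)
  expect_equal(res$n_nu_star, 0)
  expect_equal(res$distribution, rep(1 / 20, 20))
  eig <- stationary_eigen(pars, 0)
  expect_true(eig$degenerate)
})

test_that("eigenvector and iteration agree on the stationary distribution", {
  pars <- dynamics_params(N = 80, tol = 1e-12, max_iter = 20000)
  it <- run_dynamics(pars)
  eig <- stationary_eigen(pars, it$n_nu_star)
  expect_true(it$converged)
  expect_lt(sum(abs(eig$distribution - it$distribution)), 1e-6)
  # a wrong scaling is rejected
  expect_error(stationary_eigen(pars, it$n_nu_star * 2),
               class = "spacerlaw_scaling_error")
})

test_that("init validation and tidiers work", {
  pars <- dynamics_params(N = 10)
  expect_error(run_dynamics(pars, init = rep(1, 10)),
               class = "spacerlaw_param_error")
  res <- run_dynamics(dynamics_params(N = 30, max_iter = 3000))
  td <- tidy(res)
  expect_identical(names(td), c("spacer_count", "probability"))
  expect_equal(nrow(td), 30)
  gl <- glance(res)
  expect_true(gl$converged)
})

test_that("sweeps record per-point results and tolerate failures", {
  pars <- dynamics_params(N = 40, max_iter = 3000)
  empty <- sweep_dynamics(pars, "S_L", numeric())
  expect_equal(nrow(empty), 0)
  sw <- suppressWarnings(sweep_dynamics(pars, "S_L", c(0.1, 2)))
  expect_equal(nrow(sw), 2)
  expect_false(is.na(sw$alpha[1]))
  expect_true(!is.na(sw$error[2])) # S_L = 2 violates the parameter constraints
  expect_error(sweep_dynamics(pars, "q_profile", 1:2),
               class = "spacerlaw_param_error")
})
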