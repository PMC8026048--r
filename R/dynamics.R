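# Discrete-time Markov-chain model of spacer gain and loss under phage
# pressure. Cells are grouped into classes i = 1..N by the number of spacers
# in their single CRISPR array; each iteration is an infection half-step
# (transition structure A1, substochastic: the row deficit is the per-class
# death probability) followed by a replication half-step that restores the
# population to the carrying capacity F_const.

#' Parameters of the spacer-array dynamics model
#'
#' Bundles the full parameter set of the two-stage Markov model: phage
#' encounter probability `p`; survival probabilities `h` (perfect spacer
#' match), `g` (inefficient spacer), `s` (no matching spacer), constrained to
#' `s <= g <= h`; mean spacer gains `mu_n` (perfect match, priming),
#' `mu_m` (inefficient match), `mu_k` (naive adaptation), with the default
#' coupling `100 mu_k = mu_m = mu_n`; loss fraction `S_L` so a daughter cell
#' of class `i` loses on average `S_L * i` spacers; and the class cap `N`.
#' The match probability profile `q_i` and replication-rate profile `nu_i`
#' control whether longer arrays are favored ("rich get richer") and
#' penalized (replication cost).
#'
#' @param p Probability of encountering a phage per iteration.
#' @param h Probability a perfectly matching spacer saves the cell.
#' @param g Probability an inefficient spacer saves the cell.
#' @param s Probability of surviving with no matching spacer.
#' @param mu_n,mu_m,mu_k Mean spacers gained in the perfect-match,
#'   inefficient-match and naive cases. `mu_m`/`mu_k` default to `mu_n` and
#'   `mu_n / 100`.
#' @param S_L Fraction of existing spacers lost by the daughter cell
#'   (0 < `S_L` < 1); the loss mean for class `i` is `S_L * i`.
#' @param N Maximum spacer count (number of classes).
#' @param F_const Total (constant) population size.
#' @param q_profile `"linear"` (`q_i = (i-1)/N`), `"constant"`, or
#'   `"logistic"` (monotone increasing sigmoid).
#' @param nu_profile `"linear"` (`nu_i = (N+1-i)/N`), `"constant"` (1), or
#'   `"gaussian"` (`exp(-(i/width)^2)`).
#' @param q_const,q_mid,q_steep Profile parameters: constant value of `q`;
#'   logistic midpoint (class index) and steepness.
#' @param nu_const,nu_width Constant value of `nu`; Gaussian width.
#' @param tol L1 stationarity tolerance on the normalized distribution.
#' @param max_iter Iteration cap.
#' @param include_zero_gain Whether zero-gain survivals (the k = 0 mass of
#'   the geometric gain laws) stay on the diagonal of the infection matrix
#'   (default) or the gain laws are conditioned on gaining at least one
#'   spacer.
#' @param boundary Handling of acquisition events that would push an array
#'   past the cap `N`: `"lethal"` (default) removes that probability mass —
#'   the cap is a hard physical limit and overshooting transitions count as
#'   deaths, compensated by the replication rescaling — while `"absorb"`
#'   accumulates the excess in class `N`. With `"absorb"` the top class
#'   becomes a near-absorbing sink under the rich-get-richer profiles
#'   (long-array cells essentially never die), which produces a boundary
#'   atom instead of the decaying distributions the model is meant to
#'   study.
#' @return An object of class `dynamics_params`.
#' @examples
#' params <- dynamics_params(N = 100)
#' @export
dynamics_params <- function(p = 0.7, h = 1, s = 0.4, g = 0.7,
                            mu_n = 10, mu_m = mu_n, mu_k = mu_n / 100,
                            S_L = 1 / 8, N = 1000L, F_const = 1e6,
                            q_profile = c("linear", "constant", "logistic"),
                            nu_profile = c("linear", "constant", "gaussian"),
                            q_const = 0.5, q_mid = N / 2, q_steep = 10 / N,
                            nu_const = 1, nu_width = N / 2,
                            tol = 1e-10, max_iter = 10000L,
                            include_zero_gain = TRUE,
                            boundary = c("lethal", "absorb")) {
  q_profile <- match.arg(q_profile)
  nu_profile <- match.arg(nu_profile)
  boundary <- match.arg(boundary)
  chk <- function(ok, msg) if (!ok) abort(msg, class = "spacerlaw_param_error")
  for (nm in c("p", "h", "s", "g")) {
    v <- get(nm)
    chk(is.numeric(v) && v >= 0 && v <= 1, sprintf("`%s` must be in [0, 1].", nm))
  }
  chk(s <= g && g <= h, "Survival probabilities must satisfy s <= g <= h.")
  for (nm in c("mu_n", "mu_m", "mu_k")) {
    chk(get(nm) >= 0, sprintf("`%s` must be >= 0.", nm))
  }
  chk(S_L > 0 && S_L < 1, "`S_L` must be in (0, 1).")
  chk(N >= 2, "`N` must be >= 2.")
  chk(F_const > 0, "`F_const` must be positive.")
  structure(
    list(p = p, h = h, s = s, g = g,
         mu_n = mu_n, mu_m = mu_m, mu_k = mu_k,
         S_L = S_L, N = as.integer(N), F_const = F_const,
         q_profile = q_profile, nu_profile = nu_profile,
         q_const = q_const, q_mid = q_mid, q_steep = q_steep,
         nu_const = nu_const, nu_width = nu_width,
         tol = tol, max_iter = as.integer(max_iter),
         include_zero_gain = include_zero_gain, boundary = boundary),
    class = "dynamics_params"
  )
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("<dynamics_params> N =", x$N, " F_const =", format(x$F_const), "\n")
  cat("  p =", x$p, " h =", x$h, " g =", x$g, " s =", x$s, "\n")
  cat("  mu_n =", x$mu_n, " mu_m =", x$mu_m, " mu_k =", x$mu_k,
      " S_L =", signif(x$S_L, 5), "\n")
  cat("  q:", x$q_profile, "  nu:", x$nu_profile, "\n")
  invisible(x)
}

#' Spacer-match and replication-rate profiles
#'
#' `q_of_i()` gives the probability that a class-`i` array contains a spacer
#' (exactly or inexactly) matching the infecting phage; `nu_of_i()` gives the
#' class replication rate before scaling. The linear forms are
#' `q_i = (i - 1)/N` and `nu_i = (N + 1 - i)/N`.
#'
#' @param profile Profile name (see [dynamics_params()]).
#' @param i Class index vector (1 to `N`).
#' @param N Number of classes.
#' @param const Constant value for the `"constant"` profile.
#' @param mid,steep Logistic midpoint and steepness.
#' @param width Gaussian width.
#' @return Numeric vector of probabilities (`q_of_i`) or rates (`nu_of_i`).
#' @examples
#' q_of_i("linear", 1:5, N = 5)
#' nu_of_i("linear", 1:5, N = 5)
#' @export
q_of_i <- function(profile, i, N, const = 0.5, mid = N / 2, steep = 10 / N) {
  if (any(i < 1 | i > N)) abort("`i` must lie in 1..N.", class = "spacerlaw_param_error")
  switch(profile,
    constant = rep(const, length(i)),
    linear = (i - 1) / N,
    logistic = 1 / (1 + exp(-steep * (i - mid))),
    abort(sprintf("Unknown q profile '%s'.", profile), class = "spacerlaw_config_error")
  )
}

#' @rdname q_of_i
#' @export
nu_of_i <- function(profile, i, N, const = 1, width = N / 2) {
  if (any(i < 1 | i > N)) abort("`i` must lie in 1..N.", class = "spacerlaw_param_error")
  switch(profile,
    constant = rep(const, length(i)),
    linear = (N + 1 - i) / N,
    gaussian = exp(-(i / width)^2),
    abort(sprintf("Unknown nu profile '%s'.", profile), class = "spacerlaw_config_error")
  )
}

params_q <- function(params) {
  q_of_i(params$q_profile, seq_len(params$N), params$N,
         const = params$q_const, mid = params$q_mid, steep = params$q_steep)
}

params_nu <- function(params) {
  nu_of_i(params$nu_profile, seq_len(params$N), params$N,
          const = params$nu_const, width = params$nu_width)
}

#' Geometric gain/loss mass function
#'
#' The number of spacers gained (or lost) in one event is modelled as a
#' discrete exponential: a geometric distribution on {0, 1, 2, ...} with
#' mean `mu`, \eqn{P(k) = \frac{1}{1+\mu}\left(\frac{\mu}{1+\mu}\right)^k}.
#' `mu = 0` is the degenerate point mass at 0.
#'
#' @param mu Mean number of spacers gained/lost (>= 0).
#' @param k Non-negative integer count(s).
#' @return Probability vector.
#' @examples
#' gain_pmf(1, 0:3) # 1/2, 1/4, 1/8, 1/16
#' @export
gain_pmf <- function(mu, k) {
  if (mu < 0) abort("`mu` must be >= 0.", class = "spacerlaw_param_error")
  if (any(k < 0 | k != floor(k))) {
    abort("`k` must be non-negative integers.", class = "spacerlaw_param_error")
  }
  if (mu == 0) return(as.numeric(k == 0))
  r <- mu / (1 + mu)
  (1 / (1 + mu)) * r^k
}

# survival P(K >= k) of the geometric gain law
gain_tail <- function(mu, k) {
  if (mu == 0) return(as.numeric(k <= 0))
  (mu / (1 + mu))^k
}

#' Infection transition matrix
#'
#' Builds the N x N substochastic infection-stage matrix. For `j > i` the
#' entry is
#' \eqn{Q_{i,j} = p[q_i\{h P(\mu_n, j-i) + (1-h) g P(\mu_m, j-i)\} +
#' (1-q_i) s P(\mu_k, j-i)]}; the diagonal carries the no-encounter mass
#' `1 - p` plus (by default) the zero-gain survival term; gains beyond class
#' `N` are removed (`boundary = "lethal"`) or accumulated in class `N`
#' (`boundary = "absorb"`). The deficit of row `i` from 1 is the death
#' probability of class `i`.
#'
#' @param params A [dynamics_params()] object.
#' @return An `N x N` matrix with rows indexing the source class.
#' @export
infection_matrix <- function(params) {
  N <- params$N
  p <- params$p
  qi <- params_q(params)
  zg <- params$include_zero_gain

  mix_vec <- function(k_pmf_n, k_pmf_m, k_pmf_k) {
    list(
      a = params$h * k_pmf_n + (1 - params$h) * params$g * k_pmf_m,
      b = params$s * k_pmf_k
    )
  }
  kk <- 0:(N - 1L)
  cond <- function(mu, v) {
    # optionally condition the gain law on k >= 1
    if (zg || mu == 0) return(v)
    out <- v / (1 - gain_pmf(mu, 0))
    out[1] <- 0
    out
  }
  pn <- cond(params$mu_n, gain_pmf(params$mu_n, kk))
  pm <- cond(params$mu_m, gain_pmf(params$mu_m, kk))
  pk <- cond(params$mu_k, gain_pmf(params$mu_k, kk))

  mv <- mix_vec(pn, pm, pk)
  # upper-triangular Toeplitz fill: A[i, j] = row_i mix at k = j - i
  Kmat <- outer(seq_len(N), seq_len(N), function(i, j) j - i)
  idx <- which(Kmat >= 0)
  Amix <- matrix(0, N, N)
  Bmix <- matrix(0, N, N)
  Amix[idx] <- mv$a[Kmat[idx] + 1L]
  Bmix[idx] <- mv$b[Kmat[idx] + 1L]
  if (params$boundary == "absorb") {
    # clamp: last column accumulates the tail mass P(K >= N - i)
    tail_k <- N - seq_len(N)
    ct <- function(mu) {
      if (zg || mu == 0) return(gain_tail(mu, tail_k))
      tl <- gain_tail(mu, tail_k) / (1 - gain_pmf(mu, 0))
      # row i = N: conditioning leaves all mass at k >= 1, still clamped to N
      tl[tail_k == 0] <- 1
      tl
    }
    Amix[, N] <- params$h * ct(params$mu_n) + (1 - params$h) * params$g * ct(params$mu_m)
    Bmix[, N] <- params$s * ct(params$mu_k)
  }
  A <- p * (qi * Amix + (1 - qi) * Bmix)
  diag(A) <- diag(A) + (1 - p)
  rs <- rowSums(A)
  if (any(rs > 1 + 1e-12)) {
    abort("Internal error: infection matrix row sum exceeds 1.",
          class = "spacerlaw_internal_error")
  }
  A
}

#' Replication scaling factor
#'
#' The factor \eqn{N_\nu} multiplying all replication rates so that the
#' daughters produced in the replication half-step exactly compensate the
#' deaths of the infection half-step:
#' \eqn{N_\nu = (F_{const} - \sum_i F_i(t+1/2)) / (\sum_i \nu_i F_i(t+1/2))}.
#'
#' @param f_half Class abundances after the infection half-step.
#' @param nu Replication-rate vector \eqn{\nu_i}.
#' @param F_const Carrying capacity.
#' @return The non-negative scalar \eqn{N_\nu}.
#' @export
compute_scaling <- function(f_half, nu, F_const) {
  surv <- sum(f_half)
  if (surv <= 0) {
    abort("Population extinct: no survivors after the infection step.",
          class = "spacerlaw_extinction_error")
  }
  denom <- sum(nu * f_half)
  if (denom <= 0) {
    abort("No replication capacity: sum(nu * F) is zero.",
          class = "spacerlaw_extinction_error")
  }
  max((F_const - surv) / denom, 0)
}

# Replication kernel D with D[i, j] = nu_i * P(S_L * i, i - j) for j <= i
# (deletion mass below class 1 accumulated in class 1), so that
# A2 = I + N_nu * D and rowSums(D) = nu.
replication_kernel <- function(params) {
  N <- params$N
  nu <- params_nu(params)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) {
    mu <- params$S_L * i
    r <- mu / (1 + mu)
    k <- i - seq_len(i) # loss counts for columns 1..i
    pmf <- (1 / (1 + mu)) * r^k
    pmf[1] <- r^(i - 1L) # class 1 accumulates all losses >= i - 1
    D[i, seq_len(i)] <- nu[i] * pmf
  }
  D
}

#' Replication transition matrix
#'
#' Builds `A2 = I + N_nu * D` where `D[i, j] = nu_i P(S_L i, i - j)` for
#' `j <= i` describes daughters losing `i - j` spacers (deletions below
#' class 1 accumulate in class 1) and the identity keeps the parents. Row
#' `i` sums to `1 + N_nu * nu_i` exactly.
#'
#' @param params A [dynamics_params()] object.
#' @param n_nu Replication scaling factor (see [compute_scaling()]).
#' @return An `N x N` matrix, rows indexing the source class.
#' @export
replication_matrix <- function(params, n_nu) {
  if (n_nu < 0) abort("`n_nu` must be >= 0.", class = "spacerlaw_param_error")
  A2 <- n_nu * replication_kernel(params)
  diag(A2) <- diag(A2) + 1
  if (any(A2 < 0)) {
    abort("Internal error: negative entry in replication matrix.",
          class = "spacerlaw_internal_error")
  }
  A2
}

new_stationary_result <- function(distribution, iterations, converged,
                                  n_nu_star, method, params,
                                  drift = NA_real_, degenerate = FALSE) {
  structure(
    list(distribution = distribution, iterations = iterations,
         converged = converged, n_nu_star = n_nu_star, method = method,
         params = params, drift = drift, degenerate = degenerate),
    class = "stationary_result"
  )
}

#' Iterate the spacer dynamics to stationarity
#'
#' Alternates the infection and replication half-steps, recomputing the
#' replication scaling \eqn{N_\nu} each iteration, until the L1 change of
#' the normalized class distribution falls below `params$tol` or
#' `params$max_iter` is reached. The total abundance equals `F_const` after
#' every full iteration by construction (tracked by the `drift` diagnostic).
#'
#' @param params A [dynamics_params()] object.
#' @param init `"uniform"` or a length-`N` non-negative vector summing to
#'   `F_const`.
#' @return A `stationary_result`: the stationary probability vector
#'   (`distribution`), `iterations`, `converged`, the equilibrium scaling
#'   `n_nu_star`, the conservation `drift`, and a `degenerate` flag (set
#'   when the dynamics are frozen, e.g. `p = 0`).
#' @examples
#' params <- dynamics_params(N = 60, max_iter = 2000, tol = 1e-9)
#' res <- run_dynamics(params)
#' glance(res)
#' @export
run_dynamics <- function(params, init = "uniform") {
  stopifnot(inherits(params, "dynamics_params"))
  N <- params$N
  if (identical(init, "uniform")) {
    f <- rep(params$F_const / N, N)
  } else {
    if (length(init) != N || any(init < 0)) {
      abort("`init` must be a non-negative length-N vector.", class = "spacerlaw_param_error")
    }
    if (abs(sum(init) - params$F_const) > 1e-6 * params$F_const) {
      abort("`init` must sum to F_const.", class = "spacerlaw_param_error")
    }
    f <- as.numeric(init)
  }
  if (params$p == 0) {
    # no encounters: nobody dies, N_nu = 0, the state is frozen
    return(new_stationary_result(
      distribution = f / sum(f), iterations = 0L, converged = TRUE,
      n_nu_star = 0, method = "iteration", params = params,
      drift = 0, degenerate = TRUE
    ))
  }
  A1 <- infection_matrix(params)
  D <- replication_kernel(params)
  nu <- params_nu(params)
  drift <- 0
  n_nu <- NA_real_
  converged <- FALSE
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    fh <- as.numeric(f %*% A1)
    surv <- sum(fh)
    if (surv <= 0) {
      abort(sprintf("Population extinct at iteration %d.", it),
            class = "spacerlaw_extinction_error")
    }
    n_nu <- compute_scaling(fh, nu, params$F_const)
    f_new <- fh + n_nu * as.numeric(fh %*% D)
    drift <- max(drift, abs(sum(f_new) - params$F_const) / params$F_const)
    delta <- sum(abs(f_new - f)) / params$F_const
    f <- f_new
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  new_stationary_result(
    distribution = f / sum(f), iterations = it, converged = converged,
    n_nu_star = n_nu, method = "iteration", params = params, drift = drift
  )
}

#' Stationary distribution by the left principal eigenvector
#'
#' Solves \eqn{F^* = F^* A} with \eqn{A = A^{(1)} (I + N_\nu^* D)} for the
#' eigenvalue-1 left eigenvector, as an independent cross-check of
#' [run_dynamics()]. The principal eigenvalue equals 1 only when
#' `n_nu_star` is the equilibrium scaling; a deviation beyond `1e-6` raises
#' an inconsistent-scaling error. The degenerate case `A = I` (e.g.
#' `p = 0`) is returned flagged, since the eigenvalue-1 eigenspace is then
#' not one-dimensional.
#'
#' @param params A [dynamics_params()] object.
#' @param n_nu_star Equilibrium replication scaling, typically
#'   `run_dynamics(params)$n_nu_star`.
#' @return A `stationary_result` with `method = "eigenvector"`.
#' @export
stationary_eigen <- function(params, n_nu_star) {
  stopifnot(inherits(params, "dynamics_params"))
  if (n_nu_star < 0) abort("`n_nu_star` must be >= 0.", class = "spacerlaw_param_error")
  N <- params$N
  A1 <- infection_matrix(params)
  A <- A1 + n_nu_star * (A1 %*% replication_kernel(params))
  if (max(abs(A - diag(N))) < 1e-12) {
    return(new_stationary_result(
      distribution = rep(NA_real_, N), iterations = 0L, converged = FALSE,
      n_nu_star = n_nu_star, method = "eigenvector", params = params,
      degenerate = TRUE
    ))
  }
  e <- eigen(t(A))
  k <- which.min(abs(e$values - 1))
  lam1 <- e$values[k]
  if (abs(lam1 - 1) > 1e-6) {
    abort(sprintf(
      "Principal eigenvalue %.8f differs from 1: `n_nu_star` is not the equilibrium scaling.",
      Re(lam1)), class = "spacerlaw_scaling_error")
  }
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-12 * max(abs(v))) {
    abort("Internal error: principal eigenvector has negative entries.",
          class = "spacerlaw_internal_error")
  }
  v[v < 0] <- 0
  new_stationary_result(
    distribution = v / sum(v), iterations = 0L, converged = TRUE,
    n_nu_star = n_nu_star, method = "eigenvector", params = params
  )
}

#' @export
print.stationary_result <- function(x, ...) {
  cat("<stationary_result> method:", x$method,
      " N:", length(x$distribution), "\n")
  if (x$degenerate) cat("  degenerate (frozen dynamics)\n")
  cat("  iterations:", x$iterations, " converged:", x$converged,
      " N_nu*:", signif(x$n_nu_star, 6), "\n")
  invisible(x)
}

#' Fit a truncated power law to a stationary distribution
#'
#' Converts the stationary class probabilities into an abundance-weighted
#' sample (weights `F_i* = F_const * distribution`) and fits the discrete
#' truncated power law by weighted maximum likelihood — deterministic, with
#' no Monte-Carlo resampling noise.
#'
#' @param result A `stationary_result`.
#' @param family Family to fit (default truncated power law).
#' @param xmin Support minimum for the fit.
#' @return An `ht_fit` object.
#' @export
fit_stationary <- function(result, family = "truncated_powerlaw", xmin = 1L) {
  stopifnot(inherits(result, "stationary_result"))
  if (result$degenerate) {
    abort("Degenerate stationary result: nothing to fit.",
          class = "spacerlaw_fit_error")
  }
  N <- length(result$distribution)
  w <- result$distribution * result$params$F_const
  keep <- w > 0
  fit_heavy_tail(seq_len(N)[keep], family = family, xmin = xmin,
                 weights = w[keep])
}

#' Parameter sweep of the stationary spacer distribution
#'
#' Runs the dynamics to stationarity for each value of one scalar parameter
#' and fits a truncated power law to each stationary distribution, tracing
#' the \eqn{\alpha(\lambda)} trajectory. When `vary = "mu_n"` and
#' `tie_mu = TRUE` (default), `mu_m` and `mu_k` follow the coupling
#' `100 mu_k = mu_m = mu_n`. Per-point failures are recorded in the `error`
#' column and the sweep continues.
#'
#' @param params Base [dynamics_params()].
#' @param vary Name of the scalar field to vary (e.g. `"S_L"`, `"mu_n"`,
#'   `"g"`).
#' @param values Numeric values to sweep over.
#' @param tie_mu Keep `mu_m = mu_n` and `mu_k = mu_n / 100` when varying
#'   `mu_n`.
#' @return A tibble: `value`, `alpha`, `lambda`, `converged`, `error`, plus
#'   list-columns `result` and `fit`.
#' @export
sweep_dynamics <- function(params, vary, values, tie_mu = TRUE) {
  stopifnot(inherits(params, "dynamics_params"))
  if (!vary %in% names(params) || !is.numeric(params[[vary]])) {
    abort(sprintf("`vary` must name a scalar numeric field, not '%s'.", vary),
          class = "spacerlaw_param_error")
  }
  rows <- purrr::map(values, function(v) {
    pl <- unclass(params)
    pl[[vary]] <- v
    if (vary == "mu_n" && tie_mu) {
      pl$mu_m <- v
      pl$mu_k <- v / 100
    }
    pv <- try(do.call(dynamics_params, pl), silent = TRUE)
    if (inherits(pv, "try-error")) {
      return(tibble::tibble(value = v, alpha = NA_real_, lambda = NA_real_,
                            converged = NA, error = conditionMessage(attr(pv, "condition")),
                            result = list(NULL), fit = list(NULL)))
    }
    res <- try(run_dynamics(pv), silent = TRUE)
    if (inherits(res, "try-error")) {
      return(tibble::tibble(value = v, alpha = NA_real_, lambda = NA_real_,
                            converged = NA, error = conditionMessage(attr(res, "condition")),
                            result = list(NULL), fit = list(NULL)))
    }
    fit <- try(fit_stationary(res), silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(tibble::tibble(value = v, alpha = NA_real_, lambda = NA_real_,
                            converged = res$converged,
                            error = conditionMessage(attr(fit, "condition")),
                            result = list(res), fit = list(NULL)))
    }
    tibble::tibble(value = v, alpha = fit$spec$params$alpha,
                   lambda = fit$spec$params$lam, converged = res$converged,
                   error = NA_character_, result = list(res), fit = list(fit))
  })
  dplyr::bind_rows(rows)
}
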