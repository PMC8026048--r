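# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised/matrix code paths: scalar loops and direct
# summation only.

# Direct-summation normalizer for p(i) ~ i^-alpha e^-lambda i on {xmin..K}.
oracle_tpl_norm <- function(alpha, lam, xmin = 1, K = 50000) {
  i <- xmin:K
  z <- sum(i^(-alpha) * exp(-lam * i))
  # integral bound on the remainder (matters only when lam * K is small)
  if (alpha > 1 && lam * K < 30) z <- z + K^(1 - alpha) / (alpha - 1) * exp(-lam * K)
  z
}

# Truncated-power-law log-likelihood by direct summation.
oracle_tpl_loglik <- function(x, alpha, lam, xmin = 1) {
  -alpha * sum(log(x)) - lam * sum(x) -
    length(x) * log(oracle_tpl_norm(alpha, lam, xmin))
}

# geometric gain/loss pmf with mean mu
oracle_geom <- function(mu, k) {
  if (mu == 0) return(as.numeric(k == 0))
  (1 / (1 + mu)) * (mu / (1 + mu))^k
}

# One full iteration (infection + replication) of the spacer dynamics by
# exhaustive enumeration of every gain/loss outcome, scalar loops only.
oracle_dynamics_step <- function(pars, f) {
  N <- pars$N
  qi <- q_of_i(pars$q_profile, 1:N, N, const = pars$q_const,
               mid = pars$q_mid, steep = pars$q_steep)
  nu <- nu_of_i(pars$nu_profile, 1:N, N, const = pars$nu_const,
                width = pars$nu_width)
  fh <- rep(0, N)
  for (i in 1:N) {
    kmax <- if (pars$boundary == "absorb") 400L else N - i
    for (k in 0:kmax) {
      j <- min(i + k, N)
      pr <- pars$p * (qi[i] * (pars$h * oracle_geom(pars$mu_n, k) +
                                 (1 - pars$h) * pars$g * oracle_geom(pars$mu_m, k)) +
                        (1 - qi[i]) * pars$s * oracle_geom(pars$mu_k, k))
      fh[j] <- fh[j] + f[i] * pr
    }
    fh[i] <- fh[i] + (1 - pars$p) * f[i]
  }
  n_nu <- (pars$F_const - sum(fh)) / sum(nu * fh)
  out <- fh
  for (i in 1:N) {
    mu <- pars$S_L * i
    for (j in 1:i) {
      k <- i - j
      pk <- if (j == 1) (mu / (1 + mu))^(i - 1) else oracle_geom(mu, k)
      out[j] <- out[j] + n_nu * nu[i] * fh[i] * pk
    }
  }
  list(f = out, n_nu = n_nu)
}

# Small well-formed spacer-count table for IO tests.
make_fixture_tsv <- function(path, extra_rows = character()) {
  lines <- c(
    "sample_id\thabitat\tarray_id\tspacer_count",
    "MG001\tMarine\tA01\t5",
    "MG001\tMarine\tA02\t2",
    "MG002\tFresh Water\tA01\t11",
    extra_rows
  )
  writeLines(lines, path)
  path
}
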