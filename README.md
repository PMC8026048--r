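# spacerlaw

Heavy-tailed distributions and Markov-chain dynamics of CRISPR spacer
arrays.

## What this package is for

Microbes record past phage infections as *spacers* in CRISPR arrays, and
the number of spacers per array is wildly variable. Pooled across large
metagenome and genome collections, the spacer-count distribution follows a
discrete **truncated power law**

    p(i) ∝ i^(−α) · exp(−λ i),   i = 1, 2, …

with α typically between 2 and 3 and a weak exponential cutoff λ ≈ 0.004.
`spacerlaw` is for researchers in microbial ecology and phage–host
interaction who want to

* fit discrete heavy-tailed families (truncated power law, power law,
  exponential, stretched exponential, lognormal) to per-array spacer
  counts by maximum likelihood, with confidence intervals for the
  exponent;
* decide *which* family describes the data best via Vuong-style
  loglikelihood-ratio comparisons (`rank_candidates()`,
  `per_group_best_fit()`);
* simulate the mechanistic explanation: a discrete-time Markov-chain model
  in which spacer gain is faster for longer arrays (rich-get-richer,
  match probability `q_i` increasing in `i`) while replication is slower
  for longer arrays (fitness cost, rate `ν_i` decreasing in `i`). The
  stationary class-abundance vector **F*** of the two-stage transition
  structure (infection, then replication rescaled by `N_ν` to hold the
  population at `F_const`) develops exactly this truncated power law;
* generate synthetic spacer-count collections with known ground truth for
  end-to-end validation, without any external downloads.

Everything takes and returns tibbles, chains with the pipe, and has
`tidy()` / `glance()` / `autoplot()` methods.

## Worked example

```r
library(spacerlaw)

# a synthetic stand-in for a pooled metagenome collection
gen <- dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004)
dataset <- generate_spacer_dataset(gen, n_metagenomes = 20,
                                   arrays_per_metagenome = 5000, seed = 1)
summarize_spacers(dataset)
#> # A tibble: 1 × 6
#>   n_samples n_arrays n_spacers  mean    sd   max
#>       <int>    <int>     <int> <dbl> <dbl> <int>
#> 1        20   100000    169052  1.69  2.94   163

report <- run_fit(dataset)
report
#> <spacer_fit_report>
#>   arrays: 100000  samples: 20  mean count: 1.691
#>   best family: truncated_powerlaw
#>   truncated power law: alpha = 2.556  lambda = 0.006518
#> # A tibble: 4 × 7
#>   family_1           family_2                 R  sigma   p_value     n preferred
#>   <chr>              <chr>                <dbl>  <dbl>     <dbl> <dbl> <chr>
#> 1 truncated_powerlaw exponential         1.98e4 1.85   1.21e-252   1e5 truncate…
#> 2 truncated_powerlaw stretched_exponent… 1.16e4 0.391  0           1e5 truncate…
#> 3 truncated_powerlaw lognormal           1.26e5 0.846  0           1e5 truncate…
#> 4 truncated_powerlaw powerlaw            1.70e1 0.0131 4.25e-  5   1e5 truncate…
```

The ranking mirrors the empirical analysis: positive loglikelihood ratios
`R` mean the truncated power law fits better than the candidate in that
row, and the p-values say the preference is not a chance result. The
fitted exponent (α ≈ 2.56) and cutoff recover the generating values
(2.57, 0.004) up to sampling noise in λ.

The mechanistic model reproduces the law from first principles:

```r
params <- dynamics_params(N = 1000, p = 0.7, h = 1, s = 0.4,
                          mu_n = 10, S_L = 1 / 8)
sim <- run_simulate(params, cross_check = TRUE)
sim
#> <spacer_sim_report>
#>   iterations: 6159  converged: TRUE
#>   fitted truncated power law: alpha = 0.9875  lambda = 0.0028773
#>   iteration-vs-eigenvector L1: 1.27e-08
autoplot(sim$result, fit = sim$fit)   # log–log stationary distribution
```

Here a population of 10⁶ cells with at most N = 1000 spacers per array,
linear profiles `q_i = (i−1)/N` and `ν_i = (N+1−i)/N`, mean gain
μ_n = 10 and daughter loss fraction S_L = 1/8 settles into a heavy-tailed
stationary distribution with exponent α ≈ 0.99; the iterative solution
agrees with the left principal-eigenvector solution to 10⁻⁸.

Finally, the global extrapolation: scaling the empirical law
p(i) = i^(−2.57) e^(−0.004 i) to the ~10³⁰ prokaryotic cells on Earth,
the largest array size whose expected number of carriers is still at
least one cell is

```r
extrapolate_max_array(2.57, 0.004, 1e30)
#> [1] 11211
```

about eleven thousand spacers.

## Package layout

* `dist_spec()`, `dist_pmf()`, `dist_logpmf()`, `dist_rand()`,
  `fit_heavy_tail()` — discrete heavy-tailed families and MLE fitting
* `compare_fits()`, `rank_candidates()`, `per_group_best_fit()`,
  `best_fit_size_curve()` — model selection
* `dynamics_params()`, `run_dynamics()`, `stationary_eigen()`,
  `fit_stationary()`, `sweep_dynamics()` — the Markov-chain model
* `read_spacer_counts()`, `write_spacer_counts()`, `summarize_spacers()`,
  `spacer_histogram()` — tabular IO (4-column TSV; a small synthetic
  example lives in `inst/extdata/`)
* `generate_spacer_dataset()`, `generate_negative_control()` — synthetic
  data
* `run_fit()`, `run_simulate()`, `extrapolate_max_array()` — pipeline
  wrappers

The methods vignette (`vignettes/spacer-distributions.Rmd`) documents the
model assumptions, parameter meanings, numerical choices and limitations.
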