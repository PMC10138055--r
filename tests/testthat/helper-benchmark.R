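# Lazily computed, cached reduced-scale benchmark cells shared by the
# simulation-calibration tests (p = 480 genes, S = 50 replicates, B = 200
# permutations, N1 = 100 samples; one fixed seed chosen up front).
# Several test blocks assert different aspects of the same cell, so each
# cell is computed once per test run.

.bench_cache <- new.env(parent = emptyenv())

bench_cell <- function(scenario, sigma_mu, methods,
                       adjust_covariates = TRUE) {
  key <- paste(scenario, sigma_mu, paste(sort(methods), collapse = "+"),
               adjust_covariates, sep = "_")
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- run_benchmark(
      scenario, sigma_mu = sigma_mu, S = 50, n_samples = 100,
      n_genes = 480, B = 200, methods = methods, alpha = 0.05,
      seed = 20230326 + match(scenario, c("IA", "IB", "IIA", "IIB",
                                          "IIIA", "IIIB")),
      adjust_covariates = adjust_covariates)
  }
  .bench_cache[[key]]
}

bench_rate <- function(bm, m) bm$rate[bm$method == m]
bench_sens <- function(bm, m) bm$sensitivity[bm$method == m]
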