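test_that("identical config and seed give bitwise-identical datasets", {
  cfg <- sim_config("IA", sigma_mu = 0.6, n_samples = 20, n_genes = 12,
                    seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$expression, d2$expression)
  expect_identical(as.data.frame(d1$phenotypes), as.data.frame(d2$phenotypes))
  expect_identical(make_fixture(30, 60, 4, seed = 1),
                   make_fixture(30, 60, 4, seed = 1))
})

test_that("sigma_mu = 0 forces the global null", {
  d <- simulate_dataset(sim_config("IA", sigma_mu = 0, n_samples = 500,
                                   n_genes = 30, seed = 7))
  expect_true(all(d$truth_weights == 0))
  # expression columns are then iid N(0, sigma_x^2)
  expect_equal(mean(apply(d$expression, 2, sd)), 0.5, tolerance = 0.05)
  expect_lt(max(abs(cor(d$expression[, 1:10])[upper.tri(diag(10))])), 0.2)
  expect_true(all(make_fixture(30, 60, 4, seed = 1,
                               sigma_mu = 0)$truth_weights == 0))
})

test_that("simulated moments match the closed forms of the model", {
  # corr(x_j, y_k) for block-1 gene, k <= 4:
  #   sigma_mu^2 / sqrt((sigma_mu^2 + sigma_x^2)(sigma_mu^2 + sigma_k^2))
  d <- simulate_dataset(sim_config("IA", sigma_mu = 0.6, n_samples = 40000,
                                   n_genes = 6, seed = 3))
  r_expect <- 0.36 / sqrt(0.61 * 4.36)          # = 0.2208...
  y <- as.data.frame(d$phenotypes)
  r_emp <- cor(d$expression[, 1], y$pheno_1)
  expect_lt(abs(r_emp - r_expect), 0.02)
  # Var(y_k) = sigma_mu^2 + sigma_k^2 = 4.36 for k <= 4 (within 3 SE)
  expect_lt(abs(var(y$pheno_2) - 4.36), 3 * 4.36 * sqrt(2 / 40000))
})

test_that("scenario defaults reproduce the stated sigma_k vectors", {
  expect_equal(sim_config("IA", sigma_mu = 0)$sigma_k, c(rep(2, 9), 1))
  expect_equal(sim_config("IB", sigma_mu = 0)$sigma_k,
               c(0.05, 2, 2, 2, 0.05, 2, 2, 2, 2, 1))
  expect_equal(sim_config("IIIA", sigma_mu = 0)$sigma_k[6:10],
               c(2, 2, 2, 2, 1))
  expect_equal(sim_config("IIIB", sigma_mu = 0)$sigma_k[6:10],
               c(0.01, 2, 2, 2, 1))
})

test_that("scenario III yields typed phenotypes with valid supports", {
  d <- simulate_dataset(sim_config("IIIA", sigma_mu = 0.6, n_samples = 60,
                                   n_genes = 9, seed = 5))
  fams <- pheno_families(d$phenotypes)
  expect_equal(unname(fams[1:5]),
               c(rep("poisson", 4), "binomial"))
  y <- as.data.frame(d$phenotypes)
  expect_true(all(y$pheno_1 >= 0 & y$pheno_1 == round(y$pheno_1)))
  expect_true(all(y$pheno_5 %in% 0:1))
})

test_that("scenario II carries the confounder into genes and phenotypes", {
  d <- simulate_dataset(sim_config("IIA", sigma_mu = 0, sigma_c = 1,
                                   n_samples = 4000, n_genes = 9, seed = 8))
  expect_equal(dim(d$covariates), c(4000L, 1L))
  z <- d$covariates$z
  y <- as.data.frame(d$phenotypes)
  expect_gt(cor(d$expression[, 1], z), 0.5)     # block 1 loads on z
  expect_lt(abs(cor(d$expression[, 9], z)), 0.1) # block 3 does not
  expect_gt(cor(y$pheno_1, z), 0.3)
  expect_lt(abs(cor(y$pheno_10, z)), 0.1)
})

test_that("truth blocks follow the factor-sharing design", {
  d <- simulate_dataset(sim_config("IB", sigma_mu = 0.4, n_samples = 10,
                                   n_genes = 9, seed = 1))
  expect_equal(d$truth_blocks, rep(1:3, each = 3))
  expect_equal(unname(d$truth_weights[1, ]), c(rep(1L, 9), 0L))  # block 1
  expect_equal(unname(d$truth_weights[4, ]),
               c(rep(0L, 4), rep(1L, 5), 0L))                    # block 2
  expect_equal(unname(d$truth_weights[9, ]), c(rep(0L, 9), 1L))  # block 3
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config("IA", sigma_mu = -1), "non-negative")
  expect_error(sim_config("IA", sigma_mu = 0, n_samples = 0), "positive")
  expect_error(sim_config("IA", sigma_mu = 0, n_genes = 2), ">= 3")
  expect_error(make_fixture(30, 2, 4, seed = 1), "n_genes >= 3")
})

test_that("strong-signal fixture gives far-sub-uniform p-values on true pairs", {
  fx <- make_fixture(30, 60, 4, seed = 2, sigma_mu = 5)
  obs <- observed_matrices(fx$phenotypes, fx$expression)
  expect_lt(median(obs$p[fx$truth_weights == 1]), 0.01)
})

test_that("datasets round-trip through the plain-text layout", {
  dir <- withr::local_tempdir()
  d <- simulate_dataset(sim_config("IIA", sigma_mu = 0.4, n_samples = 15,
                                   n_genes = 9, seed = 4))
  write_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir,
    c("expression.tsv", "phenotypes.csv", "phenotype_families.yaml",
      "covariates.csv", "truth_weights.tsv")))))
  d2 <- read_dataset(dir)
  expect_equal(d2$expression, d$expression)
  expect_equal(pheno_families(d2$phenotypes), pheno_families(d$phenotypes))
  expect_equal(unname(d2$truth_weights), unname(d$truth_weights),
               ignore_attr = TRUE)
  expect_equal(d2$covariates$z, d$covariates$z)
})
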