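test_that("gaussian Wald fit equals the classical t-test for the slope", {
  set.seed(10)
  x <- rnorm(100); y <- 0.3 * x + rnorm(100)
  r <- fit_association(y, x, "gaussian")
  sm <- summary(lm(y ~ x))$coefficients
  expect_equal(r$p, sm["x", 4], tolerance = 1e-10)
  expect_equal(r$theta, sm["x", 1], tolerance = 1e-10)
})

test_that("degenerate predictors and perfect fits are handled", {
  set.seed(11)
  y <- rnorm(20)
  expect_error(fit_association(y, rep(1, 20), "gaussian"), "zero variance")
  x <- rnorm(20)
  r <- fit_association(x, x, "gaussian")      # y = x exactly
  expect_lt(r$p, 1e-200)                      # residuals at machine epsilon
  expect_equal(r$theta, 1, tolerance = 1e-8)
  expect_error(fit_association(y[1:3], x[1:3], "gaussian", Z = cbind(1:3)),
               "M \\+ 3")
})

test_that("poisson and binomial score scans match the anova Rao oracle", {
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("g", 1:4)))
  for (fam in c("poisson", "binomial")) {
    y <- if (fam == "poisson") rpois(n, exp(0.3 * X[, 1])) else
      rbinom(n, 1, plogis(0.8 * X[, 1]))
    yt <- typed_phenotypes(data.frame(y = y), c(y = fam))
    obs <- observed_matrices(yt, X, engine = "score")
    for (j in 1:4) {
      f0 <- glm(y ~ 1, family = fam)
      f1 <- glm(y ~ X[, j], family = fam)
      p_rao <- stats::anova(f0, f1, test = "Rao")[["Pr(>Chi)"]][2]
      expect_equal(unname(obs$p[j, 1]), p_rao, tolerance = 1e-4)
    }
  }
})

test_that("score scan with covariates matches the Rao oracle", {
  set.seed(13)
  n <- 90
  Z <- data.frame(z1 = rnorm(n), z2 = rnorm(n))
  X <- matrix(rnorm(n * 3) + Z$z1, n, 3)
  y <- rpois(n, exp(0.4 * Z$z1))
  yt <- typed_phenotypes(data.frame(y = y), c(y = "poisson"))
  obs <- observed_matrices(yt, X, covariates = Z, engine = "score")
  for (j in 1:3) {
    f0 <- glm(y ~ z1 + z2, data = Z, family = "poisson")
    f1 <- glm(y ~ X[, j] + z1 + z2, data = Z, family = "poisson")
    p_rao <- stats::anova(f0, f1, test = "Rao")[["Pr(>Chi)"]][2]
    expect_equal(unname(obs$p[j, 1]), p_rao, tolerance = 1e-4)
  }
})

test_that("glm and score engines agree for gaussian phenotypes", {
  fx <- make_fixture(40, 12, 4, seed = 6)
  o1 <- observed_matrices(fx$phenotypes, fx$expression, engine = "glm")
  o2 <- observed_matrices(fx$phenotypes, fx$expression, engine = "score")
  expect_equal(o1$p, o2$p, tolerance = 1e-8)
  expect_identical(o1$sign, o2$sign)
})

test_that("survival phenotypes go through Cox partial-likelihood Wald", {
  fx <- make_fixture(60, 9, 4, seed = 9, sigma_mu = 2, survival = TRUE)
  obs <- observed_matrices(fx$phenotypes, fx$expression)
  expect_true(all(obs$p > 0 & obs$p <= 1))
  # block-3 genes drive the hazard; their p-values should be small
  expect_lt(median(obs$p[fx$truth_blocks == 3, 4]), 0.05)
  col <- afcombine:::pheno_column(fx$phenotypes, "pheno_4")
  cx <- survival::coxph(col$y ~ fx$expression[, 7])
  expect_equal(obs$p[7, 4], summary(cx)$coefficients[1, "Pr(>|z|)"],
               tolerance = 1e-8)
})

test_that("residualize centers, annihilates perfect predictors, and is orthogonal", {
  set.seed(14)
  X <- matrix(rnorm(50 * 6), 50, 6)
  E0 <- residualize(X)
  expect_equal(E0, sweep(X, 2, colMeans(X)), tolerance = 1e-12)
  Z <- data.frame(z = X[, 3])
  E <- residualize(X, Z)
  expect_lt(max(abs(E[, 3])), 1e-8)
  nrm <- sqrt(colSums(E^2)) * sqrt(sum(Z$z^2))
  expect_lt(max(abs(crossprod(E, Z$z)) / pmax(nrm, 1e-12)), 1e-6)
  expect_warning(residualize(X, data.frame(a = Z$z, b = 2 * Z$z)),
                 "collinear")
})

test_that("misaligned sample IDs are reported by name", {
  fx <- make_fixture(10, 6, 4, seed = 1)
  Z <- data.frame(z = rnorm(10),
                  row.names = paste0("other_", 1:10))
  expect_error(observed_matrices(fx$phenotypes, fx$expression, Z),
               "misaligned.*other_1")
})

test_that("null tensor: determinism, shared permutations, identity hook", {
  fx <- make_fixture(25, 8, 4, seed = 15)
  E <- residualize(fx$expression)
  n1 <- null_tensor(fx$phenotypes, E, B = 7, seed = 3)
  n2 <- null_tensor(fx$phenotypes, E, B = 7, seed = 3)
  expect_identical(n1$p, n2$p)
  expect_identical(n1$perms, n2$perms)          # same pi_b for all genes
  expect_equal(dim(n1$p), c(7L, 8L, 4L))
  # identity permutation: slice equals observed p-values on the residuals
  id <- matrix(rep(1:25, 2), 25, 2)
  nid <- null_tensor(fx$phenotypes, E, B = 2, perms = id)
  obs <- observed_matrices(fx$phenotypes, E, engine = "score")
  expect_equal(nid$p[1, , ], unname(obs$p), tolerance = 1e-10)
})

test_that("pooled null and observed p-values are uniform under the global null", {
  d <- simulate_dataset(sim_config("IA", sigma_mu = 0, n_samples = 100,
                                   n_genes = 200, seed = 21))
  obs <- observed_matrices(d$phenotypes, d$expression)
  ks_obs <- suppressWarnings(stats::ks.test(as.vector(obs$p), "punif"))
  expect_gt(ks_obs$p.value, 0.01)
  E <- residualize(d$expression)
  nt <- null_tensor(d$phenotypes, E, B = 5, seed = 22)
  ks_null <- suppressWarnings(stats::ks.test(as.vector(nt$p), "punif"))
  expect_gt(ks_null$p.value, 0.01)
})

test_that("unadjusted p-values are anti-conservative under confounding while adjusted stay uniform", {
  d <- simulate_dataset(sim_config("IIA", sigma_mu = 0, sigma_c = 1,
                                   n_samples = 100, n_genes = 120,
                                   seed = 23))
  naive <- observed_matrices(d$phenotypes, d$expression)
  adj <- observed_matrices(d$phenotypes, d$expression, d$covariates)
  confounded <- d$truth_blocks == 1
  expect_gt(mean(naive$p[confounded, 1:9] < 0.05), 0.15)
  expect_lt(mean(adj$p[confounded, 1:9] < 0.05), 0.10)
  ks <- suppressWarnings(stats::ks.test(as.vector(adj$p[, 1:9]), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the covariate-respecting null matches observed fits and the Rao oracle", {
  d <- simulate_dataset(sim_config("IIA", sigma_mu = 0.4, n_samples = 40,
                                   n_genes = 12, seed = 2))
  E <- residualize(d$expression, d$covariates)
  id <- matrix(rep(1:40, 2), 40, 2)
  nt <- null_tensor(d$phenotypes, E, B = 2, covariates = d$covariates,
                    with_covariates = TRUE, perms = id)
  obs <- observed_matrices(d$phenotypes, d$expression, d$covariates,
                          engine = "score")
  expect_equal(nt$p[1, , ], unname(obs$p), tolerance = 1e-10)
  # permuted non-gaussian draw against a direct glm score test
  d3 <- simulate_dataset(sim_config("IIIA", sigma_mu = 0.4, n_samples = 50,
                                    n_genes = 6, seed = 3))
  Z <- data.frame(z = withr::with_seed(4, rnorm(50)))
  E3 <- residualize(d3$expression, Z)
  pm <- matrix(withr::with_seed(5, sample(50)), 50, 1)
  nt3 <- null_tensor(d3$phenotypes, E3, B = 1, covariates = Z,
                     with_covariates = TRUE, perms = pm)
  y1 <- as.data.frame(d3$phenotypes)$pheno_1
  f0 <- glm(y1 ~ Z$z, family = "poisson")
  f1 <- glm(y1 ~ E3[pm[, 1], 3] + Z$z, family = "poisson")
  expect_equal(nt3$p[1, 3, 1],
               stats::anova(f0, f1, test = "Rao")[["Pr(>Chi)"]][2],
               tolerance = 1e-4)
})
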