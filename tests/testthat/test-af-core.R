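test_that("weighted statistic matches its definition and validates input", {
  expect_equal(weighted_stat(c(exp(-1), 1, 1), c(1, 0, 0)), 1)
  expect_equal(weighted_stat(c(0.001, 1, 1), c(1, 1, 1)),
               -log(0.001))                       # 6.9078 = 13.8155/2
  expect_equal(weighted_stat(rep(1, 5), c(1, 1, 1, 1, 1)), 0)
  expect_error(weighted_stat(c(0, 0.5), c(1, 1)), "0, 1")
  expect_error(weighted_stat(c(0.5, 1.2), c(1, 1)), "0, 1")
  expect_error(weighted_stat(c(0.5, 0.5), c(0, 0)), "not all zero")
})

test_that("pooled p-value is a right-tail count with optional smoothing", {
  tab <- null_stat_table(matrix(exp(-c(1, 2, 3, 4)), 4, 1))
  expect_equal(pooled_pvalue(2.5, 1, tab), 0.5)   # direct count 2/4
  expect_equal(pooled_pvalue(0.5, 1, tab), 1)
  expect_equal(pooled_pvalue(5, 1, tab), 0)       # literal count
  expect_equal(pooled_pvalue(5, 1, tab, smooth = TRUE), 1 / 5)
  expect_equal(pooled_pvalue(2, 1, tab), 3 / 4)   # ties count themselves
  expect_error(null_stat_table(matrix(numeric(0), 0, 1)), "empty")
})

test_that("pooled p-value is non-increasing in the observed statistic", {
  set.seed(30)
  tab <- null_stat_table(rand_p_matrix(200, 2))
  u <- sort(runif(50, 0, 3))
  pv <- vapply(u, pooled_pvalue, numeric(1), w = c(1, 1), nulls = tab)
  expect_true(all(diff(pv) <= 0))
})

test_that("single-phenotype case reduces to the plain pooled count", {
  set.seed(31)
  pn <- rand_p_matrix(50, 1)
  tab <- null_stat_table(pn)
  r <- afp_gene(0.03, tab)
  expect_equal(r$w, 1L)
  expect_equal(r$T, pooled_pvalue(-log(0.03), 1, tab))
  z <- afz_gene(0.03, tab)
  expect_equal(z$T, (-log(0.03) - tab$mean[1]) / tab$sd[1])
})

test_that("reference implementations, compiled scan, and naive oracle agree", {
  set.seed(32)
  for (rep in 1:25) {
    K <- sample(2:4, 1); N <- sample(20:60, 1); G <- sample(2:6, 1)
    pn <- rand_p_matrix(N, K)
    po <- rand_p_matrix(G, K, power = sample(1:3, 1))
    if (rep %% 5 == 0) { pn[2, ] <- pn[1, ]; po[2, ] <- po[1, ] }
    or <- oracle_scan(pn, po)
    sc <- afcombine:::af_scan_cpp(-log(pn), -log(po), TRUE, TRUE, TRUE)
    expect_identical(sc$afp$count, as.integer(or$afp_count))
    expect_identical(sc$afp$subset, as.integer(or$afp_subset))
    expect_identical(sc$afz$subset, as.integer(or$afz_subset))
    expect_equal(sc$afz$stat, or$afz_stat, tolerance = 1e-12)
    expect_identical(sc$afp$null_count, as.integer(or$null_count_min))
    expect_equal(sc$afz$null_stat, or$null_z_max, tolerance = 1e-12)
    tab <- null_stat_table(pn)
    for (g in seq_len(G)) {
      rg <- afp_gene(po[g, ], tab)
      expect_equal(rg$count, or$afp_count[g])
      expect_equal(afcombine:::weights_subset(rg$w), or$afp_subset[g])
      zg <- afz_gene(po[g, ], tab)
      expect_equal(zg$T, or$afz_stat[g], tolerance = 1e-12)
      expect_equal(afcombine:::weights_subset(zg$w), or$afz_subset[g])
    }
    expect_equal(round(null_statistics(tab, "afp") * N),
                 or$null_count_min)
    expect_equal(null_statistics(tab, "afz"), or$null_z_max,
                 tolerance = 1e-12)
  }
})

test_that("hand-enumerated tiny null table reproduces the pooled counts", {
  # N = 4 pooled draws, K = 2; -log p values chosen by hand
  pn <- exp(-matrix(c(1, 2, 3, 4,
                      2, 1, 1, 2), 4, 2))
  tab <- null_stat_table(pn)
  # subsets: {1} -> u = (1,2,3,4); {2} -> (2,1,1,2); {1,2} -> (3,3,4,6)
  expect_equal(tab$sorted[, 1], c(1, 2, 3, 4))
  expect_equal(tab$sorted[, 2], c(1, 1, 2, 2))
  expect_equal(tab$sorted[, 3], c(3, 3, 4, 6))
  # observed p = (exp(-3.5), exp(-0.5)): u = 3.5, 0.5, 4.0
  r <- afp_gene(c(exp(-3.5), exp(-0.5)), tab)
  # counts: {1}: #\{>=3.5\} = 1; {2}: #\{>=0.5\} = 4; {1,2}: #\{>=4\} = 2
  expect_equal(r$count, 1)
  expect_equal(r$w, c(1L, 0L))
  expect_equal(r$T, 0.25)
})

test_that("null statistics are self-inclusive and standardization is centered", {
  set.seed(33)
  tab <- null_stat_table(rand_p_matrix(60, 3))
  T_afp <- null_statistics(tab, "afp")
  expect_true(all(T_afp >= 1 / 60))               # each draw counts itself
  # standardized u's have pooled mean ~0 and sd ~1 per subset
  z2 <- (tab$u[, 2] - tab$mean[2]) / tab$sd[2]
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z2^2)), 1, tolerance = 1e-12)
})

test_that("gene p-values count the correct tail", {
  expect_equal(gene_pvalues(0.25, c(0.1, 0.2, 0.3, 0.4), "afp"), 0.5)
  expect_equal(gene_pvalues(0.05, c(0.1, 0.2, 0.3, 0.4), "afp"), 0)
  expect_equal(gene_pvalues(0.05, c(0.1, 0.2, 0.3, 0.4), "afp",
                            smooth = TRUE), 0.2)
  expect_equal(gene_pvalues(0.1, c(0.1, 0.2, 0.3, 0.4), "afp"), 0.25)
  expect_equal(gene_pvalues(2.5, c(1, 2, 3, 4), "afz"), 0.5)
  expect_equal(gene_pvalues(3, c(1, 2, 3, 4), "afz"), 0.5)  # >= is inclusive
})

test_that("degenerate null subsets are refused with the subset named", {
  pn <- matrix(c(rep(1, 5), runif(5)), 5, 2)      # column 1 constant
  expect_error(null_stat_table(pn), "subset 1")
  expect_error(afcombine:::af_scan_cpp(-log(pn), -log(pn[1:2, , drop = FALSE]),
                                       FALSE, TRUE, TRUE),
               "subset 1")
})

test_that("all-ones subset halves the Fisher statistic and matches chi-square", {
  set.seed(34)
  p5 <- runif(5)
  expect_equal(2 * weighted_stat(p5, rep(1, 5)), fisher_statistic(p5))
  # with independent uniform p-values the pooled permutation p-value of the
  # all-ones subset approximates the chi-square(2K) tail
  K <- 3; N <- 40000
  tab_p <- rand_p_matrix(N, K)
  u_null <- sort(-rowSums(log(tab_p)))
  for (q in c(0.5, 0.9, 0.99)) {
    u0 <- stats::qchisq(q, 2 * K) / 2
    emp <- sum(u_null >= u0) / N
    expect_lt(abs(emp - stats::pchisq(2 * u0, 2 * K, lower.tail = FALSE)),
              0.012)
  }
})

test_that("engine = 'r' and engine = 'cpp' give identical af_test results", {
  fx <- make_fixture(30, 10, 4, seed = 35)
  f1 <- af_test(fx$expression, fx$phenotypes, B = 25, seed = 2,
                engine = "cpp")
  f2 <- af_test(fx$expression, fx$phenotypes, B = 25, seed = 2,
                engine = "r")
  expect_equal(f1$results$p_afp, f2$results$p_afp)
  expect_equal(f1$results$stat_afp, f2$results$stat_afp)
  expect_equal(f1$results$p_afz, f2$results$p_afz, tolerance = 1e-12)
  expect_identical(f1$w_afp, f2$w_afp)
  expect_identical(f1$w_afz, f2$w_afz)
})

test_that("K above the cap is refused with guidance", {
  y <- as.data.frame(matrix(rnorm(20 * 13), 20, 13))
  names(y) <- paste0("p", 1:13)
  expect_error(af_test(matrix(rnorm(20 * 3), 20, 3), y,
                       families = setNames(rep("gaussian", 13), names(y))),
               "k_cap")
})

test_that("gene-level p-values are approximately uniform under the global null", {
  d <- simulate_dataset(sim_config("IA", sigma_mu = 0, n_samples = 60,
                                   n_genes = 150, seed = 36))
  fit <- af_test(d$expression, d$phenotypes, B = 60, seed = 37)
  for (m in c("p_afp", "p_afz", "p_fisher", "p_minp")) {
    ks <- suppressWarnings(stats::ks.test(fit$results[[m]], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})
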