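test_that("CV filter matches a brute-force ranking", {
  set.seed(70)
  X <- matrix(rexp(40 * 25) + 0.5, 40, 25,
              dimnames = list(NULL, sprintf("g%02d", 1:25)))
  keep <- filter_by_cv(X, 10)
  cv <- apply(X, 2, sd) / colMeans(X)
  brute <- sort(names(sort(cv, decreasing = TRUE)[1:10]))
  expect_setequal(colnames(keep), brute)
  expect_identical(filter_by_cv(X, 25), X)       # top_n = p is the identity
  # two genes with CVs 2.0 and 0.1: the high-CV gene is kept
  X2 <- cbind(high = abs(rnorm(200, 1, 2)) + 1e-3,
              low = rnorm(200, 10, 1))
  cv2 <- apply(X2, 2, sd) / colMeans(X2)
  expect_gt(cv2["high"], cv2["low"])
  expect_equal(colnames(filter_by_cv(X2, 1)), "high")
})

test_that("CV filter excludes non-positive-mean genes and reports them", {
  X <- cbind(good = rexp(30) + 1, bad = rnorm(30) - 5)
  expect_message(out <- filter_by_cv(X, 1), "non-positive mean")
  expect_equal(colnames(out), "good")
})

test_that("incomplete samples are dropped and counted", {
  set.seed(71)
  n <- 319
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:4)))
  ph <- data.frame(a = rnorm(n), b = rnorm(n))
  Z <- data.frame(z = rnorm(n))
  miss <- sample(n, 40)
  Z$z[miss] <- NA                                 # 40 planted-missing
  cc <- drop_incomplete_samples(ph, Z, X)
  expect_equal(cc$n, 279)
  expect_setequal(cc$dropped, paste0("s", sort(miss)))
  expect_equal(nrow(cc$expression), 279)
  # no missingness: identity
  cc2 <- drop_incomplete_samples(ph, NULL, X)
  expect_equal(cc2$n, n)
  # one missing phenotype drops exactly one sample
  ph$a[5] <- NA
  cc3 <- drop_incomplete_samples(ph, NULL, X)
  expect_equal(cc3$n, n - 1)
  # too few remaining samples abort
  ph_bad <- data.frame(a = c(1, 2, rep(NA, n - 2)))
  expect_error(drop_incomplete_samples(ph_bad, NULL, X), "complete samples")
})

test_that("the full pipeline runs end to end, caches, and recovers planted genes", {
  dir <- withr::local_tempdir()
  fx <- make_fixture(45, 30, 4, seed = 72, sigma_mu = 3)
  cfg <- run_config(out_dir = dir, B = 60, seed = 4, L = 4, B_boot = 20,
                    min_size = 3, cluster_method = "hclust",
                    methods = c("afp", "afz", "fisher", "minp"))
  res <- suppressMessages(run_pipeline(cfg, dataset = fx))
  for (f in c("results.tsv", "significant_genes.tsv", "config.yaml",
              "run.log", "co_membership.tsv", "modules.tsv",
              "variability_index.tsv")) {
    expect_true(file.exists(file.path(dir, f)), label = f)
  }
  # strong signal: every planted gene is recalled
  planted <- colnames(fx$expression)
  expect_gte(length(intersect(res$significant, planted)) / length(planted),
             0.9)
  tab1 <- readr::read_tsv(file.path(dir, "results.tsv"),
                          show_col_types = FALSE)
  # identical rerun is a cache hit with identical outputs
  res2 <- suppressMessages(run_pipeline(cfg, dataset = fx))
  expect_true(isTRUE(res2$cached))
  tab2 <- readr::read_tsv(file.path(dir, "results.tsv"),
                          show_col_types = FALSE)
  expect_identical(tab1, tab2)
  log_lines <- readLines(file.path(dir, "run.log"))
  expect_true(any(grepl("cache hit", log_lines)))
  expect_true(any(grepl("n = 45, p = 30, K = 4", log_lines)))
})
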