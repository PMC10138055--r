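block_V <- function(sizes, within = 1, between = 0, noise_genes = 0) {
  n <- sum(sizes) + noise_genes
  V <- matrix(between, n, n)
  at <- 0
  for (s in sizes) {
    V[at + seq_len(s), at + seq_len(s)] <- within
    at <- at + s
  }
  diag(V) <- 1
  dimnames(V) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  V
}

test_that("perfect block-diagonal similarity is recovered exactly", {
  V <- block_V(c(8, 6))
  for (m in c("consensus", "hclust")) {
    mod <- tight_cluster(V, min_size = 3, method = m, seed = 1)
    expect_length(mod$modules, 2)
    expect_setequal(mod$modules[[1]], paste0("g", 1:8))
    expect_setequal(mod$modules[[2]], paste0("g", 9:14))
    expect_false(any(mod$assignment$module == "scattered"))
  }
})

test_that("genes unrelated to every block are labelled scattered", {
  V <- block_V(c(8, 6), noise_genes = 5)
  mod <- tight_cluster(V, min_size = 3, seed = 2)
  expect_length(mod$modules, 2)
  scattered <- mod$assignment$gene[mod$assignment$module == "scattered"]
  expect_setequal(scattered, paste0("g", 15:19))
})

test_that("identity similarity leaves everything scattered, with a warning-free empty result", {
  V <- diag(10)
  dimnames(V) <- list(paste0("g", 1:10), paste0("g", 1:10))
  mod <- tight_cluster(V, min_size = 3, seed = 3)
  expect_length(mod$modules, 0)
  expect_true(all(mod$assignment$module == "scattered"))
})

test_that("clustering is invariant to gene order", {
  skip_if_not_installed("mclust")
  set.seed(4)
  V <- block_V(c(10, 7, 5), within = 0.9, between = 0.05)
  noise <- matrix(runif(22 * 22, 0, 0.02), 22, 22)
  V <- pmin(V + (noise + t(noise)) / 2, 1); diag(V) <- 1
  dimnames(V) <- list(paste0("g", 1:22), paste0("g", 1:22))
  perm <- sample(nrow(V))
  m1 <- tight_cluster(V, min_size = 3, method = "hclust", seed = 5)
  m2 <- tight_cluster(V[perm, perm], min_size = 3, method = "hclust",
                      seed = 5)
  a1 <- setNames(m1$assignment$module, m1$assignment$gene)
  a2 <- setNames(m2$assignment$module, m2$assignment$gene)
  expect_equal(mclust::adjustedRandIndex(a1, a2[names(a1)]), 1)
})

test_that("modules merge only above the between-module threshold", {
  V <- block_V(c(6, 6, 6), between = 0)
  V[1:6, 7:12] <- 0.8; V[7:12, 1:6] <- 0.8       # modules 1-2 close
  V[1:12, 13:18] <- 0.1; V[13:18, 1:12] <- 0.1
  diag(V) <- 1
  mod <- tight_cluster(V, min_size = 3, method = "hclust",
                       alpha_tight = 0.85, seed = 6)
  expect_length(mod$modules, 3)
  merged <- merge_similar_modules(mod, V, merge_threshold = 0.5)
  expect_length(merged$modules, 2)
  expect_length(merged$modules[[1]], 12)
  # threshold above every between-mean leaves the assignment unchanged
  untouched <- merge_similar_modules(mod, V, merge_threshold = 0.9)
  expect_length(untouched$modules, 3)
})

test_that("module summary reports planted consensus patterns", {
  # two modules with opposite signed-weight patterns, constant over L = 3
  L <- 3; p <- 6; K <- 2
  W <- array(1L, c(L, p, K),
             dimnames = list(NULL, paste0("g", 1:p), c("a", "b")))
  Sg <- array(1, c(L, p, K), dimnames = dimnames(W))
  Sg[, 4:6, 1] <- -1
  W[, 4:6, 2] <- 0L
  boot <- structure(list(w = list(afp = W), sign = Sg, L = L,
                         methods = "afp"), class = "af_boot")
  V <- co_membership(boot)
  mod <- tight_cluster(V, min_size = 2, method = "hclust", seed = 7)
  pv <- matrix(0.01, p, K, dimnames = dimnames(W)[2:3])
  summ <- module_summary(mod, boot, pv)
  expect_equal(nrow(summ), 2 * K)
  pat <- split(summ$consensus, summ$module)
  expect_setequal(vapply(pat, paste, "", collapse = ","),
                  c("1,1", "-1,0"))
  expect_error(module_summary(tight_cluster(diag(3), min_size = 2, seed = 1),
                              boot, pv), "no modules")
})

test_that("the full pipeline recovers the planted gene blocks as modules", {
  skip_if_not_installed("mclust")
  # scaled-down analogue of the benchmark block design: strong latent
  # factors, bootstrap signed weights, co-membership, tight clustering
  d <- simulate_dataset(sim_config("IA", sigma_mu = 2, n_samples = 60,
                                   n_genes = 45, seed = 90))
  boot <- bootstrap_weights(d$expression, d$phenotypes, method = "afp",
                            L = 8, B_boot = 30, seed = 91)
  V <- co_membership(boot, method = "afp")
  mod <- tight_cluster(V, min_size = 4, seed = 92)
  lab <- setNames(mod$assignment$module, mod$assignment$gene)
  keep <- lab != "scattered"
  # tight clustering deliberately scatters genes whose bootstrap patterns
  # are unstable; a quarter of the genes forming clean modules mirrors the
  # clustered fractions seen in real applications
  expect_gt(mean(keep), 0.25)
  ari <- mclust::adjustedRandIndex(lab[keep],
                                   d$truth_blocks[match(names(lab)[keep],
                                                        colnames(d$expression))])
  expect_gte(ari, 0.8)
})
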