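#' Configure a benchmark simulation scenario
#'
#' Builds the configuration for the hierarchical random-effects generator
#' behind the benchmark scenarios. Three latent factors
#' \eqn{u_1, u_2, u_3 \sim N(0, \sigma_\mu^2)} per sample drive
#' block-structured gene-phenotype associations: the first third of genes
#' loads on \eqn{u_1}, the second on \eqn{u_2}, the third on \eqn{u_3};
#' phenotypes 1-4 load on \eqn{u_1}, phenotypes 5-9 on \eqn{u_1 + u_2}, and
#' phenotype 10 on \eqn{u_3}. Scenario families:
#' * `IA`/`IB` — ten gaussian phenotypes; `IB` gives phenotypes 1 and 5 a
#'   much smaller residual scale (0.05) so one association per gene block
#'   dominates.
#' * `IIA`/`IIB` — as `I`, plus a confounder \eqn{z \sim N(0, \sigma_c^2)}
#'   added to phenotypes 1-9 and to block-1 genes.
#' * `IIIA`/`IIIB` — mixed types: phenotypes 1-4 are Poisson with rate
#'   \eqn{\exp(u_1)}, phenotype 5 is Bernoulli with logit \eqn{u_1+u_2},
#'   phenotypes 6-10 are gaussian; `IIIB` shrinks phenotype 6's residual
#'   scale to 0.01.
#'
#' With `sigma_mu = 0` every gene-phenotype pair is null.
#'
#' @param scenario One of `"IA"`, `"IB"`, `"IIA"`, `"IIB"`, `"IIIA"`, `"IIIB"`.
#' @param sigma_mu Latent-factor standard deviation \eqn{\sigma_\mu \ge 0};
#'   the benchmark grid uses 0, 0.4, 0.6.
#' @param n_samples Sample size (benchmark grid: 100 or 30).
#' @param sigma_x Gene residual standard deviation (default 0.5).
#' @param sigma_k Length-10 vector of phenotype residual standard deviations;
#'   `NULL` takes the scenario default. Entries for non-gaussian phenotypes
#'   (scenario III, phenotypes 1-5) are ignored and may be `NA`.
#' @param sigma_c Confounder standard deviation (scenario II only; default 1).
#' @param n_genes Number of genes (default 4800; blocks are proportional
#'   thirds with the remainder in the last block).
#' @param seed Integer seed; every draw comes from this seed and the global
#'   RNG state is restored afterwards.
#' @return A `sim_config` list.
#' @seealso [simulate_dataset()], [make_fixture()]
#' @export
sim_config <- function(scenario = c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB"),
                       sigma_mu, n_samples = 100, sigma_x = 0.5,
                       sigma_k = NULL, sigma_c = 1, n_genes = 4800,
                       seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.numeric(sigma_mu) || length(sigma_mu) != 1L || sigma_mu < 0) {
    stop("sigma_mu must be a single non-negative number", call. = FALSE)
  }
  if (n_samples < 1 || n_samples != round(n_samples)) {
    stop("n_samples must be a positive integer", call. = FALSE)
  }
  if (n_genes < 3 || n_genes != round(n_genes)) {
    stop("n_genes must be an integer >= 3 (three gene blocks)", call. = FALSE)
  }
  if (sigma_x <= 0) stop("sigma_x must be positive", call. = FALSE)
  if (grepl("^II[AB]$", scenario) && sigma_c <= 0) {
    stop("sigma_c must be positive for scenario II", call. = FALSE)
  }
  if (is.null(sigma_k)) sigma_k <- default_sigma_k(scenario)
  if (length(sigma_k) != 10L) stop("sigma_k must have length 10", call. = FALSE)
  gaussian_k <- if (grepl("^III", scenario)) 6:10 else 1:10
  if (any(!is.finite(sigma_k[gaussian_k])) || any(sigma_k[gaussian_k] <= 0)) {
    stop("sigma_k must be positive for every gaussian phenotype", call. = FALSE)
  }
  structure(list(scenario = scenario, n_samples = as.integer(n_samples),
                 sigma_mu = sigma_mu, sigma_x = sigma_x, sigma_k = sigma_k,
                 sigma_c = sigma_c, n_genes = as.integer(n_genes),
                 n_phenotypes = 10L, seed = seed),
            class = "sim_config")
}

default_sigma_k <- function(scenario) {
  switch(scenario,
    IA  = ,
    IIA = c(rep(2, 9), 1),
    IB  = ,
    IIB = c(0.05, 2, 2, 2, 0.05, 2, 2, 2, 2, 1),
    IIIA = c(rep(NA_real_, 5), 2, 2, 2, 2, 1),
    IIIB = c(rep(NA_real_, 5), 0.01, 2, 2, 2, 1)
  )
}

# proportional thirds, remainder to the last block
gene_blocks <- function(n_genes) {
  b <- n_genes %/% 3L
  rep.int(1:3, c(b, b, n_genes - 2L * b))
}

#' Simulate a benchmark dataset
#'
#' Draws one dataset from the hierarchical random-effects model configured by
#' [sim_config()]: latent factors, block-structured gene expression, typed
#' phenotypes, the scenario-II confounder, and the truth indicator matrix
#' used for weight-selection sensitivity/specificity. A (gene, phenotype)
#' pair is truth-1 whenever the two share a latent factor (so block-1 genes,
#' which load on \eqn{u_1}, are associated with phenotypes 1-9, since
#' phenotypes 5-9 load on \eqn{u_1+u_2}); with `sigma_mu = 0` the truth
#' matrix is all zero.
#'
#' @param config A `sim_config`.
#' @return An `af_sim` list with elements `expression` (n x p matrix),
#'   `phenotypes` ([typed_phenotypes()]), `covariates` (n x 1 data frame for
#'   scenario II, else `NULL`), `truth_weights` (p x 10 binary matrix),
#'   `truth_blocks` (length-p block labels 1-3) and `config`.
#' @examples
#' ds <- simulate_dataset(sim_config("IA", sigma_mu = 0.6, n_samples = 50,
#'                                   n_genes = 30, seed = 1))
#' dim(ds$expression)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    return(withr::with_seed(config$seed, simulate_dataset_impl(config)))
  }
  simulate_dataset_impl(config)
}

simulate_dataset_impl <- function(config) {
  n <- config$n_samples; p <- config$n_genes; K <- 10L
  sc <- config$scenario
  u1 <- rnorm(n, 0, config$sigma_mu)
  u2 <- rnorm(n, 0, config$sigma_mu)
  u3 <- rnorm(n, 0, config$sigma_mu)
  is_ii <- grepl("^II[AB]$", sc)
  is_iii <- grepl("^III", sc)
  z <- if (is_ii) rnorm(n, 0, config$sigma_c) else NULL

  blocks <- gene_blocks(p)
  mu_gene <- cbind(u1, u2, u3)[, blocks, drop = FALSE]
  if (is_ii) mu_gene[, blocks == 1L] <- mu_gene[, blocks == 1L] + z
  X <- mu_gene + matrix(rnorm(n * p, 0, config$sigma_x), n, p)
  dimnames(X) <- list(paste0("sample_", seq_len(n)),
                      sprintf("gene_%04d", seq_len(p)))

  sk <- config$sigma_k
  Y <- matrix(0, n, K)
  if (is_iii) {
    rate <- exp(u1)
    if (any(!is.finite(rate) | rate <= 0)) {
      stop("non-positive Poisson rate after exp link", call. = FALSE)
    }
    for (k in 1:4) Y[, k] <- rpois(n, rate)
    Y[, 5] <- rbinom(n, 1, stats::plogis(u1 + u2))
    for (k in 6:9) Y[, k] <- rnorm(n, u1 + u2, sk[k])
    Y[, 10] <- rnorm(n, u3, sk[10])
    fams <- c(rep("poisson", 4), "binomial", rep("gaussian", 5))
  } else {
    zz <- if (is_ii) z else 0
    for (k in 1:4) Y[, k] <- rnorm(n, u1 + zz, sk[k])
    for (k in 5:9) Y[, k] <- rnorm(n, u1 + u2 + zz, sk[k])
    Y[, 10] <- rnorm(n, u3, sk[10])
    fams <- rep("gaussian", 10)
  }
  pheno_names <- paste0("pheno_", seq_len(K))
  colnames(Y) <- pheno_names
  names(fams) <- pheno_names
  phen <- typed_phenotypes(as.data.frame(Y), fams)

  truth <- matrix(0L, p, K,
                  dimnames = list(colnames(X), pheno_names))
  if (config$sigma_mu > 0) {
    truth[blocks == 1L, 1:9] <- 1L   # u1 feeds phenotypes 1-9
    truth[blocks == 2L, 5:9] <- 1L   # u2 feeds phenotypes 5-9
    truth[blocks == 3L, 10] <- 1L    # u3 feeds phenotype 10
  }
  covar <- if (is_ii) {
    stats::setNames(data.frame(z = z, row.names = rownames(X)), "z")
  } else NULL

  structure(list(expression = X, phenotypes = phen, covariates = covar,
                 truth_weights = truth, truth_blocks = blocks,
                 config = config),
            class = "af_sim")
}

#' @export
print.af_sim <- function(x, ...) {
  cat("<af_sim> scenario ", x$config$scenario,
      ": n = ", nrow(x$expression), ", genes = ", ncol(x$expression),
      ", phenotypes = ", ncol(x$truth_weights),
      ", sigma_mu = ", x$config$sigma_mu, "\n", sep = "")
  invisible(x)
}

#' Small deterministic fixture dataset
#'
#' A scaled-down analogue of the benchmark generator for unit tests and
#' examples: three gene blocks of proportional size driven by latent factors
#' `u1`, `u1+u2`, `u3`, with `K` gaussian phenotypes split across the three
#' factors (the last phenotype always loads on `u3`; optionally it is
#' replaced by a survival phenotype with exponential event times whose log
#' hazard is `u3`).
#'
#' @param n_samples,n_genes,K Positive integers; `n_genes >= 3` (three
#'   blocks), `K >= 3`.
#' @param seed Integer seed.
#' @param sigma_mu Latent scale (0 gives a global null fixture).
#' @param sigma_x,sigma_k Residual scales.
#' @param survival If `TRUE` the last phenotype is a survival outcome.
#' @return An `af_sim` object (see [simulate_dataset()]).
#' @examples
#' fx <- make_fixture(30, 60, K = 4, seed = 1)
#' fx$truth_blocks
#' @export
make_fixture <- function(n_samples = 30, n_genes = 60, K = 4, seed = 1,
                         sigma_mu = 1, sigma_x = 0.5, sigma_k = 1,
                         survival = FALSE) {
  if (n_samples < 1 || n_genes < 3 || K < 3 || seed != round(seed)) {
    stop("need n_samples >= 1, n_genes >= 3, K >= 3 and an integer seed",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    n <- as.integer(n_samples); p <- as.integer(n_genes); K <- as.integer(K)
    u1 <- rnorm(n, 0, sigma_mu); u2 <- rnorm(n, 0, sigma_mu)
    u3 <- rnorm(n, 0, sigma_mu)
    blocks <- gene_blocks(p)
    X <- cbind(u1, u2, u3)[, blocks, drop = FALSE] +
      matrix(rnorm(n * p, 0, sigma_x), n, p)
    dimnames(X) <- list(paste0("sample_", seq_len(n)),
                        sprintf("gene_%04d", seq_len(p)))
    # phenotype groups: 1..a on u1, a+1..K-1 on u1+u2, K on u3
    a <- max(1L, as.integer(round(0.4 * (K - 1))))
    mu_y <- cbind(matrix(u1, n, a),
                  matrix(u1 + u2, n, K - 1L - a),
                  u3)
    Y <- mu_y + matrix(rnorm(n * K, 0, sigma_k), n, K)
    pheno_names <- paste0("pheno_", seq_len(K))
    fams <- stats::setNames(rep("gaussian", K), pheno_names)
    ydf <- stats::setNames(as.data.frame(Y), pheno_names)
    if (survival) {
      tm <- rexp(n, rate = exp(u3))
      cens <- rexp(n, rate = mean(exp(u3)) / 2)
      last <- pheno_names[K]
      ydf[[last]] <- NULL
      ydf[[paste0(last, "_time")]] <- pmin(tm, cens)
      ydf[[paste0(last, "_event")]] <- as.integer(tm <= cens)
      fams[K] <- "survival"
    }
    phen <- typed_phenotypes(ydf, fams)
    truth <- matrix(0L, p, K, dimnames = list(colnames(X), pheno_names))
    if (sigma_mu > 0) {
      truth[blocks == 1L, seq_len(K - 1L)] <- 1L
      if (K - 1L > a) truth[blocks == 2L, (a + 1L):(K - 1L)] <- 1L
      truth[blocks == 3L, K] <- 1L
    }
    cfg <- list(scenario = "fixture", n_samples = n, sigma_mu = sigma_mu,
                sigma_x = sigma_x, sigma_k = rep(sigma_k, K), n_genes = p,
                n_phenotypes = K, seed = seed)
    structure(list(expression = X, phenotypes = phen, covariates = NULL,
                   truth_weights = truth, truth_blocks = blocks,
                   config = cfg),
              class = "af_sim")
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `expression.tsv` (samples in rows, genes in columns, first column
#' `sample`), `phenotypes.csv`, `phenotype_families.yaml`, and, when present,
#' `covariates.csv`, `truth_weights.tsv`, `truth_blocks.tsv`.
#'
#' @param dataset An `af_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "af_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- tibble::as_tibble(dataset$expression, rownames = "sample")
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  ph <- tibble::as_tibble(as.data.frame(dataset$phenotypes))
  ph <- tibble::add_column(ph, sample = rownames(dataset$expression),
                           .before = 1)
  readr::write_csv(ph, file.path(dir, "phenotypes.csv"))
  yaml::write_yaml(as.list(pheno_families(dataset$phenotypes)),
                   file.path(dir, "phenotype_families.yaml"))
  if (!is.null(dataset$covariates)) {
    cv <- tibble::as_tibble(dataset$covariates)
    cv <- tibble::add_column(cv, sample = rownames(dataset$expression),
                             .before = 1)
    readr::write_csv(cv, file.path(dir, "covariates.csv"))
  }
  if (!is.null(dataset$truth_weights)) {
    tw <- tibble::as_tibble(dataset$truth_weights, rownames = "gene")
    readr::write_tsv(tw, file.path(dir, "truth_weights.tsv"))
    readr::write_tsv(tibble::tibble(gene = rownames(dataset$truth_weights),
                                    block = dataset$truth_blocks),
                     file.path(dir, "truth_blocks.tsv"))
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `expression.tsv`, `phenotypes.csv` and
#'   `phenotype_families.yaml` (plus optional covariate/truth files).
#' @param transposed_expression Set `TRUE` if `expression.tsv` stores genes
#'   in rows (first column the gene ID) rather than the default layout.
#' @return A list shaped like an `af_sim` object.
#' @export
read_dataset <- function(dir, transposed_expression = FALSE) {
  expr <- readr::read_tsv(file.path(dir, "expression.tsv"),
                          show_col_types = FALSE)
  X <- as.matrix(expr[, -1]); rownames(X) <- expr[[1]]
  if (transposed_expression) X <- t(X)
  fams <- unlist(yaml::read_yaml(file.path(dir, "phenotype_families.yaml")))
  ph <- readr::read_csv(file.path(dir, "phenotypes.csv"),
                        show_col_types = FALSE)
  stopifnot(identical(ph[[1]], rownames(X)))
  phen <- typed_phenotypes(ph[, -1], fams)
  covar <- NULL
  cv_path <- file.path(dir, "covariates.csv")
  if (file.exists(cv_path)) {
    cv <- readr::read_csv(cv_path, show_col_types = FALSE)
    covar <- as.data.frame(cv[, -1], row.names = cv[[1]])
  }
  truth <- NULL; blocks <- NULL
  tw_path <- file.path(dir, "truth_weights.tsv")
  if (file.exists(tw_path)) {
    tw <- readr::read_tsv(tw_path, show_col_types = FALSE)
    truth <- as.matrix(tw[, -1]); rownames(truth) <- tw[[1]]
    tb <- readr::read_tsv(file.path(dir, "truth_blocks.tsv"),
                          show_col_types = FALSE)
    blocks <- tb$block
  }
  structure(list(expression = X, phenotypes = phen, covariates = covar,
                 truth_weights = truth, truth_blocks = blocks,
                 config = NULL),
            class = "af_sim")
}
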