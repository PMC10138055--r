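#' Empirical rejection rate
#'
#' Fraction of (replicate, gene) p-values below `alpha` — the type I error
#' estimate under a global-null scenario, the power estimate otherwise.
#' Applied to unadjusted gene p-values.
#'
#' @param pvalues Numeric vector or matrix (replicates x genes) of p-values.
#' @param alpha Rejection threshold (default 0.05).
#' @return Scalar rate in `[0, 1]`.
#' @export
rejection_rate <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(as.matrix(pvalues))
  stopifnot(all(p >= 0 & p <= 1))
  mean(p < alpha)
}

# binomial Monte-Carlo standard error, treating (replicate, gene) draws as
# independent; genes within a replicate share latent factors, so this
# understates the true error somewhat
rate_mc_se <- function(rate, n) sqrt(rate * (1 - rate) / n)

#' Weight-estimation sensitivity and specificity
#'
#' Sensitivity is the proportion of truly associated (gene, phenotype)
#' pairs assigned weight 1; specificity the proportion of truly null pairs
#' assigned weight 0, pooled over genes, phenotypes and replicates. With no
#' truth-1 pairs (a global-null scenario) sensitivity is undefined and a
#' flagged `NaN` is returned.
#'
#' @param estimates Binary weight estimates: a p x K matrix, or a
#'   replicates x p x K array, or a list of p x K matrices.
#' @param truth p x K binary truth indicator (recycled across replicates).
#' @return Scalar proportion (or `NaN`).
#' @export
weight_sensitivity <- function(estimates, truth) {
  est <- stack_weight_estimates(estimates, truth)
  denom <- sum(est$truth == 1)
  if (denom == 0) {
    warning("no truly associated pairs; sensitivity undefined",
            call. = FALSE)
    return(NaN)
  }
  sum(est$w[est$truth == 1]) / denom
}

#' @rdname weight_sensitivity
#' @export
weight_specificity <- function(estimates, truth) {
  est <- stack_weight_estimates(estimates, truth)
  denom <- sum(est$truth == 0)
  if (denom == 0) {
    warning("no truly null pairs; specificity undefined", call. = FALSE)
    return(NaN)
  }
  sum(1 - est$w[est$truth == 0]) / denom
}

stack_weight_estimates <- function(estimates, truth) {
  truth <- as.matrix(truth)
  if (is.list(estimates)) {
    w <- do.call(rbind, lapply(estimates, as.matrix))
    tt <- do.call(rbind, rep(list(truth), length(estimates)))
  } else if (length(dim(estimates)) == 3) {
    Srep <- dim(estimates)[1]
    w <- do.call(rbind, lapply(seq_len(Srep), function(s) {
      matrix(estimates[s, , ], dim(estimates)[2], dim(estimates)[3])
    }))
    tt <- do.call(rbind, rep(list(truth), Srep))
  } else {
    w <- as.matrix(estimates)
    tt <- truth
  }
  stopifnot(identical(dim(w), dim(tt)), all(w %in% c(0, 1)),
            all(tt %in% c(0, 1)))
  list(w = w, truth = tt)
}

#' Average estimated weight per phenotype and gene block
#'
#' Means of the binary weight estimates over the genes of each block (and
#' over replicates when given several estimate matrices) — the table used
#' to inspect whether a method selects all associated phenotypes evenly or
#' concentrates on the strongest one.
#'
#' @param estimates As in [weight_sensitivity()].
#' @param blocks Length-p integer block labels partitioning the genes.
#' @return Tibble with `phenotype`, one column per block (`block_1`, ...).
#' @export
block_average_weights <- function(estimates, blocks) {
  if (is.list(estimates)) {
    acc <- Reduce(`+`, lapply(estimates, as.matrix)) / length(estimates)
  } else if (length(dim(estimates)) == 3) {
    acc <- apply(estimates, c(2, 3), mean)
  } else {
    acc <- as.matrix(estimates)
  }
  stopifnot(length(blocks) == nrow(acc))
  pheno <- colnames(acc) %||% paste0("pheno_", seq_len(ncol(acc)))
  out <- tibble::tibble(phenotype = pheno)
  for (b in sort(unique(blocks))) {
    out[[paste0("block_", b)]] <- colMeans(acc[blocks == b, , drop = FALSE])
  }
  out
}

#' Run the simulation benchmark
#'
#' Loops simulate -> test -> metrics over a grid of scenarios and latent
#' effect scales, producing a table of rejection rates (type I error when
#' `sigma_mu = 0`, power otherwise) with Monte-Carlo standard errors, and —
#' for the adaptive methods — weight sensitivity, specificity and
#' block-average weight tables. All replicate seeds derive from `seed`, so
#' identical calls give identical reports. With `checkpoint_dir` set, each
#' completed (scenario, sigma_mu) cell is saved there and re-used when the
#' call is interrupted and repeated.
#'
#' @param scenarios Character vector of scenario codes (see [sim_config()]).
#' @param sigma_mu Numeric vector of latent scales.
#' @param S Replicate datasets per cell.
#' @param n_samples,n_genes,B Reduced-scale knobs (see the package
#'   vignette for the choices used in the shipped checks).
#' @param methods Methods to evaluate (see [af_test()]).
#' @param alpha Rejection threshold on unadjusted gene p-values.
#' @param seed Master seed.
#' @param adjust_covariates Pass the scenario-II confounder to the observed
#'   fits (`FALSE` gives the naive, unadjusted pipeline whose type I error
#'   inflates under confounding).
#' @param checkpoint_dir Optional directory for per-cell checkpoints.
#' @return An `af_benchmark` tibble: one row per (scenario, sigma_mu,
#'   method) with `rate`, `mc_se`, `sensitivity`, `specificity`; the
#'   per-cell block-average weight tables are in
#'   `attr(x, "block_weights")`.
#' @export
run_benchmark <- function(scenarios = "IA", sigma_mu = c(0, 0.4, 0.6),
                          S = 50, n_samples = 100, n_genes = 480, B = 200,
                          methods = c("afp", "afz", "fisher", "minp"),
                          alpha = 0.05, seed = 1, adjust_covariates = TRUE,
                          checkpoint_dir = NULL) {
  cells <- expand.grid(scenario = scenarios, sigma_mu = sigma_mu,
                       stringsAsFactors = FALSE)
  stopifnot(nrow(cells) >= 1, S >= 1)
  seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, 2L * S * nrow(cells)),
    nrow = 2L * S))
  rows <- list()
  block_weights <- list()
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]; sm <- cells$sigma_mu[ci]
    cell_id <- sprintf("%s_sigma%s_S%d_p%d_B%d", sc, sm, S, n_genes, B)
    cp_file <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, paste0(cell_id, ".rds"))
    } else NULL
    if (!is.null(cp_file) && file.exists(cp_file)) {
      cell <- readRDS(cp_file)
    } else {
      cell <- run_benchmark_cell(sc, sm, S, n_samples, n_genes, B, methods,
                                 alpha, seeds[, ci], adjust_covariates)
      if (!is.null(cp_file)) {
        dir.create(dirname(cp_file), recursive = TRUE, showWarnings = FALSE)
        saveRDS(cell, cp_file)
      }
    }
    rows[[ci]] <- cell$rows
    block_weights[[cell_id]] <- cell$block_weights
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "block_weights") <- block_weights
  attr(out, "params") <- list(S = S, n_samples = n_samples,
                              n_genes = n_genes, B = B, alpha = alpha,
                              seed = seed,
                              adjust_covariates = adjust_covariates)
  class(out) <- c("af_benchmark", class(out))
  out
}

run_benchmark_cell <- function(scenario, sigma_mu, S, n_samples, n_genes, B,
                               methods, alpha, cell_seeds, adjust_covariates) {
  adaptive <- intersect(methods, c("afp", "afz"))
  pvals <- lapply(stats::setNames(methods, methods),
                  function(m) matrix(NA_real_, S, n_genes))
  w_sum <- lapply(stats::setNames(adaptive, adaptive),
                  function(m) 0)
  truth <- NULL; blocks <- NULL
  for (s in seq_len(S)) {
    cfg <- sim_config(scenario, sigma_mu = sigma_mu, n_samples = n_samples,
                      n_genes = n_genes, seed = cell_seeds[2 * s - 1])
    ds <- simulate_dataset(cfg)
    truth <- ds$truth_weights; blocks <- ds$truth_blocks
    Z <- if (adjust_covariates) ds$covariates else NULL
    fit <- af_test(ds$expression, ds$phenotypes, covariates = Z,
                   methods = methods, B = B, seed = cell_seeds[2 * s])
    for (m in methods) pvals[[m]][s, ] <- fit$results[[paste0("p_", m)]]
    for (m in adaptive) w_sum[[m]] <- w_sum[[m]] + fit[[paste0("w_", m)]]
  }
  n_pairs <- S * n_genes
  rows <- purrr::map_dfr(methods, function(m) {
    r <- rejection_rate(pvals[[m]], alpha)
    sens <- spec <- NA_real_
    if (m %in% adaptive) {
      wbar <- w_sum[[m]] / S                 # mean weight per (gene, pheno)
      if (sum(truth == 1) > 0) {
        sens <- sum(wbar[truth == 1]) / sum(truth == 1)
      } else sens <- NaN
      spec <- sum(1 - wbar[truth == 0]) / sum(truth == 0)
    }
    tibble::tibble(scenario = scenario, sigma_mu = sigma_mu,
                   n_samples = n_samples, method = m, S = S,
                   rate = r, mc_se = rate_mc_se(r, n_pairs),
                   sensitivity = sens, specificity = spec)
  })
  bw <- lapply(w_sum, function(ws) block_average_weights(ws / S, blocks))
  list(rows = rows, block_weights = bw)
}

#' @rdname run_benchmark
#' @param object An `af_benchmark` table.
#' @param ... Unused.
#' @export
autoplot.af_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma_mu, y = .data$rate,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$rate - 2 * .data$mc_se),
      ymax = pmin(1, .data$rate + 2 * .data$mc_se))) +
    ggplot2::facet_wrap(~ .data$scenario) +
    ggplot2::labs(x = expression(sigma[mu]),
                  y = "rejection rate at 0.05",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
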