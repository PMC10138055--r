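#' Keep the genes with the largest coefficients of variation
#'
#' Standard pre-filter for expression arrays: ranks genes by CV = sd/mean
#' and keeps the `top_n` most variable, removing housekeeping-like genes
#' before testing. Genes with non-positive mean are excluded from the
#' ranking (with a message of the count). Computed on the expression scale
#' as given; set `log2_transform = TRUE` to rank on `log2(x + 1)` first.
#' Ties are broken by gene ID, so the result is deterministic.
#'
#' @param expression Samples x genes matrix or data frame.
#' @param top_n Number of genes to keep (`top_n = p` is the identity).
#' @param log2_transform Apply `log2(x + 1)` before computing CVs.
#' @return The filtered expression matrix (columns ordered as in the
#'   input).
#' @export
filter_by_cv <- function(expression, top_n, log2_transform = FALSE) {
  X <- as_expression_matrix(expression)
  stopifnot(top_n >= 1, top_n <= ncol(X))
  Xr <- if (log2_transform) log2(X + 1) else X
  mu <- colMeans(Xr)
  sdv <- apply(Xr, 2, sd)
  ok <- mu > 0
  if (any(!ok)) {
    message(sum(!ok), " gene(s) with non-positive mean excluded from CV ",
            "ranking")
  }
  cv <- ifelse(ok, sdv / mu, -Inf)
  ids <- colnames(X) %||% sprintf("gene_%04d", seq_len(ncol(X)))
  ord <- order(-cv, ids)
  keep <- sort(ord[seq_len(min(top_n, sum(ok)))])
  X[, keep, drop = FALSE]
}

#' Drop samples with missing phenotypes or covariates
#'
#' Complete-case alignment across the phenotype table, covariates and
#' expression: any sample with a missing phenotype or covariate value is
#' removed from all three, and the removed IDs are reported.
#'
#' @param phenotypes Samples x phenotypes data frame (may contain `NA`).
#' @param covariates Optional samples x M data frame (may contain `NA`).
#' @param expression Samples x genes matrix or data frame.
#' @return List with the filtered `phenotypes`, `covariates`, `expression`,
#'   plus `dropped` (IDs or indices removed) and `n` (samples kept).
#' @export
drop_incomplete_samples <- function(phenotypes, covariates = NULL,
                                    expression) {
  X <- as_expression_matrix(expression)
  ph <- as.data.frame(phenotypes)
  n <- nrow(X)
  stopifnot(nrow(ph) == n,
            is.null(covariates) || NROW(covariates) == n)
  bad <- rowSums(is.na(ph)) > 0
  if (!is.null(covariates)) {
    bad <- bad | rowSums(is.na(as.data.frame(covariates))) > 0
  }
  ids <- rownames(X) %||% as.character(seq_len(n))
  M <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (sum(!bad) < M + 3) {
    stop("only ", sum(!bad), " complete samples remain (need at least ",
         M + 3, ")", call. = FALSE)
  }
  if (any(bad)) {
    message("dropped ", sum(bad), " sample(s) with missing values; n = ",
            sum(!bad), " remain")
  }
  list(phenotypes = ph[!bad, , drop = FALSE],
       covariates = if (is.null(covariates)) NULL else {
         as.data.frame(covariates)[!bad, , drop = FALSE]
       },
       expression = X[!bad, , drop = FALSE],
       dropped = ids[bad], n = sum(!bad))
}

#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end workflow into one serializable
#' list. Either `data_dir` (a directory in the [write_dataset()] layout) or
#' an in-memory `dataset` must be supplied when running the pipeline.
#'
#' @param data_dir Directory with `expression.tsv`, `phenotypes.csv`,
#'   `phenotype_families.yaml` (optional `covariates.csv`).
#' @param out_dir Output directory for result tables, logs and the
#'   resolved configuration.
#' @param top_n_cv Optional CV-filter size (`NULL` skips the filter).
#' @param log2_cv Rank CVs on `log2(x + 1)`.
#' @param methods,B,seed,smooth,adjust_method,alpha As in [af_test()].
#' @param L,B_boot,seed_boot Bootstrap knobs (see [bootstrap_weights()]);
#'   `L = 0` skips bootstrap, co-membership and clustering.
#' @param cluster_method,alpha_tight,min_size,k_min,k_max As in
#'   [tight_cluster()].
#' @param transposed_expression Expression file stores genes in rows.
#' @return A `run_config` list.
#' @export
run_config <- function(data_dir = NULL, out_dir = tempfile("afcombine_run_"),
                       top_n_cv = NULL, log2_cv = FALSE,
                       methods = c("afp", "afz", "fisher", "minp"),
                       B = 100, seed = 1, smooth = FALSE,
                       adjust_method = "BH", alpha = 0.05,
                       L = 0, B_boot = 50, seed_boot = 1,
                       cluster_method = "consensus", alpha_tight = 0.7,
                       min_size = 5, k_min = 2, k_max = 10,
                       transposed_expression = FALSE) {
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 top_n_cv = top_n_cv, log2_cv = log2_cv, methods = methods,
                 B = B, seed = seed, smooth = smooth,
                 adjust_method = adjust_method, alpha = alpha, L = L,
                 B_boot = B_boot, seed_boot = seed_boot,
                 cluster_method = cluster_method, alpha_tight = alpha_tight,
                 min_size = min_size, k_min = k_min, k_max = k_max,
                 transposed_expression = transposed_expression),
            class = "run_config")
}

#' Run the full association workflow
#'
#' filter -> p-values -> adaptive tests + baselines -> adjustment ->
#' bootstrap -> co-membership -> module clustering -> summaries. All result
#' tables, a log and the resolved configuration are written under
#' `config$out_dir`; a repeated run with an identical resolved
#' configuration re-uses the written tables (content cache) and returns
#' bit-identical results.
#'
#' @param config A [run_config()].
#' @param dataset Optional in-memory `af_sim`-shaped dataset (used instead
#'   of `config$data_dir`).
#' @return List with `fit` ([af_test()] result), `significant` (gene IDs at
#'   the adjusted cutoff for the first method), and when `L > 0`: `boot`,
#'   `V`, `modules`, `summary`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  resolved <- c(unclass(config),
                list(package_version = as.character(
                  utils::packageVersion("afcombine"))))
  resolved$out_dir <- NULL
  done_marker <- file.path(out_dir, "results.tsv")
  cfg_text <- yaml::as.yaml(resolved)
  if (file.exists(cfg_path) && file.exists(done_marker) &&
      identical(paste(readLines(cfg_path), collapse = "\n"),
                sub("\n$", "", cfg_text))) {
    log_line(out_dir, "cache hit: outputs already present for this config")
    return(read_pipeline_outputs(out_dir, config))
  }
  cat(cfg_text, file = cfg_path)

  if (is.null(dataset)) {
    stopifnot(!is.null(config$data_dir))
    dataset <- read_dataset(config$data_dir, config$transposed_expression)
  }
  X <- dataset$expression
  phen <- dataset$phenotypes
  Z <- dataset$covariates
  log_line(out_dir, sprintf("input: n = %d, p = %d, K = %d, M = %d",
                            nrow(X), ncol(X), length(pheno_families(phen)),
                            if (is.null(Z)) 0L else ncol(Z)))
  cc <- drop_incomplete_samples(as.data.frame(phen), Z, X)
  if (length(cc$dropped)) {
    log_line(out_dir, sprintf("dropped %d incomplete sample(s): %s",
                              length(cc$dropped),
                              paste(cc$dropped, collapse = ", ")))
  }
  phen <- typed_phenotypes(cc$phenotypes, pheno_families(phen))
  X <- cc$expression; Z <- cc$covariates
  if (!is.null(config$top_n_cv)) {
    X <- filter_by_cv(X, config$top_n_cv, config$log2_cv)
    log_line(out_dir, sprintf("CV filter kept %d genes", ncol(X)))
  }

  fit <- af_test(X, phen, covariates = Z, methods = config$methods,
                 B = config$B, seed = config$seed, smooth = config$smooth,
                 adjust_method = config$adjust_method, alpha = config$alpha)
  readr::write_tsv(fit$results, file.path(out_dir, "results.tsv"))
  log_line(out_dir, sprintf("tested %d genes with B = %d (pooled null %d)",
                            nrow(fit$results), config$B, fit$N_null))

  m1 <- config$methods[1]
  qcol <- fit$results[[paste0("q_", m1)]]
  significant <- fit$results$gene[qcol < config$alpha]
  readr::write_tsv(tibble::tibble(gene = significant),
                   file.path(out_dir, "significant_genes.tsv"))
  log_line(out_dir, sprintf("%d significant genes (%s, %s < %g)",
                            length(significant), m1, config$adjust_method,
                            config$alpha))

  out <- list(fit = fit, significant = significant)
  if (config$L > 0 && length(significant) > 1) {
    boot <- bootstrap_weights(X, phen, Z,
                              method = intersect(config$methods,
                                                 c("afp", "afz")),
                              L = config$L, B_boot = config$B_boot,
                              seed = config$seed_boot)
    U <- variability_index(boot, method = m1)
    readr::write_tsv(tibble::as_tibble(U, rownames = "gene"),
                     file.path(out_dir, "variability_index.tsv"))
    V <- co_membership(boot, genes = significant, method = m1)
    readr::write_tsv(tibble::as_tibble(V, rownames = "gene"),
                     file.path(out_dir, "co_membership.tsv"))
    modules <- tight_cluster(V, k_min = config$k_min, k_max = config$k_max,
                             alpha_tight = config$alpha_tight,
                             min_size = config$min_size,
                             method = config$cluster_method,
                             seed = config$seed_boot)
    readr::write_tsv(modules$assignment,
                     file.path(out_dir, "modules.tsv"))
    if (length(modules$modules)) {
      summ <- module_summary(modules, boot, clip_p(fit$obs$p), method = m1)
      readr::write_tsv(summ, file.path(out_dir, "module_summary.tsv"))
      out$summary <- summ
    }
    log_line(out_dir, sprintf("bootstrap L = %d; %d modules, %d scattered",
                              config$L, length(modules$modules),
                              sum(modules$assignment$module == "scattered")))
    out$boot <- boot; out$V <- V; out$modules <- modules
  }
  out
}

log_line <- function(out_dir, msg) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
      file = file.path(out_dir, "run.log"), append = TRUE, sep = "")
  invisible(msg)
}

read_pipeline_outputs <- function(out_dir, config) {
  res <- readr::read_tsv(file.path(out_dir, "results.tsv"),
                         show_col_types = FALSE)
  sig <- readr::read_tsv(file.path(out_dir, "significant_genes.tsv"),
                         show_col_types = FALSE)
  list(fit = list(results = res), significant = sig$gene, cached = TRUE)
}
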