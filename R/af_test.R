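#' Adaptive Fisher association tests for every gene
#'
#' The main entry point: tests each gene's expression against all K declared
#' phenotypes at once under the union-intersection null (no phenotype
#' associated vs. at least one associated). Per-pair GLM p-values are
#' combined by the adaptive Fisher statistics — AFp (minimal pooled
#' permutation p-value over all non-empty phenotype subsets) and AFz
#' (maximal z-standardized weighted statistic) — whose optimizing binary
#' weight vector doubles as the phenotype-selection estimate. Fisher and
#' minP baselines are evaluated under the identical pooled residual-
#' permutation null, so method comparisons share one permutation pass.
#'
#' @param expression Samples x genes numeric matrix or data frame (a
#'   `sample` column, if present, becomes row names).
#' @param phenotypes A [typed_phenotypes()] table, or a plain data frame
#'   together with `families`.
#' @param covariates Optional samples x M data frame; observed fits adjust
#'   for these and the null permutes covariate-residualized expression.
#' @param families Phenotype families when `phenotypes` is a plain data
#'   frame (see [typed_phenotypes()]).
#' @param methods Any of `"afp"`, `"afz"`, `"fisher"`, `"minp"`.
#' @param B Number of permutations; the pooled null has `B * p` draws.
#' @param seed Integer seed for the permutations.
#' @param engine `"cpp"` (compiled subset scan; default) or `"r"`
#'   (reference implementation, small problems only).
#' @param stat_engine Passed to [observed_matrices()].
#' @param smooth Report add-one smoothed counts `(c+1)/(N+1)` instead of the
#'   literal `c/N` (avoids zero p-values in -log10 displays).
#' @param null_with_covariates Include the covariates in the null-side
#'   regressions so the null mirrors the observed model (default whenever
#'   covariates are supplied; without this the fixed-weight Fisher baseline
#'   is conservative under confounding, because adjusted observed p-values
#'   are compared against confounder-correlated null p-values). Set
#'   `FALSE` for the intercept-plus-permuted-residual-only variant.
#' @param adjust_method Gene-level multiplicity adjustment: `"BH"` or
#'   `"bonferroni"`.
#' @param alpha Significance cutoff applied to adjusted p-values.
#' @param k_cap Refuse K above this cap (the scan is exhaustive over
#'   `2^K - 1` subsets). Raise knowingly.
#' @param perms Optional pre-drawn permutation matrix (test hook).
#' @param eps P-value floor before log transforms.
#' @param keep_null Keep the null tensor in the returned object
#'   (memory-heavy; for diagnostics).
#' @return An `af_fit` object; `$results` is a tibble with one row per gene
#'   (statistics, permutation p-values `p_*`, adjusted `q_*`, binary weight
#'   columns `w_afp_*` / `w_afz_*` and effect-direction `sign_*` columns).
#'   [tidy()], [glance()] and [autoplot()] methods are available.
#' @examples
#' fx <- make_fixture(40, 24, K = 4, seed = 7)
#' fit <- af_test(fx$expression, fx$phenotypes, B = 40, seed = 1)
#' head(tidy(fit))
#' @export
af_test <- function(expression, phenotypes, covariates = NULL,
                    families = NULL,
                    methods = c("afp", "afz", "fisher", "minp"),
                    B = 100, seed = NULL,
                    engine = c("cpp", "r"),
                    stat_engine = c("score", "glm"),
                    smooth = FALSE, null_with_covariates = !is.null(covariates),
                    adjust_method = c("BH", "bonferroni"), alpha = 0.05,
                    k_cap = 12, perms = NULL, eps = 1e-300,
                    keep_null = FALSE) {
  engine <- match.arg(engine)
  stat_engine <- match.arg(stat_engine)
  adjust_method <- match.arg(adjust_method)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!inherits(phenotypes, "typed_phenotypes")) {
    if (is.null(families)) {
      stop("supply a typed_phenotypes table or a families vector",
           call. = FALSE)
    }
    phenotypes <- typed_phenotypes(phenotypes, families)
  }
  X <- as_expression_matrix(expression)
  K <- length(pheno_families(phenotypes))
  if (K > k_cap) {
    stop("K = ", K, " phenotypes means 2^K - 1 = ", 2^K - 1,
         " subsets; reduce K or raise k_cap knowingly", call. = FALSE)
  }

  obs <- observed_matrices(phenotypes, X, covariates,
                           engine = stat_engine, eps = eps)
  E <- residualize(X, covariates)
  nt <- null_tensor(phenotypes, E, B = B, seed = seed,
                    covariates = covariates,
                    with_covariates = null_with_covariates,
                    perms = perms, eps = eps)
  fit <- af_test_from_matrices(obs, nt, methods = methods, engine = engine,
                               smooth = smooth, eps = eps,
                               adjust_method = adjust_method, alpha = alpha)
  fit$n_samples <- nrow(X)
  if (keep_null) fit$null_tensor <- nt
  fit$perms <- nt$perms
  fit
}

# core combination step given observed matrices and a null tensor; also the
# entry point when p-values were produced elsewhere
af_test_from_matrices <- function(obs, nulls, methods, engine = "cpp",
                                  smooth = FALSE, eps = 1e-300,
                                  adjust_method = "BH", alpha = 0.05,
                                  weights_only = FALSE) {
  NLP_null <- null_nlp_matrix(nulls, eps)
  NLP_obs <- -log(clip_p(obs$p, eps))
  N <- nrow(NLP_null)
  genes <- rownames(obs$p)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(nrow(obs$p)))
  pheno <- colnames(obs$p)
  res <- tibble::tibble(gene = genes)
  out <- list(results = NULL, methods = methods, smooth = smooth,
              obs = obs, N_null = N, B = nulls$B, alpha = alpha,
              adjust_method = adjust_method)

  do_afp <- "afp" %in% methods
  do_afz <- "afz" %in% methods
  if (do_afp || do_afz) {
    if (engine == "cpp") {
      sc <- af_scan_cpp(NLP_null, NLP_obs, do_afp, do_afz, !weights_only)
      if (do_afp) {
        afp <- list(count = sc$afp$count, w = sc$afp$w,
                    null_count = sc$afp$null_count)
      }
      if (do_afz) {
        afz <- list(stat = sc$afz$stat, w = sc$afz$w,
                    null_stat = sc$afz$null_stat)
      }
    } else {
      tab <- null_stat_table(NLP_null_as_p(NLP_null), eps)
      pmat <- clip_p(obs$p, eps)
      if (do_afp) {
        gg <- lapply(seq_len(nrow(pmat)),
                     function(j) afp_gene(pmat[j, ], tab))
        afp <- list(count = vapply(gg, `[[`, numeric(1), "count"),
                    w = do.call(rbind, lapply(gg, `[[`, "w")),
                    null_count = if (weights_only) NULL else
                      round(null_statistics(tab, "afp") * N))
      }
      if (do_afz) {
        gg <- lapply(seq_len(nrow(pmat)),
                     function(j) afz_gene(pmat[j, ], tab))
        afz <- list(stat = vapply(gg, `[[`, numeric(1), "T"),
                    w = do.call(rbind, lapply(gg, `[[`, "w")),
                    null_stat = if (weights_only) NULL else
                      null_statistics(tab, "afz"))
      }
    }
    if (do_afp) {
      res$stat_afp <- pool_count(afp$count, N, smooth)
      if (!weights_only) {
        res$p_afp <- gene_pvalues(afp$count, afp$null_count, "afp", smooth)
        res$q_afp <- p.adjust(res$p_afp, adjust_method)
      }
      wdf <- as.data.frame(afp$w)
      names(wdf) <- paste0("w_afp_", pheno)
      res <- dplyr::bind_cols(res, wdf)
      out$w_afp <- matrix(afp$w, ncol = length(pheno),
                          dimnames = list(genes, pheno))
    }
    if (do_afz) {
      res$stat_afz <- afz$stat
      if (!weights_only) {
        res$p_afz <- gene_pvalues(afz$stat, afz$null_stat, "afz", smooth)
        res$q_afz <- p.adjust(res$p_afz, adjust_method)
      }
      wdf <- as.data.frame(afz$w)
      names(wdf) <- paste0("w_afz_", pheno)
      res <- dplyr::bind_cols(res, wdf)
      out$w_afz <- matrix(afz$w, ncol = length(pheno),
                          dimnames = list(genes, pheno))
    }
  }

  if (!weights_only) {
    if ("fisher" %in% methods) {
      bl <- baseline_pvalues_nlp(NLP_obs, NLP_null, "fisher", smooth)
      res$stat_fisher <- bl$stat
      res$p_fisher <- bl$p
      res$q_fisher <- p.adjust(bl$p, adjust_method)
    }
    if ("minp" %in% methods) {
      bl <- baseline_pvalues_nlp(NLP_obs, NLP_null, "minp", smooth)
      res$stat_minp <- bl$stat
      res$p_minp <- bl$p
      res$q_minp <- p.adjust(bl$p, adjust_method)
    }
  }

  sdf <- as.data.frame(obs$sign)
  names(sdf) <- paste0("sign_", pheno)
  res <- dplyr::bind_cols(res, sdf)
  out$results <- res
  structure(out, class = "af_fit")
}

# reference-path helper: turn a -log p matrix back into p for null_stat_table
NLP_as_p <- function(NLP) exp(-NLP)
NLP_null_as_p <- NLP_as_p

#' @export
print.af_fit <- function(x, ...) {
  cat("<af_fit> ", nrow(x$results), " genes, ", ncol(x$obs$p),
      " phenotypes, pooled null size ", x$N_null, "\n", sep = "")
  for (m in intersect(x$methods, c("afp", "afz", "fisher", "minp"))) {
    qc <- x$results[[paste0("q_", m)]]
    if (!is.null(qc)) {
      cat("  ", m, ": ", sum(qc < x$alpha), " genes at ",
          x$adjust_method, " < ", x$alpha, "\n", sep = "")
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname af_test
#' @param x,object An `af_fit` object.
#' @param ... Unused.
#' @export
tidy.af_fit <- function(x, ...) {
  res <- x$results
  long <- purrr::map_dfr(intersect(x$methods,
                                   c("afp", "afz", "fisher", "minp")),
    function(m) {
      tibble::tibble(gene = res$gene, method = m,
                     statistic = res[[paste0("stat_", m)]],
                     p.value = res[[paste0("p_", m)]],
                     q.value = res[[paste0("q_", m)]])
    })
  long
}

#' @rdname af_test
#' @export
glance.af_fit <- function(x, ...) {
  res <- x$results
  out <- tibble::tibble(n_genes = nrow(res), n_phenotypes = ncol(x$obs$p),
                        B = x$B, null_size = x$N_null, alpha = x$alpha,
                        adjust_method = x$adjust_method)
  for (m in intersect(x$methods, c("afp", "afz", "fisher", "minp"))) {
    qc <- res[[paste0("q_", m)]]
    if (!is.null(qc)) out[[paste0("n_sig_", m)]] <- sum(qc < x$alpha)
  }
  out
}

#' @rdname af_test
#' @export
autoplot.af_fit <- function(object, ...) {
  df <- tidy(object)
  df$neglog10 <- -log10(pmax(df$p.value, 1 / (object$N_null + 1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$neglog10)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.5) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "permutation p-value"),
                  title = "Gene-level association evidence by method") +
    ggplot2::theme_minimal()
}
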