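#' Fisher's combination statistic
#'
#' \eqn{T = -2 \sum_k \log p_k}. For example, `c(0.001, 1, 1)` and
#' `c(0.1, 0.1, 0.1)` both give 13.8 (3 s.f.) — identical evidence by
#' Fisher's measure despite very different phenotype-selection
#' interpretations, which is what the adaptive weights disambiguate.
#'
#' @param pvec P-values in `(0, 1]`.
#' @return Non-negative scalar.
#' @export
fisher_statistic <- function(pvec) {
  check_pvec(pvec)
  2 * weighted_stat(pvec, rep(1, length(pvec)))
}

#' Minimum p-value combination statistic
#' @param pvec P-values in `(0, 1]`.
#' @return `min(pvec)`, in `(0, 1]`.
#' @export
minp_statistic <- function(pvec) {
  check_pvec(pvec)
  min(pvec)
}

#' Baseline combination tests under the shared permutation null
#'
#' Evaluates the Fisher and minP statistics gene by gene and converts them
#' to pooled permutation p-values using the same null tensor as the
#' adaptive tests (right tail for Fisher, left tail for minP), so the
#' baselines and the adaptive methods are compared under one identical
#' null.
#'
#' @param obs An `af_obs` from [observed_matrices()].
#' @param nulls An `af_null_tensor` (or null p-value matrix).
#' @param method `"fisher"` or `"minp"`.
#' @param smooth Add-one smoothing of the pooled counts.
#' @param eps P-value floor.
#' @return Tibble with `gene`, `method`, `statistic`, `p.value`.
#' @export
baseline_pvalues <- function(obs, nulls, method = c("fisher", "minp"),
                             smooth = FALSE, eps = 1e-300) {
  method <- match.arg(method)
  NLP_obs <- -log(clip_p(obs$p, eps))
  NLP_null <- null_nlp_matrix(nulls, eps)
  bl <- baseline_pvalues_nlp(NLP_obs, NLP_null, method, smooth)
  genes <- rownames(obs$p)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(nrow(obs$p)))
  tibble::tibble(gene = genes, method = method, statistic = bl$stat,
                 p.value = bl$p)
}

baseline_pvalues_nlp <- function(NLP_obs, NLP_null, method, smooth = FALSE) {
  N <- nrow(NLP_null)
  if (method == "fisher") {
    stat <- 2 * rowSums(NLP_obs)
    nullstat <- sort.int(2 * rowSums(NLP_null), method = "quick")
    cnt <- N - count_lt(nullstat, stat)        # right tail
  } else {
    stat <- exp(-row_max(NLP_obs))             # min p = exp(-max(-log p))
    nullstat <- sort.int(exp(-row_max(NLP_null)), method = "quick")
    cnt <- count_le(nullstat, stat)            # left tail
  }
  list(stat = stat, p = pool_count(cnt, N, smooth))
}

row_max <- function(m) {
  out <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) out <- pmax(out, m[, k])
  out
}

#' Gene-level multiplicity adjustment
#'
#' Bonferroni or Benjamini-Hochberg step-up adjustment (via
#' [stats::p.adjust()]) with significance calls at `alpha`.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha Cutoff applied to the adjusted values.
#' @return Tibble with `p.value`, `q.value`, `significant`.
#' @export
adjust_pvalues <- function(pvalues, method = c("bh", "bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(tolower(method[1]), c("bh", "bonferroni"))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  q <- p.adjust(pvalues, method = if (method == "bh") "BH" else "bonferroni")
  tibble::tibble(p.value = as.numeric(pvalues), q.value = q,
                 significant = q < alpha)
}
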