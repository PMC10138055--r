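#' Score genes with a user-supplied association test
#'
#' Plugin protocol for external multivariate tests (e.g. MANOVA, aSPU,
#' TATES implementations): any callable mapping one gene's expression
#' vector plus the phenotype table and covariates to a single p-value can
#' be benchmarked alongside the built-in methods. The callable is invoked
#' once per gene as `fun(phenotypes, x, covariates)` and must return a
#' scalar p-value in `[0, 1]`.
#'
#' @param fun The test: `function(phenotypes, x, covariates) -> p-value`.
#' @param phenotypes A [typed_phenotypes()] table (passed through as-is).
#' @param expression Samples x genes matrix or data frame.
#' @param covariates Optional covariate data frame.
#' @param method_name Label used in the output.
#' @return Tibble with `gene`, `method`, `p.value`.
#' @examples
#' fx <- make_fixture(30, 9, K = 4, seed = 1)
#' # a naive minimum-p plugin built from per-phenotype correlation tests
#' naive <- function(phen, x, covar) {
#'   min(vapply(as.data.frame(phen), function(y) cor.test(x, y)$p.value,
#'              numeric(1)))
#' }
#' head(plugin_pvalues(naive, fx$phenotypes, fx$expression), 3)
#' @export
plugin_pvalues <- function(fun, phenotypes, expression, covariates = NULL,
                           method_name = "plugin") {
  X <- as_expression_matrix(expression)
  check_alignment(X, phenotypes, covariates)
  p <- vapply(seq_len(ncol(X)), function(j) {
    out <- fun(phenotypes, X[, j], covariates)
    stopifnot(is.numeric(out), length(out) == 1, out >= 0, out <= 1)
    out
  }, numeric(1))
  genes <- colnames(X)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(ncol(X)))
  tibble::tibble(gene = genes, method = method_name, p.value = p)
}
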