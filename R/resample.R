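#' Bootstrap the adaptive weight estimates
#'
#' Draws `L` bootstrap resamples of the samples (with replacement), reruns
#' the full estimation pipeline on each — observed p-values, a fresh
#' residual-permutation null of `B_boot` permutations, and the subset scan —
#' and records the binary weight estimate and the sign of the fitted
#' coefficient for every (gene, phenotype). Resamples in which a binomial /
#' survival-event phenotype collapses to a constant are redrawn (and
#' counted).
#'
#' @param expression,phenotypes,covariates As in [af_test()].
#' @param method `"afp"`, `"afz"` or both.
#' @param L Number of bootstrap resamples (>= 2).
#' @param B_boot Permutations per resample (smaller than the testing `B`;
#'   only the argmin/argmax weights are needed, not gene p-values).
#' @param seed Integer seed governing resampling and permutation draws.
#' @param stat_engine,eps As in [af_test()].
#' @return An `af_boot` list: `w` (named list per method of `L x p x K`
#'   binary arrays), `sign` (`L x p x K`), `indices` (n x L resample index
#'   matrix), `redraws` (count of discarded degenerate resamples).
#' @export
bootstrap_weights <- function(expression, phenotypes, covariates = NULL,
                              method = c("afp", "afz"), L = 50, B_boot = 50,
                              seed = 1, stat_engine = c("score", "glm"),
                              eps = 1e-300) {
  method <- match.arg(method, several.ok = TRUE)
  stat_engine <- match.arg(stat_engine)
  stopifnot(L >= 2)
  X <- as_expression_matrix(expression)
  stopifnot(inherits(phenotypes, "typed_phenotypes"))
  n <- nrow(X); p <- ncol(X)
  fams <- pheno_families(phenotypes)
  K <- length(fams)
  dn <- list(NULL, colnames(X), names(fams))
  w_arr <- lapply(stats::setNames(method, method),
                  function(m) array(NA_integer_, c(L, p, K), dimnames = dn))
  s_arr <- array(NA_real_, c(L, p, K), dimnames = dn)
  idx_mat <- matrix(NA_integer_, n, L)
  redraws <- 0L

  withr::with_seed(seed, {
    for (l in seq_len(L)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- resample_phenotypes(phenotypes, idx)
        if (!is.null(yb)) break
        redraws <- redraws + 1L
      }
      idx_mat[, l] <- idx
      Xb <- X[idx, , drop = FALSE]
      rownames(Xb) <- NULL
      Zb <- if (is.null(covariates)) NULL else {
        zz <- as.data.frame(covariates)[idx, , drop = FALSE]
        rownames(zz) <- NULL
        zz
      }
      obs <- observed_matrices(yb, Xb, Zb, engine = stat_engine, eps = eps)
      E <- residualize(Xb, Zb)
      nt <- null_tensor(yb, E, B = B_boot, eps = eps)
      fit <- af_test_from_matrices(obs, nt, methods = method,
                                   weights_only = TRUE)
      for (m in method) {
        w_arr[[m]][l, , ] <- fit[[paste0("w_", m)]]
      }
      s_arr[l, , ] <- obs$sign
    }
  })
  structure(list(w = w_arr, sign = s_arr, indices = idx_mat,
                 redraws = redraws, L = L, methods = method),
            class = "af_boot")
}

# NULL when the resample degenerates (constant binomial/poisson phenotype,
# all-censored survival)
resample_phenotypes <- function(phenotypes, idx) {
  fams <- pheno_families(phenotypes)
  vals <- as.data.frame(phenotypes)[idx, , drop = FALSE]
  rownames(vals) <- NULL
  for (nm in names(fams)) {
    fam <- fams[[nm]]
    col <- if (fam == "survival") vals[[paste0(nm, "_event")]] else vals[[nm]]
    if (fam %in% c("binomial", "survival") && length(unique(col)) < 2) {
      return(NULL)
    }
    if (fam != "survival" && stats::var(vals[[nm]]) == 0) return(NULL)
  }
  typed_phenotypes(vals, fams)
}

#' @export
print.af_boot <- function(x, ...) {
  d <- dim(x$sign)
  cat("<af_boot> L = ", d[1], " resamples, ", d[2], " genes, ", d[3],
      " phenotypes (", x$redraws, " redraws)\n", sep = "")
  invisible(x)
}

#' Bootstrap variability index of the weight estimates
#'
#' `4 * Var(w_hat)` per (gene, phenotype) with the biased (divide-by-L)
#' variance; for binary weights this equals `4 f (1 - f)` where `f` is the
#' bootstrap selection frequency, so the index lives in `[0, 1]`: 0 means
#' the phenotype is always (or never) selected for that gene, 1 means a
#' coin flip.
#'
#' @param boot An `af_boot` from [bootstrap_weights()], or a bare
#'   `L x p x K` binary array.
#' @param method Which method's weights when `boot` is an `af_boot`.
#' @return p x K matrix of indices in `[0, 1]`.
#' @export
variability_index <- function(boot, method = "afp") {
  W <- if (inherits(boot, "af_boot")) boot$w[[method]] else boot
  stopifnot(length(dim(W)) == 3, dim(W)[1] >= 2)
  L <- dim(W)[1]
  f <- apply(W, c(2, 3), mean)
  U <- 4 * apply(W, c(2, 3), function(w) mean((w - mean(w))^2))
  # identical to 4 f (1-f) for binary weights; keep the variance form
  dimnames(U) <- dimnames(f)
  U
}

#' Bootstrap co-membership matrix of signed weights
#'
#' The signed weight of a (gene, phenotype) is
#' \eqn{\hat v = \hat w \times \mathrm{sign}(\hat\theta)} (in -1/0/+1, a
#' zero or failed coefficient counting as its own level). Two genes
#' co-belong in one bootstrap when their signed weight vectors agree on all
#' K phenotypes; averaging the indicator over the `L` bootstraps gives a
#' similarity in `[0, 1]` used for module clustering.
#'
#' @param boot An `af_boot`.
#' @param genes Optional character or integer subset (typically the
#'   significant genes) — the matrix is `length(genes)` squared.
#' @param method `"afp"` or `"afz"`.
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
co_membership <- function(boot, genes = NULL, method = "afp") {
  stopifnot(inherits(boot, "af_boot"))
  W <- boot$w[[method]]
  Sg <- boot$sign
  if (is.null(genes)) genes <- seq_len(dim(W)[2])
  if (is.character(genes)) genes <- match(genes, dimnames(W)[[2]])
  stopifnot(length(genes) >= 1, !anyNA(genes))
  L <- dim(W)[1]; K <- dim(W)[3]
  ng <- length(genes)
  V <- matrix(0, ng, ng)
  for (l in seq_len(L)) {
    wl <- matrix(W[l, genes, ], ng, K)
    sl <- matrix(Sg[l, genes, ], ng, K)
    v <- wl * sign(sl)
    key <- apply(v + 1, 1, paste, collapse = ",")  # levels -1/0/1 -> 0/1/2
    V <- V + outer(key, key, "==")
  }
  V <- V / L
  gene_ids <- dimnames(W)[[2]][genes]
  if (!is.null(gene_ids)) dimnames(V) <- list(gene_ids, gene_ids)
  V
}
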