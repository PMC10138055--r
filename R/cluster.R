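#' Tight consensus clustering of genes by co-membership
#'
#' Clusters significant genes into compact modules of shared phenotype
#' association pattern, discarding "scattered" genes that fit no module.
#' The procedure is a resampled k-means consensus on the co-membership
#' similarity: repeatedly subsample genes, run k-means on the rows of `V`
#' (scanning `k_min:k_max` and keeping the most stable k), accumulate
#' co-cluster frequencies, extract the largest candidate set whose mean
#' internal consensus and co-membership reach `alpha_tight`, remove it, and
#' repeat until no qualifying set of at least `min_size` genes remains.
#' A simpler deterministic fallback (`method = "hclust"`) cuts an
#' average-linkage tree on `1 - V` at height `1 - alpha_tight`.
#'
#' @param V Co-membership similarity matrix (symmetric, unit diagonal,
#'   entries in `[0, 1]`; see [co_membership()]).
#' @param k_min,k_max Range of cluster counts scanned inside each
#'   consensus round.
#' @param alpha_tight Minimum average within-module co-membership.
#' @param min_size Minimum module size; smaller candidate sets are left
#'   scattered.
#' @param n_resample,subsample_frac Consensus knobs: number of k-means
#'   subsampling rounds and the gene fraction drawn per round.
#' @param method `"consensus"` (default) or `"hclust"`.
#' @param seed Integer seed (consensus resampling and k-means starts).
#' @return An `af_modules` object: tibble `assignment` (`gene`, `module`;
#'   label `"scattered"` for unclustered genes) plus `modules` (list of
#'   gene-ID vectors) and the call parameters.
#' @export
tight_cluster <- function(V, k_min = 2, k_max = 10, alpha_tight = 0.7,
                          min_size = 20, n_resample = 20,
                          subsample_frac = 0.7,
                          method = c("consensus", "hclust"), seed = 1) {
  method <- match.arg(method)
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (max(abs(V - t(V))) > 1e-8 || any(V < -1e-8) || any(V > 1 + 1e-8)) {
    stop("V must be a symmetric similarity with entries in [0, 1]",
         call. = FALSE)
  }
  if (is.null(rownames(V))) {
    dimnames(V) <- list(paste0("gene_", seq_len(nrow(V))),
                        paste0("gene_", seq_len(nrow(V))))
  }
  genes <- rownames(V)
  assignment <- stats::setNames(rep("scattered", nrow(V)), genes)

  modules <- withr::with_seed(seed, {
    if (method == "hclust") {
      tight_modules_hclust(V, alpha_tight, min_size)
    } else {
      tight_modules_consensus(V, k_min, k_max, alpha_tight, min_size,
                              n_resample, subsample_frac)
    }
  })
  for (i in seq_along(modules)) {
    assignment[modules[[i]]] <- as.character(i)
  }
  new_af_modules(assignment, genes, alpha_tight = alpha_tight,
                 min_size = min_size)
}

new_af_modules <- function(assignment, genes, ...) {
  mods <- sort(unique(unname(assignment[assignment != "scattered"])))
  nm <- if (length(mods)) paste0("module_", mods) else character(0)
  structure(list(
    assignment = tibble::tibble(gene = genes,
                                module = unname(assignment[genes])),
    modules = lapply(stats::setNames(as.list(mods), nm),
                     function(m) genes[assignment[genes] == m]),
    params = list(...)),
    class = "af_modules")
}

#' @export
print.af_modules <- function(x, ...) {
  sizes <- vapply(x$modules, length, integer(1))
  cat("<af_modules> ", length(x$modules), " modules (sizes: ",
      paste(sizes, collapse = ", "), "), ",
      sum(x$assignment$module == "scattered"), " scattered genes\n", sep = "")
  invisible(x)
}

# cut an average-linkage tree on 1 - V; keep clusters that are big and tight
tight_modules_hclust <- function(V, alpha_tight, min_size) {
  genes <- rownames(V)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(V)))
  if (nrow(V) < 2) return(list())
  hc <- stats::hclust(stats::as.dist(1 - V), method = "average")
  labs <- stats::cutree(hc, h = 1 - alpha_tight)
  keep <- list()
  for (m in unique(labs)) {
    members <- genes[labs == m]
    if (length(members) >= max(2, min_size) &&
        mean_offdiag(V[members, members, drop = FALSE]) >= alpha_tight) {
      keep[[length(keep) + 1]] <- members
    }
  }
  keep[order(-vapply(keep, length, integer(1)))]
}

mean_offdiag <- function(M) {
  n <- nrow(M)
  if (n < 2) return(1)
  (sum(M) - sum(diag(M))) / (n * (n - 1))
}

# resampled k-means consensus; peel off one tight set per outer round
tight_modules_consensus <- function(V, k_min, k_max, alpha_tight, min_size,
                                    n_resample, subsample_frac) {
  genes <- rownames(V)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(V)))
  remaining <- genes
  found <- list()
  repeat {
    if (length(remaining) < max(2, min_size)) break
    Vr <- V[remaining, remaining, drop = FALSE]
    cons <- consensus_frequencies(Vr, k_min, k_max, n_resample,
                                  subsample_frac)
    cand <- candidate_set(cons, Vr, alpha_tight, min_size)
    if (is.null(cand)) break
    found[[length(found) + 1]] <- remaining[cand]
    remaining <- remaining[-cand]
  }
  found
}

consensus_frequencies <- function(V, k_min, k_max, n_resample,
                                  subsample_frac) {
  n <- nrow(V)
  hits <- matrix(0, n, n)
  tries <- matrix(0, n, n)
  n_sub <- max(2, ceiling(subsample_frac * n))
  k_lo <- max(2, k_min)
  k_hi <- max(k_lo, min(k_max, n_sub - 1))
  for (r in seq_len(n_resample)) {
    sub <- sort(sample.int(n, n_sub))
    k_r <- k_lo + (r - 1) %% (k_hi - k_lo + 1)   # cycle through the k range
    k_r <- min(k_r, nrow(unique(V[sub, , drop = FALSE])))
    cl <- if (k_r < 2) {
      rep(1L, length(sub))                       # one pattern: one cluster
    } else {
      tryCatch(
        stats::kmeans(V[sub, , drop = FALSE], centers = k_r, nstart = 2,
                      iter.max = 30)$cluster,
        error = function(e) NULL)
    }
    if (is.null(cl)) next                        # degenerate round: skip
    same <- outer(cl, cl, "==")
    tries[sub, sub] <- tries[sub, sub] + 1
    hits[sub, sub] <- hits[sub, sub] + same
  }
  out <- ifelse(tries > 0, hits / pmax(tries, 1), 0)
  diag(out) <- 1
  out
}

# largest average-linkage cluster of the consensus matrix that is tight both
# in consensus frequency and in raw co-membership
candidate_set <- function(cons, V, alpha_tight, min_size) {
  n <- nrow(cons)
  if (n < 2) return(NULL)
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  for (h in c(1 - alpha_tight, 0.5, 0.25)) {
    labs <- stats::cutree(hc, h = h)
    sets <- split(seq_len(n), labs)
    sets <- Filter(function(s) length(s) >= max(2, min_size), sets)
    if (!length(sets)) next
    tight <- Filter(function(s) {
      mean_offdiag(cons[s, s, drop = FALSE]) >= alpha_tight &&
        mean_offdiag(V[s, s, drop = FALSE]) >= alpha_tight
    }, sets)
    if (length(tight)) {
      return(tight[[which.max(vapply(tight, length, integer(1)))]])
    }
  }
  NULL
}

#' Merge modules with high between-module co-membership
#'
#' Modules whose mean between-module co-membership exceeds
#' `merge_threshold` are merged (highest pair first, recomputing after each
#' merge), mirroring the manual step of combining adjacent tight clusters
#' into one module.
#'
#' @param assignment An `af_modules` object.
#' @param V The co-membership matrix the assignment was built from.
#' @param merge_threshold Mean between-module co-membership above which two
#'   modules merge.
#' @return An `af_modules` object with merged (renumbered) modules.
#' @export
merge_similar_modules <- function(assignment, V, merge_threshold = 0.5) {
  stopifnot(inherits(assignment, "af_modules"))
  mods <- assignment$modules
  if (length(mods) < 2) return(assignment)
  repeat {
    if (length(mods) < 2) break
    nm <- length(mods)
    best <- NULL; best_val <- merge_threshold
    for (i in seq_len(nm - 1)) {
      for (j in (i + 1):nm) {
        val <- mean(V[mods[[i]], mods[[j]]])
        if (val > best_val) { best <- c(i, j); best_val <- val }
      }
    }
    if (is.null(best)) break
    mods[[best[1]]] <- c(mods[[best[1]]], mods[[best[2]]])
    mods[[best[2]]] <- NULL
  }
  genes <- assignment$assignment$gene
  lab <- stats::setNames(rep("scattered", length(genes)), genes)
  ord <- order(-vapply(mods, length, integer(1)))
  for (i in seq_along(ord)) lab[mods[[ord[i]]]] <- as.character(i)
  new_af_modules(lab, genes, merged_at = merge_threshold)
}

#' Per-module summary of weights, signs and evidence
#'
#' For each module: the consensus signed-weight pattern (per-phenotype
#' majority of each member gene's modal signed weight over the bootstraps),
#' the mean -log10 p-value per phenotype, and the member count — the data
#' behind a module-by-phenotype association heatmap. Scattered genes are
#' omitted.
#'
#' @param assignment An `af_modules` object.
#' @param boot An `af_boot` from [bootstrap_weights()].
#' @param pvalues p x K observed p-value matrix (rows named by gene).
#' @param method `"afp"` or `"afz"`.
#' @return Tibble with one row per (module, phenotype): `module`, `n_genes`,
#'   `phenotype`, `consensus` (in -1/0/1), `mean_neglog10_p`.
#' @export
module_summary <- function(assignment, boot, pvalues, method = "afp") {
  stopifnot(inherits(assignment, "af_modules"), inherits(boot, "af_boot"))
  if (!length(assignment$modules)) {
    stop("assignment has no modules", call. = FALSE)
  }
  W <- boot$w[[method]]
  Sg <- boot$sign
  gene_ids <- dimnames(W)[[2]]
  pheno <- dimnames(W)[[3]]
  K <- dim(W)[3]
  purrr::map_dfr(seq_along(assignment$modules), function(m) {
    members <- assignment$modules[[m]]
    gi <- match(members, gene_ids)
    cons <- vapply(seq_len(K), function(k) {
      modal <- vapply(gi, function(j) {
        v <- W[, j, k] * sign(Sg[, j, k])
        as.integer(names(which.max(table(factor(v, levels = -1:1)))))
      }, integer(1))
      as.integer(names(which.max(table(factor(modal, levels = -1:1)))))
    }, integer(1))
    mlp <- colMeans(-log10(pvalues[members, , drop = FALSE]))
    tibble::tibble(module = names(assignment$modules)[m],
                   n_genes = length(members), phenotype = pheno,
                   consensus = cons, mean_neglog10_p = unname(mlp))
  })
}

#' Heatmap of a co-membership matrix with module annotation
#'
#' @param V Co-membership matrix.
#' @param assignment Optional `af_modules`; genes are ordered by module.
#' @return A ggplot object.
#' @export
plot_co_membership <- function(V, assignment = NULL) {
  genes <- rownames(V) %||% paste0("gene_", seq_len(nrow(V)))
  ord <- genes
  if (!is.null(assignment)) {
    df <- assignment$assignment
    ord <- df$gene[order(df$module != "scattered", df$module,
                         decreasing = TRUE)]
    ord <- intersect(ord, genes)
  }
  long <- tibble::tibble(
    g1 = factor(rep(ord, times = length(ord)), levels = ord),
    g2 = factor(rep(ord, each = length(ord)), levels = ord),
    v = as.vector(V[ord, ord]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$g1, y = .data$g2,
                                     fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "co-membership") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
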