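#' Weighted sum of -log p-values
#'
#' The building block of the adaptive statistics:
#' \eqn{u(w) = -\sum_k w_k \log p_k} with binary weights; twice this value
#' at the all-ones weight is the classical Fisher combination statistic.
#'
#' @param pvec Length-K p-values, each in `(0, 1]`.
#' @param w Length-K binary weight vector (not all zero).
#' @return Non-negative scalar (natural log).
#' @examples
#' weighted_stat(c(exp(-1), 1, 1), c(1, 0, 0))  # 1
#' @export
weighted_stat <- function(pvec, w) {
  check_pvec(pvec)
  w <- check_weight(w, length(pvec))
  u <- 0
  for (k in which(w == 1)) u <- u + (-log(pvec[k]))
  u
}

check_pvec <- function(pvec) {
  if (!is.numeric(pvec) || any(!is.finite(pvec)) ||
      any(pvec <= 0) || any(pvec > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  invisible(pvec)
}

check_weight <- function(w, K) {
  if (length(w) != K || !all(w %in% c(0, 1)) || sum(w) == 0) {
    stop("w must be a binary vector of length ", K, ", not all zero",
         call. = FALSE)
  }
  as.integer(w)
}

# count of sorted values strictly below / at-or-below x (vectorized over x)
count_lt <- function(sorted, x) findInterval(x, sorted, left.open = TRUE)
count_le <- function(sorted, x) findInterval(x, sorted)

pool_count <- function(cnt, N, smooth = FALSE) {
  if (smooth) (cnt + 1) / (N + 1) else cnt / N
}

# subset index s <-> weight vector: bit k-1 of s is phenotype k
subset_weights <- function(s, K) as.integer(bitwAnd(s, 2L^(seq_len(K) - 1L)) > 0)
weights_subset <- function(w) sum(as.integer(w) * 2L^(seq_along(w) - 1L))

#' Pooled null table for the subset scan
#'
#' Expands the pooled permutation null (all `B * p` permuted p-value rows)
#' into per-subset weighted statistics for every non-empty subset of the K
#' phenotypes, with sorted columns and pooled moments. This is the reference
#' (pure R) machinery behind [afp_gene()] / [afz_gene()]; it materializes a
#' `(B*p) x (2^K - 1)` matrix and is meant for moderate K and pooled sizes
#' ([af_test()] uses a compiled scan that never materializes it).
#'
#' @param nulls An `af_null_tensor` from [null_tensor()], or a numeric
#'   matrix of null p-values with K columns (rows are pooled draws).
#' @param eps P-value floor before the log transform.
#' @return An `af_null_table`: list with `u` (N x S raw statistics), `sorted`
#'   (N x S), `mean`, `sd` (biased, divide-by-N), `N`, `K`.
#' @export
null_stat_table <- function(nulls, eps = 1e-300) {
  NLP <- null_nlp_matrix(nulls, eps)
  N <- nrow(NLP); K <- ncol(NLP)
  if (K > 14) stop("K too large to materialize the subset table", call. = FALSE)
  S <- 2L^K - 1L
  U <- matrix(0, N, S)
  for (s in seq_len(S)) {
    hb <- 2L^(floor(log2(s)))               # highest set bit
    k <- as.integer(log2(hb)) + 1L
    rest <- s - hb
    U[, s] <- (if (rest > 0L) U[, rest] else 0) + NLP[, k]
  }
  mu <- colMeans(U)
  sdv <- sqrt(colMeans(sweep(U, 2, mu)^2))  # biased (divide-by-N), two-pass
  if (any(!(sdv > 0))) {
    stop("degenerate null subset (sd = 0): subset ",
         paste(which(!(sdv > 0)), collapse = ", "), call. = FALSE)
  }
  structure(list(u = U, sorted = apply(U, 2, sort.int, method = "quick"),
                 mean = mu, sd = sdv, N = N, K = K),
            class = "af_null_table")
}

null_nlp_matrix <- function(nulls, eps = 1e-300) {
  P <- if (inherits(nulls, "af_null_tensor")) {
    d <- dim(nulls$p)
    matrix(nulls$p, d[1] * d[2], d[3])
  } else {
    as.matrix(nulls)
  }
  if (nrow(P) == 0) stop("empty null table", call. = FALSE)
  -log(clip_p(P, eps))
}

#' Pooled permutation p-value of a weighted statistic
#'
#' Right-tail empirical exceedance of `u_obs` over all pooled null draws of
#' the same subset: `#\{u_null >= u_obs\} / N`. Can be exactly 0 under the
#' literal count; `smooth = TRUE` reports `(c + 1) / (N + 1)` instead.
#'
#' @param u_obs Observed weighted statistic.
#' @param w Binary weight vector selecting the subset.
#' @param nulls An `af_null_table` (see [null_stat_table()]).
#' @param smooth Use the add-one smoothed count.
#' @return Scalar pooled p-value.
#' @export
pooled_pvalue <- function(u_obs, w, nulls, smooth = FALSE) {
  stopifnot(inherits(nulls, "af_null_table"))
  w <- check_weight(w, nulls$K)
  s <- weights_subset(w)
  cnt <- nulls$N - count_lt(nulls$sorted[, s], u_obs)
  pool_count(cnt, nulls$N, smooth)
}

# tie chain shared by the reference implementations (pooled counts are
# discrete, ties are common under strong signal):
# AFp: smaller pooled count, then larger mean-centered statistic
# u - E(u(w)) ("centered evidence": a phenotype stays in the subset only
# when its -log p exceeds its null expectation), then smaller cardinality,
# then smaller subset index (implicit in the scan order).
# AFz: larger z, then larger u, then smaller cardinality, then index.
afp_better <- function(cnt, cu, card, b) {
  cnt < b$cnt || (cnt == b$cnt && (cu > b$cu || (cu == b$cu && card < b$card)))
}
afz_better <- function(z, u, card, b) {
  z > b$z || (z == b$z && (u > b$u || (u == b$u && card < b$card)))
}

obs_subset_sums <- function(pvec, K) {
  nlp <- -log(pvec)
  S <- 2L^K - 1L
  u <- numeric(S)
  for (s in seq_len(S)) {
    hb <- 2L^(floor(log2(s)))
    k <- as.integer(log2(hb)) + 1L
    rest <- s - hb
    u[s] <- (if (rest > 0L) u[rest] else 0) + nlp[k]
  }
  u
}

#' AFp statistic and weight estimate for one gene (reference implementation)
#'
#' Exhaustively minimizes the pooled permutation p-value of the weighted
#' statistic over all non-empty phenotype subsets. The minimizing subset is
#' the phenotype-selection estimate. Pooled p-values are discrete (resolution
#' `1/N`), so under strong signal many subsets tie at the minimum; ties are
#' resolved by the largest mean-centered statistic `u(w) - E(u(w))`
#' ("centered evidence": a phenotype stays selected only when its `-log p`
#' exceeds its pooled-null expectation), then the smallest cardinality, then
#' the smallest subset index.
#'
#' @inheritParams pooled_pvalue
#' @param pvec Length-K observed p-values in `(0, 1]`.
#' @return List with `T` (minimal pooled p-value), `count` (its integer
#'   numerator), `w` (binary weight vector), `u` (weighted statistic at the
#'   optimum).
#' @seealso [af_test()] for the genome-wide compiled path.
#' @export
afp_gene <- function(pvec, nulls, smooth = FALSE) {
  stopifnot(inherits(nulls, "af_null_table"))
  check_pvec(pvec)
  K <- nulls$K
  stopifnot(length(pvec) == K)
  u_all <- obs_subset_sums(pvec, K)
  best <- list(cnt = Inf, cu = -Inf, card = K + 1, s = 0L, u = -1)
  for (s in seq_len(2L^K - 1L)) {
    cnt <- nulls$N - count_lt(nulls$sorted[, s], u_all[s])
    cu <- u_all[s] - nulls$mean[s]
    card <- sum(subset_weights(s, K))
    if (afp_better(cnt, cu, card, best)) {
      best <- list(cnt = cnt, cu = cu, card = card, s = s, u = u_all[s])
    }
  }
  list(T = pool_count(best$cnt, nulls$N, smooth), count = best$cnt,
       w = subset_weights(best$s, K), u = best$u)
}

#' AFz statistic and weight estimate for one gene (reference implementation)
#'
#' Exhaustively maximizes the z-standardized weighted statistic
#' \eqn{(u(w) - \hat E(u(w))) / \hat{sd}(u(w))} over all non-empty subsets,
#' with moments estimated from the pooled permutation null.
#'
#' @inheritParams afp_gene
#' @return List with `T` (maximal standardized statistic), `w`, `u`.
#' @export
afz_gene <- function(pvec, nulls) {
  stopifnot(inherits(nulls, "af_null_table"))
  check_pvec(pvec)
  K <- nulls$K
  stopifnot(length(pvec) == K)
  u_all <- obs_subset_sums(pvec, K)
  best <- list(z = -Inf, u = -1, card = K + 1, s = 0L)
  for (s in seq_len(2L^K - 1L)) {
    z <- (u_all[s] - nulls$mean[s]) / nulls$sd[s]
    card <- sum(subset_weights(s, K))
    if (afz_better(z, u_all[s], card, best)) {
      best <- list(z = z, u = u_all[s], card = card, s = s)
    }
  }
  list(T = best$z, w = subset_weights(best$s, K), u = best$u)
}

#' Null distribution of the adaptive statistics (reference implementation)
#'
#' Applies the AFp / AFz optimization to every pooled null draw, re-using
#' the same pooled counts (self-inclusive: each draw counts itself, so AFp
#' null statistics are always at least `1/N`).
#'
#' @inheritParams pooled_pvalue
#' @param method `"afp"` or `"afz"`.
#' @return Length-N numeric vector of null statistics (pooled p-values for
#'   AFp, standardized maxima for AFz).
#' @export
null_statistics <- function(nulls, method = c("afp", "afz"), smooth = FALSE) {
  stopifnot(inherits(nulls, "af_null_table"))
  method <- match.arg(method)
  N <- nulls$N; S <- ncol(nulls$u)
  if (method == "afp") {
    best <- rep(Inf, N)
    for (s in seq_len(S)) {
      cnt <- N - (rank(nulls$u[, s], ties.method = "min") - 1L)
      best <- pmin(best, cnt)
    }
    pool_count(best, N, smooth)
  } else {
    best <- rep(-Inf, N)
    for (s in seq_len(S)) {
      best <- pmax(best, (nulls$u[, s] - nulls$mean[s]) / nulls$sd[s])
    }
    best
  }
}

#' Gene-level permutation p-values from observed and null statistics
#'
#' Pooled exceedance of the adaptive statistic: left tail for AFp (small
#' pooled p-values are extreme), right tail for AFz.
#'
#' @param T_obs Observed per-gene statistics.
#' @param T_null Pooled null statistics (see [null_statistics()]).
#' @param method `"afp"` or `"afz"`.
#' @param smooth Add-one smoothing of the counts.
#' @return Per-gene p-values in `[0, 1]`.
#' @export
gene_pvalues <- function(T_obs, T_null, method = c("afp", "afz"),
                         smooth = FALSE) {
  method <- match.arg(method)
  srt <- sort(T_null)
  N <- length(T_null)
  cnt <- if (method == "afp") {
    count_le(srt, T_obs)
  } else {
    N - count_lt(srt, T_obs)
  }
  pool_count(cnt, N, smooth)
}
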