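# Naive, independently-written reference computations used as oracles.
# Everything here uses plain loops and direct counting, no shared code with
# the package internals beyond exported constructors.

# subset s (1..2^K-1) -> binary weight vector, bit k-1 <-> phenotype k
oracle_weights <- function(s, K) as.integer(bitwAnd(s, 2^(0:(K - 1))) > 0)

# left-to-right sum over ascending phenotype index (the documented order)
oracle_u <- function(nlp_row, w) {
  u <- 0
  for (k in seq_along(w)) if (w[k] == 1) u <- u + nlp_row[k]
  u
}

# full double-loop AFp/AFz scan on p-value matrices (rows = draws)
oracle_scan <- function(p_null, p_obs) {
  K <- ncol(p_null); N <- nrow(p_null); G <- nrow(p_obs); S <- 2^K - 1
  nl <- -log(p_null); ob <- -log(p_obs)
  un <- matrix(0, N, S); uo <- matrix(0, G, S)
  for (s in 1:S) {
    w <- oracle_weights(s, K)
    for (i in 1:N) un[i, s] <- oracle_u(nl[i, ], w)
    for (g in 1:G) uo[g, s] <- oracle_u(ob[g, ], w)
  }
  cnt_obs <- matrix(0L, G, S); cnt_null <- matrix(0L, N, S)
  zn <- matrix(NA_real_, N, S); zo <- matrix(NA_real_, G, S)
  mns <- numeric(S); sds <- numeric(S)
  for (s in 1:S) {
    for (g in 1:G) cnt_obs[g, s] <- sum(un[, s] >= uo[g, s])
    for (i in 1:N) cnt_null[i, s] <- sum(un[, s] >= un[i, s])
    mns[s] <- mean(un[, s])
    sds[s] <- sqrt(mean((un[, s] - mns[s])^2))
    if (sds[s] > 0) {
      zn[, s] <- (un[, s] - mns[s]) / sds[s]
      zo[, s] <- (uo[, s] - mns[s]) / sds[s]
    }
  }
  card <- vapply(1:S, function(s) sum(oracle_weights(s, K)), numeric(1))
  pick_afp <- function(g) {
    best <- 1
    for (s in 2:S) {
      cu <- uo[g, s] - mns[s]; bcu <- uo[g, best] - mns[best]
      if (cnt_obs[g, s] < cnt_obs[g, best] ||
          (cnt_obs[g, s] == cnt_obs[g, best] &&
           (cu > bcu || (cu == bcu && card[s] < card[best])))) best <- s
    }
    best
  }
  pick_afz <- function(g) {
    best <- 1
    for (s in 2:S) {
      if (isTRUE(zo[g, s] > zo[g, best]) ||
          (isTRUE(zo[g, s] == zo[g, best]) &&
           (uo[g, s] > uo[g, best] ||
            (uo[g, s] == uo[g, best] && card[s] < card[best])))) best <- s
    }
    best
  }
  afp_s <- vapply(1:G, pick_afp, numeric(1))
  afz_s <- vapply(1:G, pick_afz, numeric(1))
  list(afp_count = cnt_obs[cbind(1:G, afp_s)], afp_subset = afp_s,
       afz_stat = zo[cbind(1:G, afz_s)], afz_subset = afz_s,
       null_count_min = apply(cnt_null, 1, min),
       null_z_max = apply(zn, 1, max),
       u_null = un, u_obs = uo, mean = mns, sd = sds)
}

# deterministic small p-value matrices
rand_p_matrix <- function(n, K, power = 1) matrix(runif(n * K)^power, n, K)
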