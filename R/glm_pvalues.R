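#' Wald association test between one phenotype and one gene
#'
#' Fits the generalized linear model `g(E(y)) = x*theta + Z*alpha` for the
#' declared family (Cox proportional hazards for survival phenotypes, with
#' partial-likelihood Wald) and returns the Wald test of `theta`. On
#' non-convergence or separation the Rao score test of adding `x` to the
#' covariate-only model is used as a fallback; if that also fails the pair is
#' flagged and reported as `p = 1`, `theta = 0` rather than aborting a
#' genome-wide run.
#'
#' @param y Phenotype vector (or `survival::Surv` object).
#' @param x Length-n numeric predictor with nonzero variance.
#' @param family `"gaussian"`, `"binomial"`, `"poisson"` or `"survival"`.
#' @param Z Optional covariate data frame / matrix (n x M).
#' @param eps P-value floor: p-values below `eps` are clipped so that
#'   \eqn{-\log p} stays finite downstream.
#' @return List with `theta` (coefficient of `x`), `p` (two-sided Wald
#'   p-value in `(0, 1]`), and `flag` (`TRUE` when the fit failed and the
#'   fallback value was returned).
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.5 * x + rnorm(50)
#' fit_association(y, x, "gaussian")$p
#' @export
fit_association <- function(y, x, family, Z = NULL, eps = 1e-300) {
  n <- length(x)
  M <- if (is.null(Z)) 0L else ncol(as.matrix(Z))
  if (n < M + 3) stop("need at least M + 3 samples", call. = FALSE)
  if (var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  if (family == "survival") {
    return(fit_association_cox(y, x, Z, eps))
  }
  df <- data.frame(.y = y, .x = x)
  if (!is.null(Z)) df <- cbind(df, as.data.frame(Z))
  out <- withCallingHandlers(
    tryCatch({
      fit <- glm(.y ~ ., data = df, family = family)
      sm <- summary(fit)$coefficients
      list(theta = unname(coef(fit)[".x"]),
           p = clip_p(sm[".x", 4], eps), flag = FALSE,
           converged = isTRUE(fit$converged))
    }, error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!is.null(out) && isTRUE(out$converged) && is.finite(out$p)) {
    out$converged <- NULL
    return(out)
  }
  # score-test fallback: Rao test of adding x to the covariate-only model
  out <- tryCatch({
    f0 <- glm(.y ~ . - .x, data = df, family = family)
    f1 <- glm(.y ~ ., data = df, family = family)
    an <- stats::anova(f0, f1, test = "Rao")
    list(theta = unname(coef(f1)[".x"]),
         p = clip_p(an[["Pr(>Chi)"]][2], eps), flag = FALSE)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(out) && is.finite(out$p)) return(out)
  list(theta = 0, p = 1, flag = TRUE)
}

fit_association_cox <- function(y, x, Z, eps) {
  stopifnot(inherits(y, "Surv"))
  df <- data.frame(.x = x)
  if (!is.null(Z)) df <- cbind(df, as.data.frame(Z))
  out <- tryCatch({
    fit <- survival::coxph(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    list(theta = unname(coef(fit)[".x"]),
         p = clip_p(sm[".x", "Pr(>|z|)"], eps), flag = FALSE)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(out) && is.finite(out$p)) return(out)
  list(theta = 0, p = 1, flag = TRUE)
}

clip_p <- function(p, eps = 1e-300) pmin(pmax(p, eps), 1)

#' Observed p-value and sign matrices for all gene-phenotype pairs
#'
#' Applies the per-pair association test to every (gene, phenotype) pair.
#' Two engines are available: `"glm"` calls [fit_association()] pair by pair
#' (Wald tests with score fallback), while `"score"` computes the same
#' quantities in closed form across all genes at once — the exact OLS t-test
#' for gaussian phenotypes (identical to the GLM Wald test) and the
#' efficient score test for poisson/binomial phenotypes. Survival phenotypes
#' always go through `coxph`.
#'
#' @param phenotypes A [typed_phenotypes()] table.
#' @param expression n x p numeric matrix, samples in rows. Row names, when
#'   present, must match across `phenotypes` attributes and `covariates`.
#' @param covariates Optional n x M data frame / matrix.
#' @param engine `"score"` (vectorized; default) or `"glm"`.
#' @param eps P-value floor (see [fit_association()]).
#' @return An `af_obs` list: `p` and `sign` (p x K matrices), `flags`
#'   (logical p x K), `families`.
#' @export
observed_matrices <- function(phenotypes, expression, covariates = NULL,
                              engine = c("score", "glm"), eps = 1e-300) {
  engine <- match.arg(engine)
  X <- as_expression_matrix(expression)
  check_alignment(X, phenotypes, covariates)
  fams <- pheno_families(phenotypes)
  K <- length(fams); p <- ncol(X)
  P <- matrix(NA_real_, p, K, dimnames = list(colnames(X), names(fams)))
  S <- matrix(0, p, K, dimnames = dimnames(P))
  FL <- matrix(FALSE, p, K, dimnames = dimnames(P))
  Z <- normalize_covariates(covariates)

  for (k in seq_len(K)) {
    nm <- names(fams)[k]
    col <- pheno_column(phenotypes, nm)
    if (engine == "glm" || col$family == "survival") {
      for (j in seq_len(p)) {
        r <- fit_association(col$y, X[, j], col$family, Z, eps)
        P[j, k] <- r$p; S[j, k] <- sign(r$theta); FL[j, k] <- r$flag
      }
    } else {
      r <- score_scan_column(col$y, col$family, X, Z, eps)
      P[, k] <- r$p; S[, k] <- r$sign; FL[, k] <- r$flag
    }
  }
  structure(list(p = P, sign = S, flags = FL, families = fams),
            class = "af_obs")
}

#' @export
print.af_obs <- function(x, ...) {
  cat("<af_obs> ", nrow(x$p), " genes x ", ncol(x$p), " phenotypes; ",
      sum(x$flags), " flagged fits\n", sep = "")
  invisible(x)
}

# closed-form association scan of all genes against one phenotype
score_scan_column <- function(y, family, X, Z, eps) {
  n <- nrow(X)
  D <- cbind(`(Intercept)` = rep(1, n), as_covariate_matrix(Z, n))
  if (family == "gaussian") {
    qrD <- qr(D)
    Xr <- qr.resid(qrD, X)
    yr <- qr.resid(qrD, y)
    df <- n - qrD$rank - 1L
    ss_x <- colSums(Xr^2); ss_y <- sum(yr^2)
    bad <- ss_x <= 0 | ss_y <= 0
    r <- crossprod(Xr, yr)[, 1] / sqrt(pmax(ss_x, .Machine$double.xmin) * ss_y)
    r <- pmin(pmax(r, -1), 1)
    tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
    p <- 2 * pt(-abs(tval), df)
  } else {
    fit0 <- glm(y ~ D - 1, family = family)
    mu <- stats::fitted(fit0)
    w <- switch(family, poisson = mu, binomial = mu * (1 - mu))
    A <- crossprod(D, D * w)
    Xt <- X - D %*% solve(A, crossprod(D, X * w))
    U <- crossprod(Xt, y - mu)[, 1]
    V <- colSums(Xt^2 * w)
    bad <- !is.finite(V) | V <= 0
    z <- U / sqrt(pmax(V, .Machine$double.xmin))
    p <- 2 * pnorm(-abs(z))
    r <- z
  }
  p <- clip_p(p, eps)
  p[bad] <- 1; r[bad] <- 0
  list(p = p, sign = sign(r), flag = bad)
}

#' Residualize expression on covariates
#'
#' Least-squares residuals of each gene on an intercept plus the covariates;
#' with no covariates this is column centering. Collinear covariate columns
#' are dropped with a warning. These residuals are what gets permuted to
#' build the null: shuffling them breaks every gene-phenotype association
#' while the covariate-phenotype and covariate-expression associations in
#' the observed fits are left intact.
#'
#' @param expression n x p matrix (samples in rows).
#' @param covariates Optional n x M data frame / matrix.
#' @return n x p residual matrix (column means ~ 0).
#' @export
residualize <- function(expression, covariates = NULL) {
  X <- as_expression_matrix(expression)
  n <- nrow(X)
  Z <- as_covariate_matrix(normalize_covariates(covariates), n)
  if (!is.null(Z) && n <= ncol(Z)) stop("need n > M samples", call. = FALSE)
  D <- cbind(`(Intercept)` = rep(1, n), Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("dropping ", ncol(D) - qrD$rank,
            " collinear covariate column(s)", call. = FALSE)
  }
  E <- qr.resid(qrD, X)
  dimnames(E) <- dimnames(X)
  E
}

#' Residual-permutation null p-value tensor
#'
#' For each of `B` permutations one shuffling of the sample indices is drawn
#' and applied to every gene's residual vector (the same permutation for all
#' genes, so gene-gene correlation is preserved within a permutation). Each
#' phenotype is then regressed on the permuted residuals with intercept only
#' and the two-sided p-value of the slope recorded, giving a `B x p x K`
#' tensor whose pooled entries approximate the null with resolution
#' `1 / (B * p)`. Setting `with_covariates = TRUE` adds the covariates back
#' into the null-side regressions (a variant; off by default).
#'
#' @param phenotypes A [typed_phenotypes()] table.
#' @param residuals n x p residual matrix from [residualize()].
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @param covariates Covariates, only used when `with_covariates = TRUE`.
#' @param with_covariates Include covariates in the null regressions.
#' @param perms Optional n x B integer matrix of pre-drawn permutations
#'   (test hook; overrides `seed`).
#' @param eps P-value floor.
#' @return An `af_null_tensor`: list with `p` (B x p x K array), `perms`
#'   (n x B), `B`, and a `failed` count of degenerate fits.
#' @export
null_tensor <- function(phenotypes, residuals, B = 100, seed = NULL,
                        covariates = NULL, with_covariates = FALSE,
                        perms = NULL, eps = 1e-300) {
  E <- as.matrix(residuals)
  n <- nrow(E); p <- ncol(E)
  stopifnot(B >= 1)
  if (is.null(perms)) {
    perms <- if (is.null(seed)) {
      vapply(seq_len(B), function(b) sample.int(n), integer(n))
    } else {
      withr::with_seed(seed, vapply(seq_len(B), function(b) sample.int(n),
                                    integer(n)))
    }
  }
  stopifnot(nrow(perms) == n, ncol(perms) == B)
  fams <- pheno_families(phenotypes)
  K <- length(fams)
  Zm <- if (with_covariates) {
    as_covariate_matrix(normalize_covariates(covariates), n)
  } else NULL

  ss_e <- colSums(E^2)
  dead <- ss_e <= 0
  Eu <- sweep(E, 2, sqrt(pmax(ss_e, .Machine$double.xmin)), "/")

  # per-phenotype prepared pieces
  prep <- lapply(names(fams), function(nm) {
    col <- pheno_column(phenotypes, nm)
    fam <- col$family
    if (fam == "gaussian") {
      yr <- if (is.null(Zm)) col$y - mean(col$y) else {
        qr.resid(qr(cbind(1, Zm)), col$y)
      }
      list(family = fam, yu = yr / sqrt(sum(yr^2)),
           df = n - 2L - if (is.null(Zm)) 0L else ncol(Zm))
    } else if (fam %in% c("poisson", "binomial")) {
      if (is.null(Zm)) {
        mu <- rep(mean(col$y), n)
      } else {
        mu <- stats::fitted(glm(col$y ~ Zm, family = fam))
      }
      w <- if (fam == "poisson") mu else mu * (1 - mu)
      list(family = fam, yc = col$y - mu, w = w)
    } else {
      list(family = fam, y = col$y)
    }
  })

  out <- array(NA_real_, dim = c(B, p, K))
  n_failed <- 0L
  fast <- !any(vapply(prep, function(pk) pk$family == "survival",
                      logical(1)))
  if (fast) {
    # t(E[perm_b, ]) %*% y equals t(E) %*% y[inverse(perm_b)], so all B
    # permutations of all K phenotypes collapse into one matrix product.
    # With covariates in the null model the numerator is unchanged by
    # projecting the permuted residuals (the adjusted response is already
    # orthogonal to the covariate space / satisfies the null score
    # equations); only per-permutation scale corrections are needed.
    inv <- apply(perms, 2, order)
    Ybig <- matrix(0, n, B * K)
    for (k in seq_len(K)) {
      pk <- prep[[k]]
      ycol <- if (pk$family == "gaussian") pk$yu else pk$yc
      Ybig[, (k - 1L) * B + seq_len(B)] <- ycol[inv]
    }
    CC <- crossprod(Eu, Ybig)                      # p x (B*K)
    ssproj <- NULL
    if (!is.null(Zm)) {
      D <- cbind(1, Zm)
      qrD <- qr(D)
      Q <- qr.Q(qrD)                               # n x rank, orthonormal
      ssproj <- matrix(1, p, B)                    # ||P_perp e_perm||^2
      for (b in seq_len(B)) {
        QtE <- crossprod(Q[inv[, b], , drop = FALSE], Eu)
        ssproj[, b] <- pmax(1 - colSums(QtE^2), .Machine$double.xmin)
      }
      Eu2 <- Eu^2
    }
    for (k in seq_len(K)) {
      pk <- prep[[k]]
      Ck <- CC[, (k - 1L) * B + seq_len(B), drop = FALSE]
      if (pk$family == "gaussian") {
        r <- if (is.null(ssproj)) Ck else Ck / sqrt(ssproj)
        r <- pmin(pmax(r, -1), 1)
        tval <- r * sqrt(pk$df / pmax(1 - r^2, .Machine$double.xmin))
        pv <- 2 * pt(-abs(tval), pk$df)
      } else if (is.null(Zm)) {
        # intercept-only null: constant weights, unit-SS residual columns
        v_k <- pk$w[1]
        z <- Ck / sqrt(max(v_k, .Machine$double.xmin))
        pv <- 2 * pnorm(-abs(z))
        if (!is.finite(v_k) || v_k <= 0) pv[] <- 1
      } else {
        # efficient-score variance with the covariates in the null model
        Dw <- cbind(1, Zm) * pk$w
        DWD <- crossprod(cbind(1, Zm), Dw)
        V <- matrix(NA_real_, p, B)
        for (b in seq_len(B)) {
          ib <- inv[, b]
          T1 <- crossprod(Eu2, pk$w[ib])[, 1]
          Aw <- crossprod(Dw[ib, , drop = FALSE], Eu)
          V[, b] <- T1 - colSums(Aw * solve(DWD, Aw))
        }
        z <- Ck / sqrt(pmax(V, .Machine$double.xmin))
        pv <- 2 * pnorm(-abs(z))
        pv[!is.finite(V) | V <= 0] <- 1
      }
      pv[dead, ] <- 1
      out[, , k] <- t(clip_p(pv, eps))
    }
    n_failed <- sum(dead) * B * K
    if (sum(dead) > 0.01 * p) {
      warning(sum(dead), " constant gene(s) produced degenerate null fits",
              call. = FALSE)
    }
    return(structure(list(p = out, perms = perms, B = B,
                          n_failed = n_failed, families = fams),
                     class = "af_null_tensor"))
  }
  for (b in seq_len(B)) {
    idx <- perms[, b]
    Eb <- Eu[idx, , drop = FALSE]
    if (!is.null(Zm)) {
      # permuted residuals are no longer orthogonal to Z; re-project
      Eb <- qr.resid(qr(cbind(1, Zm)), Eb)
      sse_b <- colSums(Eb^2)
      Eb <- sweep(Eb, 2, sqrt(pmax(sse_b, .Machine$double.xmin)), "/")
    }
    for (k in seq_len(K)) {
      pk <- prep[[k]]
      if (pk$family == "gaussian") {
        r <- crossprod(Eb, pk$yu)[, 1]
        r <- pmin(pmax(r, -1), 1)
        tval <- r * sqrt(pk$df / pmax(1 - r^2, .Machine$double.xmin))
        pv <- 2 * pt(-abs(tval), pk$df)
      } else if (pk$family %in% c("poisson", "binomial")) {
        num <- crossprod(Eb, pk$yc)[, 1]
        V <- colSums(Eb^2 * pk$w)
        z <- num / sqrt(pmax(V, .Machine$double.xmin))
        pv <- 2 * pnorm(-abs(z))
        pv[!is.finite(V) | V <= 0] <- 1
      } else { # survival: per-gene Cox fits on the permuted residuals
        pv <- vapply(seq_len(p), function(j) {
          fit_association_cox(pk$y, E[idx, j], NULL, eps)$p
        }, numeric(1))
      }
      pv[dead] <- 1
      out[b, , k] <- clip_p(pv, eps)
    }
  }
  n_failed <- sum(dead) * B * K
  if (sum(dead) > 0.01 * p) {
    warning(sum(dead), " constant gene(s) produced degenerate null fits",
            call. = FALSE)
  }
  structure(list(p = out, perms = perms, B = B, n_failed = n_failed,
                 families = fams),
            class = "af_null_tensor")
}

#' @export
print.af_null_tensor <- function(x, ...) {
  d <- dim(x$p)
  cat("<af_null_tensor> B = ", d[1], ", genes = ", d[2],
      ", phenotypes = ", d[3], " (pooled null size ", d[1] * d[2], ")\n",
      sep = "")
  invisible(x)
}

# ---- input coercion helpers -------------------------------------------------

as_expression_matrix <- function(expression) {
  if (is.matrix(expression)) return(expression)
  df <- as.data.frame(expression)
  if ("sample" %in% names(df)) {
    rn <- df$sample
    df$sample <- NULL
    X <- as.matrix(df); rownames(X) <- rn
    return(X)
  }
  as.matrix(df)
}

normalize_covariates <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (NCOL(covariates) == 0) return(NULL)
  covariates
}

as_covariate_matrix <- function(Z, n) {
  if (is.null(Z)) return(NULL)
  Zm <- if (is.data.frame(Z)) {
    stats::model.matrix(~ . - 1, data = Z)
  } else {
    as.matrix(Z)
  }
  stopifnot(nrow(Zm) == n)
  Zm
}

check_alignment <- function(X, phenotypes, covariates) {
  n <- nrow(X)
  if (nrow(phenotypes) != n) {
    stop("expression has ", n, " samples but phenotypes has ",
         nrow(phenotypes), call. = FALSE)
  }
  if (!is.null(covariates) && NROW(covariates) != n) {
    stop("expression has ", n, " samples but covariates has ",
         NROW(covariates), call. = FALSE)
  }
  rn <- rownames(X)
  cn <- if (is.null(covariates)) NULL else rownames(as.data.frame(covariates))
  default_rn <- function(x) is.null(x) || identical(x, paste(seq_along(x)))
  if (!default_rn(rn) && !default_rn(cn) && !identical(rn, cn)) {
    bad <- head(cn[rn != cn], 5)
    stop("sample IDs misaligned between expression and covariates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
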