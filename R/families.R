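#' Declare a typed phenotype table
#'
#' Bundles a samples-by-phenotypes data frame with the distribution family
#' declared for each phenotype. Families determine the generalized linear
#' model (and link) used when each phenotype is regressed on a gene:
#' `gaussian` (identity link), `binomial` (logit), `poisson` (log) and
#' `survival` (Cox proportional hazards). A survival phenotype occupies two
#' columns, `<name>_time` and `<name>_event`, and is declared once under
#' `<name>`.
#'
#' @param values A data frame (samples x phenotypes) with no missing values.
#'   Rows with missing phenotypes must be dropped upstream (see
#'   [drop_incomplete_samples()]).
#' @param families Named character vector mapping each phenotype name to one
#'   of `"gaussian"`, `"binomial"`, `"poisson"`, `"survival"`. Unnamed
#'   vectors are matched positionally to the declared phenotypes.
#' @return A `typed_phenotypes` object: a tibble with a `families` attribute.
#' @examples
#' yt <- typed_phenotypes(
#'   data.frame(bmi = rnorm(20), case = rbinom(20, 1, 0.5)),
#'   c(bmi = "gaussian", case = "binomial")
#' )
#' pheno_families(yt)
#' @export
typed_phenotypes <- function(values, families) {
  values <- tibble::as_tibble(values)
  fam_ok <- c("gaussian", "binomial", "poisson", "survival")
  families <- as.character(families)
  if (is.null(names(families)) || any(!nzchar(names(families)))) {
    # positional: survival names inferred from *_time/*_event pairs
    names(families) <- infer_pheno_names(values, families)
  }
  if (!all(families %in% fam_ok)) {
    stop("unknown phenotype family: ",
         paste(setdiff(families, fam_ok), collapse = ", "), call. = FALSE)
  }
  for (nm in names(families)) {
    fam <- families[[nm]]
    if (fam == "survival") {
      tnm <- paste0(nm, "_time"); enm <- paste0(nm, "_event")
      if (!all(c(tnm, enm) %in% names(values))) {
        stop("survival phenotype '", nm, "' needs columns '", tnm,
             "' and '", enm, "'", call. = FALSE)
      }
      tt <- values[[tnm]]; ee <- values[[enm]]
      if (anyNA(tt) || anyNA(ee)) stop("missing values in phenotype '", nm, "'",
                                       call. = FALSE)
      if (any(tt <= 0)) stop("survival times for '", nm, "' must be > 0",
                             call. = FALSE)
      if (!all(ee %in% c(0, 1))) stop("survival event indicator for '", nm,
                                      "' must be 0/1", call. = FALSE)
      next
    }
    if (!nm %in% names(values)) {
      stop("phenotype '", nm, "' not found in the table", call. = FALSE)
    }
    yy <- values[[nm]]
    if (anyNA(yy)) stop("missing values in phenotype '", nm, "'", call. = FALSE)
    if (fam == "binomial" && !all(yy %in% c(0, 1))) {
      stop("binomial phenotype '", nm, "' must be coded 0/1", call. = FALSE)
    }
    if (fam == "poisson" && (any(yy < 0) || any(yy != round(yy)))) {
      stop("poisson phenotype '", nm, "' must be non-negative integers",
           call. = FALSE)
    }
  }
  structure(values, families = families,
            class = c("typed_phenotypes", class(values)))
}

infer_pheno_names <- function(values, families) {
  nms <- character(length(families))
  cols <- names(values)
  i_col <- 1L
  for (i in seq_along(families)) {
    if (families[[i]] == "survival") {
      base <- sub("_time$", "", cols[[i_col]])
      nms[[i]] <- base
      i_col <- i_col + 2L
    } else {
      nms[[i]] <- cols[[i_col]]
      i_col <- i_col + 1L
    }
  }
  nms
}

#' Phenotype families of a typed phenotype table
#' @param y A `typed_phenotypes` object.
#' @return Named character vector of families.
#' @export
pheno_families <- function(y) {
  stopifnot(inherits(y, "typed_phenotypes"))
  attr(y, "families")
}

#' @export
print.typed_phenotypes <- function(x, ...) {
  fam <- attr(x, "families")
  cat("<typed_phenotypes> ", nrow(x), " samples, ", length(fam),
      " phenotypes\n", sep = "")
  cat(paste0("  ", names(fam), " <", fam, ">", collapse = "\n"), "\n")
  invisible(x)
}

# n x 1 numeric (or Surv) response for phenotype k, plus its family
pheno_column <- function(y, name) {
  fam <- pheno_families(y)[[name]]
  if (fam == "survival") {
    list(y = survival::Surv(y[[paste0(name, "_time")]],
                            y[[paste0(name, "_event")]]),
         family = fam)
  } else {
    list(y = y[[name]], family = fam)
  }
}
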