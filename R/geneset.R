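#' Bonferroni significance threshold
#'
#' @param alpha family-wise error target.
#' @param n_tests number of tests (>= 1).
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Drop the unassigned ("gray") module from a gene universe
#'
#' The unassigned set collects genes belonging to no co-expression module;
#' it is removed from the tested sets, and genes found only in it leave the
#' background universe entirely.
#'
#' @param universe data.frame with a `gene` column and logical set-membership
#'   columns.
#' @param set_cols names of the set-membership columns.
#' @param unassigned_set_id name of the unassigned set column (absent is a
#'   no-op).
#' @return universe with the unassigned column removed and its exclusive
#'   genes dropped; attribute `tested_sets` lists the remaining sets.
#' @export
exclude_unassigned <- function(universe, set_cols,
                               unassigned_set_id = "gray") {
  if (!(unassigned_set_id %in% set_cols)) {
    attr(universe, "tested_sets") <- set_cols
    return(universe)
  }
  others <- setdiff(set_cols, unassigned_set_id)
  in_other <- if (length(others))
    Reduce(`|`, lapply(others, function(s) universe[[s]])) else
      rep(FALSE, nrow(universe))
  keep <- !universe[[unassigned_set_id]] | in_other
  out <- universe[keep, setdiff(names(universe), unassigned_set_id),
                  drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested_sets") <- others
  out
}

# standardize covariates: log10 for strictly positive scale covariates
# (length, expression), raw fraction for GC; then z-score
.standardize_covariates <- function(universe, covariates) {
  X <- NULL
  for (cv in covariates) {
    v <- universe[[cv]]
    if (any(!is.finite(v))) stop("covariate ", cv, " has non-finite values")
    if (cv %in% c("gene_length", "length_bp", "mean_expression", "expr"))
      v <- log10(pmax(v, .Machine$double.eps))
    s <- stats::sd(v)
    v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    X <- cbind(X, v)
  }
  if (!is.null(X)) colnames(X) <- covariates
  X
}

# Firth-penalized logistic regression: Newton iterations on the modified
# score U*(b) = X'(y - p + h (1/2 - p)), h the leverages of the weighted fit
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, X)
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    H <- XW %*% solve(XtWX, t(XW))
    h <- diag(H)
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- solve(XtWX, U)
    b <- b + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  se <- sqrt(diag(solve(XtWX)))
  list(coef = stats::setNames(b, colnames(X)),
       se = stats::setNames(se, colnames(X)), iterations = it)
}

#' Indicator-based gene-set enrichment by logistic regression
#'
#' Covariate-adjusted enrichment of a disease gene list in a gene set
#' (co-expression module or cell-type marker set). Two orientations are
#' supported, matching the two analyses: `"module"` fits
#' is.disease ~ is.set + covariates; `"celltype"` fits
#' is.set ~ is.disease + covariates. Covariates are transformed (log10 for
#' length and expression, raw for GC fraction) and z-scored internally. The
#' p-value is the Wald test on the indicator coefficient. Complete or
#' quasi-complete separation is detected; with `firth = TRUE` a
#' Firth-penalized fit is used and flagged, otherwise separation is an
#' explicit error.
#'
#' @param universe data.frame with `gene`, logical membership columns and
#'   covariate columns.
#' @param set_id name of the gene-set membership column.
#' @param disease_id name of the disease-list membership column.
#' @param orientation `"module"` or `"celltype"`.
#' @param covariates covariate column names (may be empty).
#' @param firth enable the penalized fallback under separation.
#' @return data.frame: set, disease, orientation, coefficient (log-odds),
#'   se, p, separation, firth.
#' @export
fit_enrichment <- function(universe, set_id, disease_id,
                           orientation = c("module", "celltype"),
                           covariates = intersect(
                             c("gc_content", "gene_length", "mean_expression"),
                             names(universe)),
                           firth = FALSE) {
  orientation <- match.arg(orientation)
  s <- as.logical(universe[[set_id]])
  d <- as.logical(universe[[disease_id]])
  for (v in list(s, d)) {
    if (all(v) || !any(v))
      stop("indicator with no genes on one side (set or disease spans the ",
           "whole universe or none of it)")
  }
  y <- if (orientation == "module") d else s
  x <- if (orientation == "module") s else d
  X <- cbind(indicator = as.numeric(x),
             .standardize_covariates(universe, covariates))

  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), as.numeric(y),
                                         family = stats::binomial()))
  pr <- fit$fitted.values
  sep <- any(pr < 1e-8 | pr > 1 - 1e-8) || any(abs(fit$coefficients) > 15)
  used_firth <- FALSE
  if (sep) {
    if (!firth)
      stop("separation detected in logistic fit for set '", set_id,
           "'; enable the Firth fallback to obtain a penalized estimate")
    ff <- .firth_logistic(X, as.numeric(y))
    coef <- ff$coef[["indicator"]]
    se <- ff$se[["indicator"]]
    used_firth <- TRUE
  } else {
    sm <- chol2inv(chol(crossprod(sqrt(fit$weights) * cbind(1, X))))
    coef <- fit$coefficients[2L]
    se <- sqrt(diag(sm))[2L]
  }
  z <- coef / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(set = set_id, disease = disease_id, orientation = orientation,
             coefficient = unname(coef), se = unname(se), p = unname(p),
             separation = sep, firth = used_firth, stringsAsFactors = FALSE)
}

#' Enrichment matrix over many sets and disease lists
#'
#' @param universe gene universe data.frame.
#' @param set_cols set membership columns (the unassigned set should already
#'   be excluded, see [exclude_unassigned()]).
#' @param disease_cols disease membership columns.
#' @param n_tests Bonferroni divisor (defaults to the number of sets, the
#'   published convention even when an unassigned set is untested).
#' @param alpha family-wise error target.
#' @inheritParams fit_enrichment
#' @return long data.frame of [fit_enrichment()] rows with a `significant`
#'   flag at the Bonferroni threshold (attribute `threshold`).
#' @export
enrichment_matrix <- function(universe, set_cols, disease_cols,
                              orientation = "module",
                              n_tests = length(set_cols), alpha = 0.05,
                              covariates = intersect(
                                c("gc_content", "gene_length", "mean_expression"),
                                names(universe)),
                              firth = TRUE) {
  thr <- bonferroni_threshold(alpha, n_tests)
  rows <- list()
  for (s in set_cols) for (d in disease_cols) {
    rows[[paste(s, d)]] <- fit_enrichment(universe, s, d,
                                          orientation = orientation,
                                          covariates = covariates,
                                          firth = firth)
  }
  res <- do.call(rbind, rows)
  res$significant <- res$p <= thr
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}
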