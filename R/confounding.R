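#' Nagelkerke pseudo-R2 of structure covariates against a binary phenotype
#'
#' Quantifies how much variance in a case/control phenotype is explained by
#' structure covariates (typically principal components of a haplotype
#' sharing matrix) — a direct measure of stratification-driven GWAS
#' confounding. Logistic models with intercept-only (null) and
#' intercept-plus-covariates are fit by maximum likelihood and
#' `R2 = (1 - exp((2/n) (l0 - l1))) / (1 - exp((2/n) l0))`
#' with l0, l1 the null and fitted log-likelihoods. Both the cumulative R2
#' (covariates added left to right) and each covariate's marginal R2 (that
#' covariate alone) are reported.
#'
#' @param phenotype 0/1 vector (at least two of each class).
#' @param covariates numeric matrix or data frame of covariate columns.
#' @return object of class `nagelkerke_r2`: list with `r2` (full model),
#'   `table` (data frame: covariate, marginal_r2, cumulative_r2),
#'   `separation` flag.
#' @export
nagelkerke_r2 <- function(phenotype, covariates) {
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1",
                                 call. = FALSE)
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    stop("need at least two of each phenotype class", call. = FALSE)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop("covariates must be finite", call. = FALSE)
  n <- length(y)
  separated <- FALSE
  fit_r2 <- function(cols) {
    f0 <- stats::glm(y ~ 1, family = stats::binomial())
    f1 <- withCallingHandlers(
      stats::glm(y ~ x[, cols, drop = FALSE], family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    # glm diverges slowly under separation and may stop before its own
    # warning fires; a perfectly classifying fit with ~zero deviance is
    # separation regardless
    mu <- stats::fitted(f1)
    if (f1$deviance < 1e-2 && max(mu[y == 0]) < min(mu[y == 1]))
      separated <<- TRUE
    l0 <- as.numeric(stats::logLik(f0))
    l1 <- as.numeric(stats::logLik(f1))
    r2 <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
    min(max(r2, 0), 1)
  }
  marg <- vapply(seq_len(ncol(x)), function(j) fit_r2(j), numeric(1))
  cumu <- vapply(seq_len(ncol(x)), function(j) fit_r2(seq_len(j)),
                 numeric(1))
  if (separated)
    warning("perfect or quasi-perfect separation detected; R2 capped at 1")
  structure(list(r2 = cumu[length(cumu)],
                 table = data.frame(covariate = colnames(x),
                                    marginal_r2 = marg,
                                    cumulative_r2 = cumu,
                                    stringsAsFactors = FALSE),
                 separation = separated),
            class = "nagelkerke_r2")
}

#' @export
print.nagelkerke_r2 <- function(x, ...) {
  cat(sprintf("Nagelkerke R2 (full model): %.4f%s\n", x$r2,
              if (x$separation) "  [separation: capped]" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}
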