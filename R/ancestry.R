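#' Donor-group copying matrix from a reference painting
#'
#' From a donors-vs-donors painting, normalises each donor's row to 1,
#' aggregates donor columns by group, and averages rows within each group.
#' Row g of the result is the average proportion of DNA that individuals of
#' donor group g copy from each donor group, including their own — the
#' mixture basis for [nnls_profile()].
#'
#' @param painting square coancestry matrix of the reference donors.
#' @param groups named character vector mapping every donor id to a group
#'   label; an optional `country` attribute (named character vector, group
#'   -> country) is carried through for [aggregate_by_country()].
#' @param countries optional named character vector mapping group labels to
#'   country labels.
#' @return matrix of class `donor_copy_matrix` (G x G, rows summing to 1)
#'   with attribute `country` when provided.
#' @export
donor_copy_matrix <- function(painting, groups, countries = NULL) {
  check_coancestry(painting)
  gl <- check_assignment(painting, groups)
  labs <- sort(unique(gl))
  if (any(table(gl) < 1)) stop("every donor group must be non-empty",
                               call. = FALSE)
  s <- rowSums(painting)
  if (any(s == 0)) stop("donor row(s) with zero total copying: ",
                        paste(rownames(painting)[s == 0], collapse = ", "),
                        call. = FALSE)
  norm <- painting / s
  agg <- norm %*% (outer(gl, labs, "==") * 1)       # columns by group
  X <- rowsum(agg, gl) / as.vector(table(gl)[labs]) # rows averaged in group
  X <- X[labs, , drop = FALSE]
  colnames(X) <- labs
  if (!is.null(countries)) {
    if (!all(labs %in% names(countries)))
      stop("country label missing for group(s): ",
           paste(setdiff(labs, names(countries)), collapse = ", "),
           call. = FALSE)
    attr(X, "country") <- countries[labs]
  }
  class(X) <- c("donor_copy_matrix", class(X))
  X
}

#' Non-negative least squares ancestry profile
#'
#' Models a target individual's copying vector as a non-negative mixture of
#' donor-group copying vectors: minimise `||y - t(X) %*% beta||` subject to
#' `beta >= 0`, then rescale beta to sum to 1. The coefficients are the
#' cleaned proportions of the genome most closely shared with each donor
#' group. The sum-to-one constraint is enforced by post-hoc renormalisation
#' of the unconstrained NNLS solution by default; `method = "penalty"`
#' appends a heavily weighted sum-to-one pseudo-observation instead (both
#' agree to ~1e-3 on well-posed problems).
#'
#' @param y target copying vector over the G donor groups, summing to 1.
#' @param x donor copy matrix ([donor_copy_matrix()]), rows = groups.
#' @param method `"renormalize"` (default) or `"penalty"`.
#' @return object of class `ancestry_profile`: list with `beta` (named,
#'   non-negative, summing to 1), `retained` (groups with positive weight),
#'   `residual` (NNLS residual norm).
#' @examples
#' X <- diag(3); dimnames(X) <- list(LETTERS[1:3], LETTERS[1:3])
#' nnls_profile(c(A = 0.5, B = 0.3, C = 0.2), X)$beta
#' @export
nnls_profile <- function(y, x, method = c("renormalize", "penalty")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  G <- nrow(x)
  if (length(y) != ncol(x))
    stop("target vector length must match donor-group count", call. = FALSE)
  if (abs(sum(y) - 1) > 1e-6)
    stop("target copying vector must be normalized to sum 1", call. = FALSE)
  A <- t(unclass(x))                      # columns are donor-group profiles
  if (method == "penalty") {
    w <- 1e3
    A <- rbind(A, rep(w, G))
    yy <- c(y, w)
  } else yy <- y
  beta <- pracma::lsqnonneg(A, yy)$x
  if (sum(beta) <= 0)
    stop("all-zero NNLS solution: target is orthogonal to every donor profile",
         call. = FALSE)
  beta <- beta / sum(beta)
  names(beta) <- rownames(x)
  structure(list(beta = beta, retained = names(beta)[beta > 0],
                 residual = sqrt(sum((y - as.vector(t(unclass(x)) %*% beta))^2)),
                 country = attr(x, "country")),
            class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat("Ancestry profile (NNLS mixture shares):\n")
  print(round(x$beta[x$beta > 0], 4))
  invisible(x)
}

#' Prune weak donor groups and refit
#'
#' Iteratively drops retained groups whose share is below `threshold` for
#' this individual and refits the NNLS on the survivors, renormalising each
#' time, until every retained share is at least `threshold` (or one group
#' remains). This eliminates noise contributions from donor groups that
#' resemble the real sources.
#'
#' @param profile an `ancestry_profile` from [nnls_profile()].
#' @param x the donor copy matrix used for the original fit.
#' @param y the original target vector (needed for refitting).
#' @param threshold minimum share, in (0, 1); `0` disables pruning.
#' @return a pruned `ancestry_profile` whose `beta` keeps all G names (
#'   dropped groups at exactly 0).
#' @export
prune_and_refit <- function(profile, x, y, threshold = 0.05) {
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)", call. = FALSE)
  if (threshold == 0) return(profile)
  beta <- profile$beta
  keep <- names(beta)[beta > 0]
  repeat {
    weak <- keep[beta[keep] < threshold]
    if (length(weak) == 0 || length(keep) <= 1) break
    if (length(weak) == length(keep))   # keep the strongest group alive
      weak <- setdiff(weak, keep[which.max(beta[keep])])
    keep <- keep[!(keep %in% weak)]
    if (length(keep) == 1) {
      beta[] <- 0; beta[keep] <- 1
      break
    }
    sub <- unclass(x)[keep, , drop = FALSE]
    b <- pracma::lsqnonneg(t(sub), as.numeric(y))$x
    if (sum(b) <= 0) stop("refit produced an all-zero solution",
                          call. = FALSE)
    beta[] <- 0
    beta[keep] <- b / sum(b)
  }
  structure(list(beta = beta, retained = names(beta)[beta >= threshold &
                                                       beta > 0],
                 residual = sqrt(sum((as.numeric(y) -
                                        as.vector(t(unclass(x)) %*% beta))^2)),
                 country = profile$country),
            class = "ancestry_profile")
}

#' Aggregate an ancestry profile by country
#'
#' Sums mixture shares over donor groups with the same country label; the
#' country shares conserve the total (sum to 1).
#'
#' @param profile an `ancestry_profile`.
#' @param countries named character vector (group -> country); defaults to
#'   the `country` attribute carried from [donor_copy_matrix()].
#' @return named numeric vector of country shares.
#' @export
aggregate_by_country <- function(profile, countries = NULL) {
  if (is.null(countries)) countries <- profile$country
  if (is.null(countries))
    stop("no country labels available for aggregation", call. = FALSE)
  groups <- names(profile$beta)
  if (!all(groups %in% names(countries)))
    stop("country label missing for group(s): ",
         paste(setdiff(groups, names(countries)), collapse = ", "),
         call. = FALSE)
  out <- tapply(profile$beta, countries[groups], sum)
  out <- out[sort(names(out))]
  c(out)
}

#' Fit ancestry profiles for a cohort of targets
#'
#' Convenience wrapper: NNLS fit plus prune-and-refit for each row of a
#' target matrix.
#'
#' @param targets n x G matrix of target copying vectors (rows sum to 1).
#' @param x donor copy matrix.
#' @param threshold prune threshold passed to [prune_and_refit()].
#' @return n x G matrix of mixture shares.
#' @export
ancestry_profiles <- function(targets, x, threshold = 0.05) {
  out <- t(apply(targets, 1, function(y) {
    p <- nnls_profile(y, x)
    prune_and_refit(p, x, y, threshold = threshold)$beta
  }))
  dimnames(out) <- list(rownames(targets), rownames(x))
  out
}
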