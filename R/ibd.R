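#' IBD segment length bin
#'
#' Half-open interval \[L1, L2) in cM. Half-open bins make any partition of
#' segment lengths disjoint, so binned sharing matrices over a partition sum
#' exactly to the total sharing matrix. `L2 = Inf` is allowed (open-ended
#' bin).
#'
#' @param L1,L2 bounds in cM, `0 < L1 < L2`.
#' @return object of class `segment_bin`.
#' @export
segment_bin <- function(L1, L2) {
  if (!(is.finite(L1) && L1 > 0 && L2 > L1))
    stop("need 0 < L1 < L2", call. = FALSE)
  structure(list(L1 = L1, L2 = L2), class = "segment_bin")
}

#' @export
print.segment_bin <- function(x, ...) {
  cat(sprintf("IBD length bin [%g, %g) cM\n", x$L1, x$L2))
  invisible(x)
}

#' Length-binned pairwise IBD sharing matrix
#'
#' Entry (i, j) is the total cM length (or the count) of IBD segments of
#' length in \[L1, L2) shared between i and j; symmetric with zero diagonal.
#' Individuals sharing no segment still appear (as zero rows) when listed
#' in `roster`.
#'
#' @param segments IBD segment data frame ([read_ibd()]).
#' @param bin a [segment_bin()].
#' @param statistic `"total_cM"` (default) or `"count"`.
#' @param roster optional character vector of individual ids fixing the
#'   matrix order; defaults to the sorted ids present in `segments`.
#' @return square symmetric matrix with roster ids as dimnames.
#' @export
binned_sharing_matrix <- function(segments, bin,
                                  statistic = c("total_cM", "count"),
                                  roster = NULL) {
  statistic <- match.arg(statistic)
  if (!inherits(bin, "segment_bin")) bin <- do.call(segment_bin, as.list(bin))
  if (is.null(roster))
    roster <- sort(unique(c(segments$id1, segments$id2)))
  if (length(roster) == 0) stop("empty roster", call. = FALSE)
  n <- length(roster)
  m <- matrix(0, n, n, dimnames = list(roster, roster))
  keep <- segments$length_cM >= bin$L1 & segments$length_cM < bin$L2
  s <- segments[keep, , drop = FALSE]
  if (nrow(s) > 0) {
    i <- match(s$id1, roster); j <- match(s$id2, roster)
    if (anyNA(i) || anyNA(j))
      stop("segment ids absent from roster: ",
           paste(unique(c(s$id1[is.na(i)], s$id2[is.na(j)])), collapse = ", "),
           call. = FALSE)
    val <- if (statistic == "total_cM") s$length_cM else rep(1, nrow(s))
    for (k in seq_along(i)) {
      m[i[k], j[k]] <- m[i[k], j[k]] + val[k]
      m[j[k], i[k]] <- m[j[k], i[k]] + val[k]
    }
  }
  attr(m, "bin") <- bin
  attr(m, "statistic") <- statistic
  m
}

#' Expected age of IBD segments in a length bin
#'
#' Closed-form expectation of the coalescence time of segments whose length
#' falls between `L1` and `L2` cM, in the large-population limit:
#' `E[T] = 75 (1/L1 + 1/L2)` generations, converted to years with an
#' approximate human generation time (28 years by default). The degenerate
#' limit L1 = L2 = L gives 150/L generations. The Monte-Carlo oracle
#' [tmrca_mc_oracle()] reproduces this value by simulation.
#'
#' @param bin a [segment_bin()] (or `c(L1, L2)`).
#' @param generation_time_years years per generation.
#' @return list with `generations` and `years` (years before present, as a
#'   pure duration; anchoring to a calendar epoch is left to the caller).
#' @examples
#' expected_tmrca(segment_bin(3, 5))$years   # 1120
#' @export
expected_tmrca <- function(bin, generation_time_years = 28) {
  if (!inherits(bin, "segment_bin")) bin <- do.call(segment_bin, as.list(bin))
  if (bin$L1 <= 0) stop("L1 must be positive", call. = FALSE)
  gen <- 75 * (1 / bin$L1 + 1 / bin$L2)
  list(generations = gen, years = gen * generation_time_years)
}

#' PCA plus Gaussian-mixture clustering of a sharing matrix
#'
#' Projects a binned IBD sharing (or coancestry) matrix onto its leading
#' principal components ([pca_coancestry()] convention: column-centred,
#' unscaled, fixed signs) and clusters the scores with a Gaussian mixture
#' model, selecting the number of components and the covariance family
#' (diagonal `"VVI"` or full `"VVV"`) by BIC over k = 1..`k_max`.
#'
#' @param m square symmetric sharing matrix with id dimnames.
#' @param n_pcs number of principal components to cluster (capped at
#'   `nrow(m) - 1`).
#' @param k_max largest number of mixture components tried; needs at least
#'   `k_max + 1` individuals.
#' @param seed integer seed (the EM initialisation is deterministic, but the
#'   seed is set for any stochastic refinement).
#' @return list with `assignment` (named cluster labels "1".."k"),
#'   `chosen_k`, `model` (covariance family), `bic_table` (k x family BIC
#'   values, larger is better in the mclust convention).
#' @importFrom mclust Mclust mclustBIC
#' @export
pca_gmm_cluster <- function(m, n_pcs = 10, k_max = 9, seed = 1L) {
  check_coancestry(m)
  if (nrow(m) < k_max + 1)
    stop("need at least k_max + 1 individuals", call. = FALSE)
  if (all(m == 0)) stop("degenerate (all-zero) sharing matrix",
                        call. = FALSE)
  n_pcs <- min(n_pcs, nrow(m) - 1)
  scores <- pca_coancestry(m, n_components = n_pcs)$scores
  keep <- apply(scores, 2, function(s) stats::sd(s) > 1e-12)
  scores <- scores[, keep, drop = FALSE]
  set.seed(as.integer(seed))
  fit <- mclust::Mclust(scores, G = 1:k_max,
                        modelNames = c("VVI", "VVV"), verbose = FALSE)
  if (is.null(fit))
    stop("Gaussian mixture fit failed for every model", call. = FALSE)
  list(assignment = stats::setNames(as.character(fit$classification),
                                    rownames(m)),
       chosen_k = fit$G, model = fit$modelName,
       bic_table = fit$BIC)
}

#' Mean pairwise IBD sharing within and between groups
#'
#' Entry (g, h) is the total qualifying sharing statistic over the relevant
#' pair set divided by the exact pair-count denominator: `(N^2 - N) / 2` for
#' a group of size N with itself and `N * M` for two groups of sizes N and
#' M. The default statistic is the segment count ("mean number of segments
#' shared"); `"total_cM"` averages total length instead.
#'
#' @param segments IBD segment data frame.
#' @param groups named character vector mapping ids to group labels; must
#'   cover every id appearing in `segments`, and may include extra ids
#'   (counted in the denominators as zero-sharing members).
#' @param bin a [segment_bin()].
#' @param statistic `"count"` (default) or `"total_cM"`.
#' @return symmetric group x group matrix of means.
#' @export
mean_pairwise_sharing <- function(segments, groups, bin,
                                  statistic = c("count", "total_cM")) {
  statistic <- match.arg(statistic)
  if (!inherits(bin, "segment_bin")) bin <- do.call(segment_bin, as.list(bin))
  ids <- names(groups)
  miss <- setdiff(unique(c(segments$id1, segments$id2)), ids)
  if (length(miss) > 0)
    stop("group label missing for id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  labs <- sort(unique(groups))
  sizes <- table(factor(groups, levels = labs))
  if (any(sizes == 1))
    stop("within-group mean undefined for singleton group(s): ",
         paste(labs[sizes == 1], collapse = ", "), call. = FALSE)
  keep <- segments$length_cM >= bin$L1 & segments$length_cM < bin$L2
  s <- segments[keep, , drop = FALSE]
  num <- matrix(0, length(labs), length(labs),
                dimnames = list(labs, labs))
  if (nrow(s) > 0) {
    g1 <- groups[s$id1]; g2 <- groups[s$id2]
    val <- if (statistic == "count") rep(1, nrow(s)) else s$length_cM
    for (k in seq_len(nrow(s))) {
      num[g1[k], g2[k]] <- num[g1[k], g2[k]] + val[k]
      if (g1[k] != g2[k]) num[g2[k], g1[k]] <- num[g2[k], g1[k]] + val[k]
    }
  }
  nn <- as.vector(sizes)
  den <- outer(nn, nn)                    # N * M between groups
  diag(den) <- (nn^2 - nn) / 2            # (N^2 - N) / 2 within
  num / den
}
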