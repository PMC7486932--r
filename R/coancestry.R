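check_coancestry <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("coancestry matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("coancestry matrix needs identical row and column ids",
         call. = FALSE)
  if (any(m < 0)) stop("coancestry entries must be >= 0", call. = FALSE)
  invisible(m)
}

check_assignment <- function(m, clusters) {
  ids <- rownames(m)
  if (is.null(names(clusters)) || !all(ids %in% names(clusters)))
    stop("cluster assignment must cover every id in the matrix",
         call. = FALSE)
  clusters[ids]
}

#' Per-cluster copying vectors
#'
#' The copying vector of cluster A has one component per cluster k: the mean
#' over recipients in A of the total genetic length donated to them by the
#' members of k. Donations from a cluster's own members are included (only
#' the self-individual is excluded, through the matrix's zero diagonal).
#' When normalised, each vector is divided by its sum so it is a probability
#' vector over donor clusters — the form required by [tvd_pair()].
#'
#' @param m square coancestry matrix (recipients x donors, id dimnames).
#' @param clusters named character vector mapping every id to a cluster
#'   label.
#' @param normalize logical; divide each vector by its sum (default `TRUE`).
#' @return matrix of class `copying_vectors`, one row per cluster, columns
#'   in the same cluster order, with attribute `normalized`.
#' @examples
#' m <- matrix(c(0, 10, 10, 0), 2, 2,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' copying_vectors(m, c(a = "A", b = "B"))
#' @export
copying_vectors <- function(m, clusters, normalize = TRUE) {
  check_coancestry(m)
  cl <- check_assignment(m, clusters)
  labs <- sort(unique(cl))
  if (any(table(cl) < 1)) stop("every cluster must be non-empty",
                               call. = FALSE)
  donor_ind <- outer(cl, labs, "==") * 1          # n x k column aggregator
  agg <- m %*% donor_ind                          # per-recipient, per-cluster
  v <- rowsum(agg, cl) / as.vector(table(cl)[labs])
  v <- v[labs, , drop = FALSE]
  colnames(v) <- labs
  if (normalize) {
    s <- rowSums(v)
    if (any(s == 0)) stop("cannot normalize an all-zero copying vector",
                          call. = FALSE)
    v <- v / s
  }
  structure(v, class = c("copying_vectors", class(v)), normalized = normalize)
}

is_normalized_vectors <- function(v, tol = 1e-9) {
  isTRUE(attr(v, "normalized")) ||
    (all(v >= 0) && max(abs(rowSums(unclass(v)) - 1)) <= tol)
}

#' Principal components of a coancestry or sharing matrix
#'
#' Columns are centred but not variance-scaled, matching the default
#' convention of the painting toolchain; no randomness is involved. The sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive, making scores reproducible across platforms.
#'
#' @param m square matrix with id dimnames (coancestry or binned IBD
#'   sharing).
#' @param n_components number of components, `< nrow(m)`.
#' @return list with `scores` (individuals x components, ordered by
#'   decreasing explained variance), `sdev` (component standard deviations)
#'   and `explained` (per-component variance share).
#' @export
pca_coancestry <- function(m, n_components = 10) {
  check_coancestry(m)
  if (n_components <= 0) stop("n_components must be positive", call. = FALSE)
  if (n_components >= nrow(m))
    stop("n_components must be smaller than the number of individuals",
         call. = FALSE)
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  rownames(scores) <- rownames(m)
  list(scores = scores, sdev = p$sdev,
       explained = p$sdev^2 / sum(p$sdev^2))
}
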