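#' Total variation distance between two cluster copying vectors
#'
#' Cluster distinctness measured on normalised copying vectors. By default
#' this is the metric convention `0.5 * sum(|v_a - v_b|)`, which lies in
#' \[0, 1\]; `raw_l1 = TRUE` returns the unhalved sum of absolute
#' differences. Permutation p-values are identical under either convention.
#'
#' @param v normalised copying vectors ([copying_vectors()] with
#'   `normalize = TRUE`).
#' @param a,b cluster labels (rows of `v`).
#' @param raw_l1 logical; return the raw L1 sum instead of half of it.
#' @return a single number in \[0, 1\] (or \[0, 2\] when `raw_l1`).
#' @examples
#' v <- rbind(A = c(0.6, 0.3, 0.1), B = c(0.2, 0.5, 0.3))
#' attr(v, "normalized") <- TRUE
#' tvd_pair(v, "A", "B")   # 0.4
#' @export
tvd_pair <- function(v, a, b, raw_l1 = FALSE) {
  if (!is_normalized_vectors(v))
    stop("copying vectors must be normalized (rows summing to 1); ",
         "recompute with copying_vectors(..., normalize = TRUE)",
         call. = FALSE)
  if (!all(c(a, b) %in% rownames(v)))
    stop("unknown cluster label(s): ",
         paste(setdiff(c(a, b), rownames(v)), collapse = ", "),
         call. = FALSE)
  l1 <- sum(abs(v[a, ] - v[b, ]))
  if (raw_l1) l1 else l1 / 2
}

# TVD between clusters `a` and `b` for one membership of the pooled a+b
# individuals, with all other clusters' memberships fixed. `others` is the
# n x (k-2) per-recipient aggregate over the unchanged donor clusters,
# `pool_cols` the per-recipient columns of the pooled individuals.
.tvd_for_split <- function(others, pool_cols, in_a) {
  col_a <- rowSums(pool_cols[, in_a, drop = FALSE])
  col_b <- rowSums(pool_cols[, !in_a, drop = FALSE])
  rec_a <- colnames(pool_cols)[in_a]
  rec_b <- colnames(pool_cols)[!in_a]
  va <- c(colMeans(others[rec_a, , drop = FALSE]),
          mean(col_a[rec_a]), mean(col_b[rec_a]))
  vb <- c(colMeans(others[rec_b, , drop = FALSE]),
          mean(col_a[rec_b]), mean(col_b[rec_b]))
  va <- va / sum(va); vb <- vb / sum(vb)
  sum(abs(va - vb)) / 2
}

#' Permutation test of cluster-pair distinctness (TVD)
#'
#' Tests whether clusters `a` and `b` are more distinct than chance by
#' permuting their pooled members into pseudo-clusters of the original
#' sizes, recomputing normalised copying vectors (memberships of all other
#' clusters held fixed — they are unchanged by the permutation) and the TVD
#' between the pseudo-pair. The p-value is the plain ratio
#' `count(permutation TVD >= observed) / n_perm`. When the number of
#' distinct memberships `choose(|a|+|b|, |a|)` is at most `n_perm`, all of
#' them are enumerated exactly and the result is flagged exhaustive (the
#' observed membership is then one of the arrangements, so p > 0). In Monte
#' Carlo mode a zero count is reported as p = 1/n_perm, i.e. "< 1/n_perm",
#' never 0.
#'
#' @param m square coancestry matrix.
#' @param clusters named cluster assignment covering all ids.
#' @param a,b the two cluster labels under test (disjoint by construction).
#' @param n_perm number of permutations (and the exhaustive-enumeration
#'   threshold).
#' @param seed integer seed for Monte Carlo mode.
#' @param method `"auto"` (exhaustive when feasible), `"exhaustive"` or
#'   `"montecarlo"`.
#' @return object of class `tvd_result`: list with `cluster_a`, `cluster_b`,
#'   `tvd`, `n_permutations`, `n_at_least_as_extreme`, `p_value`,
#'   `exhaustive`.
#' @export
tvd_permutation_test <- function(m, clusters, a, b, n_perm = 1000,
                                 seed = 1L,
                                 method = c("auto", "exhaustive",
                                            "montecarlo")) {
  method <- match.arg(method)
  if (n_perm <= 0) stop("n_perm must be positive", call. = FALSE)
  check_coancestry(m)
  cl <- check_assignment(m, clusters)
  if (a == b) stop("clusters a and b must differ", call. = FALSE)
  ids_a <- names(cl)[cl == a]; ids_b <- names(cl)[cl == b]
  if (length(ids_a) < 1 || length(ids_b) < 1)
    stop("both clusters must be non-empty", call. = FALSE)
  pool <- c(ids_a, ids_b)
  size_a <- length(ids_a)

  other_labs <- setdiff(sort(unique(cl)), c(a, b))
  donor_ind <- outer(cl, other_labs, "==") * 1
  others <- m %*% donor_ind                    # n x (k-2), may be 0 columns
  colnames(others) <- other_labs
  pool_cols <- m[, pool, drop = FALSE]

  obs <- .tvd_for_split(others, pool_cols,
                        colnames(pool_cols) %in% ids_a)

  n_arrange <- choose(length(pool), size_a)
  exhaustive <- switch(method,
                       auto = n_arrange <= n_perm,
                       exhaustive = TRUE,
                       montecarlo = FALSE)
  if (exhaustive) {
    splits <- utils::combn(length(pool), size_a)
    stat <- apply(splits, 2, function(ix)
      .tvd_for_split(others, pool_cols, seq_along(pool) %in% ix))
    n_used <- ncol(splits)
  } else {
    set.seed(as.integer(seed))
    stat <- vapply(seq_len(n_perm), function(r) {
      ix <- sample(length(pool), size_a)
      .tvd_for_split(others, pool_cols, seq_along(pool) %in% ix)
    }, numeric(1))
    n_used <- n_perm
  }
  count <- sum(stat >= obs)
  p <- if (count == 0) 1 / n_used else count / n_used
  structure(list(cluster_a = a, cluster_b = b, tvd = obs,
                 n_permutations = n_used, n_at_least_as_extreme = count,
                 p_value = p, exhaustive = exhaustive),
            class = "tvd_result")
}

#' @export
print.tvd_result <- function(x, ...) {
  cat(sprintf("TVD(%s, %s) = %.4f; p %s %.4g (%d/%d %s permutations)\n",
              x$cluster_a, x$cluster_b, x$tvd,
              if (x$n_at_least_as_extreme == 0) "<" else "=",
              x$p_value, x$n_at_least_as_extreme, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte Carlo"))
  invisible(x)
}

#' All-pairs TVD permutation tests
#'
#' Applies [tvd_permutation_test()] to every unordered pair of clusters.
#' P-values are reported raw, without multiplicity correction.
#'
#' @inheritParams tvd_permutation_test
#' @return data frame with one row per unordered pair: cluster_a, cluster_b,
#'   tvd, p_value, n_at_least_as_extreme, n_permutations, exhaustive.
#' @export
tvd_matrix <- function(m, clusters, n_perm = 1000, seed = 1L) {
  cl <- check_assignment(check_coancestry(m), clusters)
  labs <- sort(unique(cl))
  if (length(labs) < 2) stop("need at least two clusters", call. = FALSE)
  pairs <- utils::combn(labs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    r <- tvd_permutation_test(m, clusters, pairs[1, j], pairs[2, j],
                              n_perm = n_perm,
                              seed = (as.double(seed) + j) %% 2147483587)
    data.frame(cluster_a = r$cluster_a, cluster_b = r$cluster_b,
               tvd = r$tvd, p_value = r$p_value,
               n_at_least_as_extreme = r$n_at_least_as_extreme,
               n_permutations = r$n_permutations,
               exhaustive = r$exhaustive, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' TVD merge tree over clusters
#'
#' Builds a binary tree in k-1 steps by successively merging the pair of
#' clusters with the lowest TVD, recomputing copying vectors and TVD over
#' the reduced cluster set after every merge (a merged cluster is the union
#' of its members). Ties are broken by the lexicographic order of the joined
#' label pair. Branch lengths in the Newick output are the merge TVD values.
#'
#' @param m square coancestry matrix.
#' @param clusters named cluster assignment with at least two clusters.
#' @return object of class `tvd_tree`: list with `merges` (data frame step,
#'   left, right, tvd), `newick` (tree string with branch lengths) and
#'   `leaves`.
#' @export
tvd_tree <- function(m, clusters) {
  cl <- check_assignment(check_coancestry(m), clusters)
  labs <- sort(unique(cl))
  if (length(labs) < 2) stop("need at least two clusters", call. = FALSE)
  subtree <- stats::setNames(labs, labs)   # newick fragment per live cluster
  merges <- data.frame(step = integer(), left = character(),
                       right = character(), tvd = double(),
                       stringsAsFactors = FALSE)
  live <- cl
  step <- 0L
  while (length(unique(live)) > 1) {
    v <- copying_vectors(m, live, normalize = TRUE)
    cur <- rownames(v)
    pairs <- utils::combn(cur, 2)
    tv <- apply(pairs, 2, function(p) tvd_pair(v, p[1], p[2]))
    ord <- order(tv, pairs[1, ], pairs[2, ])   # lexicographic tie-break
    best <- ord[1]
    la <- pairs[1, best]; lb <- pairs[2, best]
    step <- step + 1L
    merges <- rbind(merges, data.frame(step = step, left = la, right = lb,
                                       tvd = tv[best],
                                       stringsAsFactors = FALSE))
    new_lab <- paste(sort(c(la, lb)), collapse = "+")
    bl <- format(tv[best], digits = 10, trim = TRUE, scientific = FALSE)
    subtree[new_lab] <- sprintf("(%s:%s,%s:%s)", subtree[la], bl,
                                subtree[lb], bl)
    subtree <- subtree[setdiff(names(subtree), c(la, lb))]
    live[live %in% c(la, lb)] <- new_lab
  }
  structure(list(merges = merges,
                 newick = paste0(subtree[[1]], ";"),
                 leaves = labs),
            class = "tvd_tree")
}

#' @export
print.tvd_tree <- function(x, ...) {
  cat(sprintf("TVD merge tree over %d clusters (%d merges)\n",
              length(x$leaves), nrow(x$merges)))
  print(x$merges, row.names = FALSE)
  invisible(x)
}

#' Write a TVD tree as Newick
#'
#' @param tree a `tvd_tree`.
#' @param path output path.
#' @export
write_tvd_tree <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
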