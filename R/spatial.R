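#' Geographic axis of an ancestry gradient
#'
#' Scans compass bearings from 0 to 359 degrees in 1-degree steps. For each
#' bearing theta the coordinates are projected onto the axis
#' `p = longitude * sin(theta) + latitude * cos(theta)` (planar degree
#' space; `cos_lat = TRUE` multiplies longitudes by cos(mean latitude)
#' first) and the shares are regressed on the projection. The reported
#' bearing maximises the coefficient of determination among bearings with a
#' positive slope — it is the direction of increasing ancestry share (theta
#' and theta + 180 have equal r-squared and opposite slopes).
#'
#' @param values per-individual ancestry share (non-constant).
#' @param coords matrix/data frame with columns longitude, latitude
#'   (degrees).
#' @param cos_lat logical; apply the cos-latitude correction to longitudes.
#' @return object of class `gradient_result`: list with `bearing_deg` (in
#'   \[0, 360)), `r_squared`, `slope`, `p_value` (regression F-test at the
#'   chosen bearing), `compass` (quadrant rendering, display only).
#' @examples
#' set.seed(1)
#' xy <- cbind(longitude = runif(50), latitude = runif(50))
#' v <- xy[, "latitude"]            # due-north gradient
#' gradient_axis_scan(v, xy)$bearing_deg
#' @export
gradient_axis_scan <- function(values, coords, cos_lat = FALSE) {
  values <- as.numeric(values)
  coords <- as.matrix(coords[, c("longitude", "latitude")])
  if (length(values) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant values: gradient axis undefined", call. = FALSE)
  lon <- coords[, 1]
  if (cos_lat) lon <- lon * cos(mean(coords[, 2]) * pi / 180)
  lat <- coords[, 2]
  theta <- (0:359) * pi / 180
  P <- outer(lon, sin(theta)) + outer(lat, cos(theta))   # n x 360
  Pc <- sweep(P, 2, colMeans(P))
  vc <- values - mean(values)
  sxy <- as.vector(crossprod(Pc, vc))
  sxx <- colSums(Pc^2)
  ok <- sxx > 0
  r2 <- rep(0, 360); slope <- rep(0, 360)
  slope[ok] <- sxy[ok] / sxx[ok]
  r2[ok] <- (sxy[ok]^2) / (sxx[ok] * sum(vc^2))
  pos <- which(slope > 0)
  if (length(pos) == 0)
    stop("no bearing with positive slope; values may be constant along all axes",
         call. = FALSE)
  best <- pos[which.max(r2[pos])]
  fit <- stats::lm(values ~ P[, best])
  fstat <- suppressWarnings(summary(fit))$fstatistic  # exact fits are fine
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  bearing <- best - 1L
  structure(list(bearing_deg = bearing, r_squared = r2[best],
                 slope = slope[best], p_value = unname(p),
                 compass = compass_label(bearing)),
            class = "gradient_result")
}

# Quadrant rendering of a compass bearing, e.g. 246 deg -> "S66W".
compass_label <- function(bearing) {
  b <- bearing %% 360
  if (b <= 90) sprintf("N%.0fE", b)
  else if (b <= 180) sprintf("S%.0fE", 180 - b)
  else if (b <= 270) sprintf("S%.0fW", b - 180)
  else sprintf("N%.0fW", 360 - b)
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("Ancestry gradient: bearing %d deg (%s), r2 = %.3f, p = %.3g\n",
              x$bearing_deg, x$compass, x$r_squared, x$p_value))
  invisible(x)
}

spatial_weights <- function(coords, weight_spec = c("inverse_distance",
                                                    "knn", "gaussian"),
                            k = 5) {
  weight_spec <- match.arg(weight_spec)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  if (weight_spec == "inverse_distance") {
    off <- d[upper.tri(d)]
    if (any(off == 0))
      stop("coincident coordinates give infinite inverse-distance weights; ",
           "use weight_spec = \"knn\"", call. = FALSE)
    w <- 1 / d
  } else if (weight_spec == "knn") {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(min(k, n - 1) + 1)]
      w[i, nb] <- 1
    }
    w <- pmax(w, t(w))    # symmetrise so W fits the cross-product form
  } else {
    h <- mean(d[upper.tri(d)])
    w <- exp(-(d / h)^2)
  }
  diag(w) <- 0
  w
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with z the centred
#' values and S0 the total weight. Weights default to inverse Euclidean
#' distance in degree space (zero diagonal); k-nearest-neighbour (k = 5,
#' symmetrised) and Gaussian-kernel alternatives are available. The p-value
#' permutes values over locations and is two-sided: the proportion of
#' permuted I at least as far from the permutation mean as the observed I
#' (a zero count is reported as 1/n_perm).
#'
#' @param values numeric vector (non-constant, n >= 4).
#' @param coords matrix/data frame with columns longitude, latitude.
#' @param weight_spec `"inverse_distance"`, `"knn"` or `"gaussian"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `morans_i`: list with `I`, `expected`
#'   (`-1/(n-1)`), `p_value`, `n_permutations`, `weight_spec`.
#' @export
morans_i <- function(values, coords, weight_spec = "inverse_distance",
                     n_perm = 10000, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant values: Moran's I undefined", call. = FALSE)
  coords <- as.matrix(coords[, c("longitude", "latitude")])
  w <- spatial_weights(coords, weight_spec)
  s0 <- sum(w)
  stat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * sum(w * outer(zc, zc)) / sum(zc^2)
  }
  obs <- stat(values)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(r) stat(sample(values)),
                 numeric(1))
  ctr <- mean(perm)
  count <- sum(abs(perm - ctr) >= abs(obs - ctr))
  p <- if (count == 0) 1 / n_perm else count / n_perm
  structure(list(I = obs, expected = -1 / (n - 1), p_value = p,
                 n_permutations = n_perm, weight_spec = weight_spec),
            class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), p = %.4g (%d permutations, %s weights)\n",
              x$I, x$expected, x$p_value, x$n_permutations, x$weight_spec))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles, with significance from joint
#' row/column permutations of the first matrix. The p-value is one-sided:
#' the proportion of permutations with correlation at least the observed
#' one (a zero count is reported as 1/n_perm).
#'
#' @param value_dist symmetric matrix of pairwise value distances (for
#'   ancestry shares, `abs(outer(share, share, "-"))`), zero diagonal.
#' @param geo_dist symmetric matrix of pairwise geographic distances in the
#'   same individual order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `mantel_result`: list with `r`, `p_value`,
#'   `n_permutations`.
#' @export
mantel_test <- function(value_dist, geo_dist, n_perm = 10000, seed = 1L) {
  value_dist <- as.matrix(value_dist); geo_dist <- as.matrix(geo_dist)
  if (!isTRUE(all.equal(value_dist, t(value_dist))) ||
      !isTRUE(all.equal(geo_dist, t(geo_dist))))
    stop("distance matrices must be symmetric", call. = FALSE)
  if (any(dim(value_dist) != dim(geo_dist)))
    stop("distance matrices must have the same order", call. = FALSE)
  ut <- upper.tri(value_dist)
  if (stats::sd(value_dist[ut]) == 0 || stats::sd(geo_dist[ut]) == 0)
    stop("constant upper triangle: Mantel correlation undefined",
         call. = FALSE)
  obs <- stats::cor(value_dist[ut], geo_dist[ut])
  n <- nrow(value_dist)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(r) {
    ix <- sample(n)
    stats::cor(value_dist[ix, ix][ut], geo_dist[ut])
  }, numeric(1))
  count <- sum(perm >= obs)
  p <- if (count == 0) 1 / n_perm else count / n_perm
  structure(list(r = obs, p_value = p, n_permutations = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, one-sided p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}
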