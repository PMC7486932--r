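test_that("donor copy matrices match hand arithmetic", {
  ids <- c("w", "x", "y", "z")
  groups <- stats::setNames(c("G1", "G1", "G2", "G2"), ids)
  # block-exclusive painting -> identity mixing matrix
  m <- rbind(c(0, 5, 0, 0), c(5, 0, 0, 0), c(0, 0, 0, 4), c(0, 0, 4, 0))
  dimnames(m) <- list(ids, ids)
  X <- donor_copy_matrix(m, groups)
  expect_equal(unclass(X), diag(2), ignore_attr = TRUE)
  # hand fixture: rows normalised, columns grouped, rows averaged
  m2 <- rbind(c(0, 4, 1, 1), c(2, 0, 1, 1), c(1, 1, 0, 2), c(1, 1, 6, 0))
  dimnames(m2) <- list(ids, ids)
  X2 <- donor_copy_matrix(m2, groups,
                          countries = c(G1 = "NL", G2 = "BE"))
  expect_equal(unclass(X2),
               rbind(c(7 / 12, 5 / 12), c(3 / 8, 5 / 8)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(rowSums(X2)), c(1, 1), tolerance = 1e-9)
  expect_error(donor_copy_matrix(m2, groups, countries = c(G1 = "NL")),
               "G2")
})

test_that("NNLS profiles solve constructed inverse problems exactly", {
  X <- donor_matrix5()
  # y equal to one donor profile -> indicator
  p <- nnls_profile(X["S2", ], X)
  expect_equal(p$beta, c(S1 = 0, S2 = 1, S3 = 0, S4 = 0, S5 = 0),
               tolerance = 1e-8)
  # y a two-source mixture -> exact coefficients
  y <- 0.7 * X["S1", ] + 0.3 * X["S3", ]
  p2 <- nnls_profile(y, X)
  expect_equal(p2$beta, c(S1 = 0.7, S2 = 0, S3 = 0.3, S4 = 0, S5 = 0),
               tolerance = 1e-8)
  # identity basis returns the target itself
  I5 <- diag(5); dimnames(I5) <- dimnames(X)
  yy <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  expect_equal(unname(nnls_profile(yy, I5)$beta), yy, tolerance = 1e-10)
  # renormalisation and penalty-row formulations agree
  p3 <- nnls_profile(y, X, method = "penalty")
  expect_equal(p3$beta, p2$beta, tolerance = 1e-3)
  expect_error(nnls_profile(c(0.5, 0.5, 0, 0, 0.2), X), "sum 1")
})

test_that("prune-and-refit drops weak groups and renormalises", {
  X <- donor_matrix5()
  y <- 0.96 * X["S1", ] + 0.04 * X["S2", ]
  p <- nnls_profile(y, X)
  pruned <- prune_and_refit(p, X, y, threshold = 0.05)
  expect_equal(pruned$beta[["S1"]], 1)
  expect_equal(sum(pruned$beta), 1)
  expect_equal(pruned$retained, "S1")
  # nothing below threshold -> unchanged; threshold 0 -> identity
  y2 <- 0.5 * X["S1", ] + 0.5 * X["S2", ]
  p2 <- nnls_profile(y2, X)
  expect_equal(prune_and_refit(p2, X, y2, 0.05)$beta, p2$beta)
  expect_identical(prune_and_refit(p2, X, y2, 0), p2)
  expect_error(prune_and_refit(p2, X, y2, 1.2), "threshold")
})

test_that("country aggregation conserves the unit total", {
  beta <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
  prof <- structure(list(beta = beta, retained = names(beta),
                         country = NULL), class = "ancestry_profile")
  shares <- aggregate_by_country(prof,
                                 c(g1 = "A", g2 = "A", g3 = "B"))
  expect_equal(shares, c(A = 0.8, B = 0.2))
  # order invariance under permuting groups
  prof2 <- prof; prof2$beta <- beta[c(3, 1, 2)]
  expect_equal(aggregate_by_country(prof2,
                                    c(g1 = "A", g2 = "A", g3 = "B")),
               shares)
  expect_equal(sum(shares), 1)
  prof3 <- prof
  expect_equal(aggregate_by_country(prof3,
                                    c(g1 = "A", g2 = "A", g3 = "A")),
               c(A = 1))
  expect_error(aggregate_by_country(prof, c(g1 = "A", g2 = "A")), "g3")
})

test_that("noiseless targets are recovered exactly through the full fit", {
  cfg <- ancestry_config(seed = 71, noise_sd = 0)
  X <- donor_matrix5()
  sim <- simulate_ancestry_targets(cfg, X)
  est <- ancestry_profiles(sim$targets, X)
  expect_lt(max(abs(est - sim$truth)), 1e-8)
})

test_that("gradient axis scan recovers injected bearings", {
  set.seed(5)
  n <- 60
  coords <- cbind(longitude = runif(n, 4, 7), latitude = runif(n, 51, 54))
  proj <- coords[, 1] * sin(73 * pi / 180) + coords[, 2] * cos(73 * pi / 180)
  v <- 0.2 + 0.05 * proj
  g <- gradient_axis_scan(v, coords)
  expect_equal(g$bearing_deg, 73)
  expect_equal(g$r_squared, 1, tolerance = 1e-9)
  expect_gt(g$slope, 0)
  # slope-free values error out
  expect_error(gradient_axis_scan(rep(1, n), coords), "constant")
})

test_that("recovered bearings are equivariant under coordinate rotation", {
  set.seed(6)
  n <- 80
  coords <- cbind(longitude = runif(n, -1, 1), latitude = runif(n, -1, 1))
  proj <- coords[, 1] * sin(30 * pi / 180) + coords[, 2] * cos(30 * pi / 180)
  v <- 0.3 + 0.1 * proj
  base <- gradient_axis_scan(v, coords)$bearing_deg
  for (phi in c(30, 121, 270)) {
    a <- phi * pi / 180
    rot <- coords %*% rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    colnames(rot) <- c("longitude", "latitude")
    got <- gradient_axis_scan(v, rot)$bearing_deg
    expect_lte(min(abs(got - (base + phi) %% 360),
                   360 - abs(got - (base + phi) %% 360)), 1)
  }
})

test_that("under pure noise the best bearing has no directional preference", {
  set.seed(7)
  n <- 20
  coords <- cbind(longitude = runif(n), latitude = runif(n))
  bearings <- vapply(1:200, function(s) {
    set.seed(s)
    gradient_axis_scan(stats::rnorm(n), coords)$bearing_deg
  }, numeric(1))
  sector <- floor(bearings / 45)
  counts <- table(factor(sector, levels = 0:7))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("Moran's I matches the direct formula and detects gradients", {
  # 2x2 checkerboard: negative autocorrelation, value cross-checked
  coords <- cbind(longitude = c(0, 1, 0, 1), latitude = c(0, 0, 1, 1))
  v <- c(1, -1, -1, 1)
  r <- morans_i(v, coords, n_perm = 100, seed = 1)
  d <- as.matrix(stats::dist(coords)); w <- 1 / d; diag(w) <- 0
  direct <- (4 / sum(w)) * sum(w * outer(v, v)) / sum(v^2)
  expect_equal(r$I, direct, tolerance = 1e-12)
  expect_lt(r$I, 0)
  skip_if_not_installed("ape")
  expect_equal(r$I, ape::Moran.I(v, w)$observed, tolerance = 1e-10)
})

test_that("a smooth gradient on a grid is strongly autocorrelated", {
  grid <- expand.grid(longitude = 0:4, latitude = 0:4)
  v <- grid$latitude + 0.05 * seq_len(25)   # north-south trend
  r <- morans_i(v, grid, n_perm = 1e4, seed = 2)
  expect_gt(r$I, 0)
  expect_lte(r$p_value, 0.001)
})

test_that("degenerate spatial inputs raise informative errors", {
  coords <- cbind(longitude = c(0, 0, 1, 1), latitude = c(0, 0, 1, 1))
  expect_error(morans_i(c(1, 2, 3, 4), coords), "knn")
  r <- morans_i(c(1, 2, 3, 4), coords, weight_spec = "knn", n_perm = 50,
                seed = 1)
  expect_true(is.finite(r$I))
  expect_error(morans_i(rep(1, 4),
                        cbind(longitude = 1:4, latitude = 1:4)),
               "constant")
})

test_that("the Mantel statistic behaves as a permutation correlation", {
  set.seed(8)
  xy <- cbind(longitude = runif(10), latitude = runif(10))
  gd <- as.matrix(stats::dist(xy))
  # identical matrices: r = 1, p at the 1/n_perm floor
  r <- mantel_test(gd, gd, n_perm = 999, seed = 1)
  expect_equal(r$r, 1)
  expect_lte(r$p_value, 1 / 999 + 1e-12)
  # invariance under a simultaneous row/column permutation of both
  u <- runif(10)
  vd <- abs(outer(u, u, "-"))
  ix <- sample(10)
  r1 <- mantel_test(vd, gd, n_perm = 99, seed = 2)
  r2 <- mantel_test(vd[ix, ix], gd[ix, ix], n_perm = 99, seed = 2)
  expect_equal(r1$r, r2$r)
  expect_error(mantel_test(matrix(0, 10, 10), gd), "constant")
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(stats::as.dist(vd), stats::as.dist(gd),
                      permutations = 99)
  expect_equal(r1$r, unname(vg$statistic), tolerance = 1e-10)
})

test_that("Mantel p-values are calibrated under independence", {
  pvals <- vapply(1:200, function(s) {
    set.seed(s)
    a <- as.matrix(stats::dist(runif(8)))
    b <- as.matrix(stats::dist(runif(8)))
    mantel_test(a, b, n_perm = 199, seed = s + 1000)$p_value
  }, numeric(1))
  # discrete permutation p-values tie; the KS distance is still the check
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
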