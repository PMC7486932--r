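test_that("TVD pair values match hand arithmetic and the metric bounds", {
  v <- rbind(A = c(0.6, 0.3, 0.1), B = c(0.2, 0.5, 0.3))
  colnames(v) <- paste0("C", 1:3)
  attr(v, "normalized") <- TRUE
  expect_equal(tvd_pair(v, "A", "B"), 0.4)          # 0.5 * (0.4+0.2+0.2)
  expect_equal(tvd_pair(v, "A", "B", raw_l1 = TRUE), 0.8)
  expect_equal(tvd_pair(v, "A", "A"), 0)
  d <- rbind(A = c(1, 0), B = c(0, 1))
  attr(d, "normalized") <- TRUE
  expect_equal(tvd_pair(d, "A", "B"), 1)            # disjoint supports
  raw <- rbind(A = c(2, 3), B = c(1, 1))
  expect_error(tvd_pair(raw, "A", "B"), "normalize")
})

test_that("TVD is a metric on normalised vectors", {
  for (s in 1:20) {
    v <- random_simplex_rows(3, 6, seed = s)
    ab <- tvd_pair(v, "C1", "C2")
    bc <- tvd_pair(v, "C2", "C3")
    ac <- tvd_pair(v, "C1", "C3")
    expect_equal(ab, tvd_pair(v, "C2", "C1"))
    expect_lte(ac, ab + bc + 1e-12)
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
})

test_that("singleton pair permutation is exhaustive with p = 1", {
  m <- matrix(c(0, 2, 5, 3, 0, 1, 4, 6, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  r <- tvd_permutation_test(m, c(a = "A", b = "B", c = "C"), "A", "B",
                            n_perm = 100)
  expect_true(r$exhaustive)
  expect_equal(r$n_permutations, 2)
  expect_equal(r$p_value, 1)       # both arrangements give the same TVD
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
  fx <- crafted_six()
  ex <- tvd_permutation_test(fx$m, fx$clusters, "A", "B", n_perm = 100,
                             method = "exhaustive")
  expect_true(ex$exhaustive)
  expect_equal(ex$n_permutations, 20)
  mc <- tvd_permutation_test(fx$m, fx$clusters, "A", "B", n_perm = 1e4,
                             seed = 2, method = "montecarlo")
  se <- sqrt(ex$p_value * (1 - ex$p_value) / mc$n_permutations)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1e-12)
})

test_that("permutation p-values are invariant to relabeling and pair order", {
  fx <- crafted_six()
  r1 <- tvd_permutation_test(fx$m, fx$clusters, "A", "B", n_perm = 100)
  r2 <- tvd_permutation_test(fx$m, fx$clusters, "B", "A", n_perm = 100)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$tvd, r2$tvd)
  # renaming individuals (consistently) changes nothing
  new_ids <- paste0("x", 1:6)
  m2 <- fx$m; dimnames(m2) <- list(new_ids, new_ids)
  cl2 <- stats::setNames(unname(fx$clusters), new_ids)
  r3 <- tvd_permutation_test(m2, cl2, "A", "B", n_perm = 100)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$tvd, r1$tvd)
})

test_that("all-pairs TVD covers every unordered pair, raw p-values", {
  coh <- generate_cohort(structured_config(seed = 41, n_per_deme = 4))
  cl <- stats::setNames(coh$individuals$deme, coh$individuals$id)
  tab <- tvd_matrix(coh$coancestry, cl, n_perm = 50, seed = 1)
  expect_equal(nrow(tab), 3)          # 3 clusters -> 3 unordered pairs
  expect_true(all(tab$tvd >= 0 & tab$tvd <= 1))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("strong structure yields p <= 0.001 for every cluster pair", {
  coh <- generate_cohort(structured_config(seed = 42, n_per_deme = 10))
  cl <- stats::setNames(coh$individuals$deme, coh$individuals$id)
  tab <- tvd_matrix(coh$coancestry, cl, n_perm = 1000, seed = 3)
  expect_true(all(tab$p_value <= 0.001))
})

test_that("the TVD tree merges lowest pairs first and preserves leaves", {
  # k = 2: a single merge at exactly the pairwise TVD
  coh <- generate_cohort(null_config(seed = 55))
  cl <- stats::setNames(coh$individuals$deme, coh$individuals$id)
  tr2 <- tvd_tree(coh$coancestry, cl)
  expect_equal(nrow(tr2$merges), 1)
  expect_equal(tr2$merges$tvd,
               tvd_pair(copying_vectors(coh$coancestry, cl),
                        "deme1", "deme2"))
  # 4 clusters: replay the k-1 steps with an independent plain-loop oracle
  coh4 <- generate_cohort(scenario_config(n_demes = 4,
                                          deme_centers = list(c(4.5, 51.5),
                                                              c(6, 51.8),
                                                              c(4.8, 52.8),
                                                              c(6.3, 53.1)),
                                          n_per_deme = 4, kappa = 12,
                                          lambda_within = 0,
                                          lambda_between = 0, seed = 44))
  cl4 <- stats::setNames(coh4$individuals$deme, coh4$individuals$id)
  tree <- tvd_tree(coh4$coancestry, cl4)
  expect_equal(nrow(tree$merges), 3)
  expect_setequal(tree$leaves, unique(cl4))
  expect_true(all(tree$merges$tvd >= 0))

  oracle_vectors <- function(m, assign) {
    labs <- sort(unique(assign))
    v <- matrix(0, length(labs), length(labs),
                dimnames = list(labs, labs))
    for (A in labs) {
      rec <- names(assign)[assign == A]
      for (k in labs) {
        don <- names(assign)[assign == k]
        v[A, k] <- mean(sapply(rec, function(i) sum(m[i, don])))
      }
    }
    v / rowSums(v)
  }
  assign <- cl4
  for (s in seq_len(3)) {
    labs <- sort(unique(assign))
    best <- NULL
    for (i in seq_along(labs)) for (j in seq_along(labs)) if (i < j) {
      v <- oracle_vectors(coh4$coancestry, assign)
      tv <- sum(abs(v[labs[i], ] - v[labs[j], ])) / 2
      if (is.null(best) || tv < best$tv)
        best <- list(a = labs[i], b = labs[j], tv = tv)
    }
    expect_equal(tree$merges$left[s], best$a)
    expect_equal(tree$merges$right[s], best$b)
    expect_equal(tree$merges$tvd[s], best$tv)
    assign[assign %in% c(best$a, best$b)] <-
      paste(sort(c(best$a, best$b)), collapse = "+")
  }
  # the Newick string is a valid tree over the same leaves
  skip_if_not_installed("ape")
  phy <- ape::read.tree(text = tree$newick)
  expect_setequal(phy$tip.label, tree$leaves)
})

test_that("Nagelkerke R2 matches an independent likelihood maximisation", {
  # constant covariate explains nothing
  y <- rep(c(0, 1), each = 5)
  expect_equal(nagelkerke_r2(y, matrix(1, 10, 1))$r2, 0, tolerance = 1e-8)
  # 10-row worked fixture against a direct optimiser of the log-likelihood
  x <- matrix(c(0.3, -1.2, 0.8, 2.0, -0.5, 1.4, -0.9, 0.1, 1.9, -1.7),
              ncol = 1, dimnames = list(NULL, "PC1"))
  y <- c(1, 0, 0, 1, 0, 1, 0, 0, 1, 0)   # classes overlap on x
  loglik <- function(par, xx) {
    eta <- par[1] + if (length(par) > 1) xx %*% par[-1] else 0
    sum(y * eta - log(1 + exp(eta)))
  }
  l0 <- stats::optimize(function(b) loglik(b, NULL), c(-10, 10),
                        maximum = TRUE)$objective
  l1 <- stats::optim(c(0, 0), function(p) -loglik(p, x),
                     method = "BFGS")$value * -1
  n <- length(y)
  expected <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
  got <- nagelkerke_r2(y, x)
  expect_equal(got$r2, expected, tolerance = 1e-6)
  expect_equal(got$table$marginal_r2, got$table$cumulative_r2)
})

test_that("structure PCs explain phenotype only under stratification", {
  # fixed structured cohort, phenotype redrawn under the null across seeds
  base <- scenario_config(n_demes = 2,
                          deme_centers = list(c(5, 51.5), c(6, 53)),
                          n_per_deme = 300, kappa = 8, lambda_within = 0,
                          lambda_between = 0, seed = 60)
  coh <- generate_cohort(base)
  pcs <- pca_coancestry(coh$coancestry, n_components = 3)$scores
  r2_null <- vapply(1:20, function(s) {
    cfg <- base; cfg$seed <- 7000 + s
    ph <- simulate_phenotype(cfg, coh$individuals)
    nagelkerke_r2(ph, pcs)$r2
  }, numeric(1))
  expect_gte(mean(r2_null < 0.02), 0.9)
  # deme-stratified phenotype: PC1 captures the confounding
  cfg_s <- base
  cfg_s$phenotype_intercepts <- c(-2, 2)
  ph <- simulate_phenotype(cfg_s, coh$individuals)
  expect_gt(nagelkerke_r2(ph, pcs[, 1, drop = FALSE])$r2, 0.1)
})

test_that("perfect separation is flagged and capped", {
  y <- rep(c(0, 1), each = 10)
  x <- matrix(y * 2 - 1 + seq(-0.01, 0.01, length.out = 20), ncol = 1)
  expect_warning(r <- nagelkerke_r2(y, x), "separation")
  expect_lte(r$r2, 1)
  expect_true(r$separation)
})
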