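# Shared fixtures for the structkit test suite. Everything is built in code;
# no binary fixtures.

# Exchangeable ("no structure") cohort: no within-deme boost and a spatial
# decay range so large that every recipient row has the same Dirichlet
# expectation, so permuting individuals between demes is a true null.
null_config <- function(seed, n_per_deme = 5) {
  scenario_config(n_demes = 2,
                  deme_centers = list(c(5, 51.5), c(6, 53)),
                  n_per_deme = n_per_deme,
                  kappa = 0, rho = 1e6, alpha = 50,
                  lambda_within = 1, lambda_between = 1,
                  seed = seed)
}

# Strongly structured small cohort (clean deme blocks in coancestry).
structured_config <- function(seed, n_per_deme = 10) {
  scenario_config(kappa = 50, rho = 0.5, alpha = 1000,
                  n_per_deme = n_per_deme, seed = seed)
}

# Five-source gradient specification used for the ancestry recovery suite:
# two antipodal pairs (slopes cancel, so raw shares sum to 1 exactly) plus a
# flat background source.
gradient_specs5 <- function(noise_sd = 0.005) {
  data.frame(source = paste0("S", 1:5),
             bearing_deg = c(73, 253, 0, 180, 0),
             intercept = c(0.25, 0.25, 0.2, 0.2, 0.1),
             slope_per_deg = c(0.05, 0.05, 0.04, 0.04, 0),
             noise_sd = noise_sd,
             stringsAsFactors = FALSE)
}

# 200-individual, four-deme scenario for ancestry recovery.
ancestry_config <- function(seed, noise_sd = 0.005) {
  scenario_config(n_demes = 4,
                  deme_centers = list(c(4.5, 51.5), c(6.0, 51.8),
                                      c(4.8, 52.8), c(6.3, 53.1)),
                  n_per_deme = 50, deme_scatter_sd = 0.4,
                  gradient_specs = gradient_specs5(noise_sd),
                  seed = seed)
}

# Strongly distinct donor groups: near-diagonal copying matrix.
donor_matrix5 <- function() {
  g <- paste0("S", 1:5)
  X <- matrix(0.05 / 5, 5, 5, dimnames = list(g, g))
  diag(X) <- diag(X) + 0.95
  X
}

# Hand-computed 4x4 coancestry fixture: clusters A = {a, b}, B = {c, d}.
# Copying vectors: A -> (3.5, 6.5) -> (0.35, 0.65); B -> (8, 2) -> (0.8, 0.2)
# and TVD(A, B) = 0.45.
hand_matrix4 <- function() {
  m <- rbind(a = c(0, 3, 5, 2),
             b = c(4, 0, 1, 5),
             c = c(2, 6, 0, 2),
             d = c(7, 1, 2, 0))
  colnames(m) <- rownames(m)
  m
}

hand_clusters4 <- c(a = "A", b = "A", c = "B2", d = "B2")

# A normalised random copying-vector matrix (rows on the simplex).
random_simplex_rows <- function(k, g, seed) {
  set.seed(seed)
  v <- matrix(stats::rgamma(k * g, 1), k, g)
  v <- v / rowSums(v)
  dimnames(v) <- list(paste0("C", seq_len(k)), paste0("C", seq_len(g)))
  attr(v, "normalized") <- TRUE
  v
}

# Small crafted coancestry matrix over two labelled triples, for the
# exhaustive-vs-Monte-Carlo permutation comparison.
crafted_six <- function(seed = 4) {
  set.seed(seed)
  ids <- paste0("s", 1:6)
  m <- matrix(runif(36, 1, 10), 6, 6, dimnames = list(ids, ids))
  diag(m) <- 0
  list(m = m, clusters = stats::setNames(rep(c("A", "B"), each = 3), ids))
}
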