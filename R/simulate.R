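#' Generate a synthetic structured cohort
#'
#' Draws every component of a cohort from a [scenario_config()]: individual
#' geography scattered around deme centres, a block-structured coancestry
#' (chunklength) matrix with spatial decay and Dirichlet row noise, pairwise
#' IBD segments with deme-dependent coalescence-time distributions, target
#' copying vectors following linear spatial ancestry gradients with known
#' truth, and a deme-stratified binary phenotype. Each component uses its own
#' seed substream, so the same configuration and seed always reproduce the
#' identical cohort.
#'
#' @param config a `scenario_config`.
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `individuals` (data frame: id, deme, longitude, latitude, town,
#'   province), `coancestry` (square matrix, recipients x donors, rows
#'   summing to `genome_length_cM`, zero diagonal), `ibd` (segment data
#'   frame, see [read_ibd()]), `donor_matrix` (the donor-group copying
#'   matrix used for ancestry targets), `targets` (per-individual copying
#'   vectors over sources), `true_ancestry` (per-individual true mixture
#'   shares, rows summing to 1), and `phenotype` (named 0/1 vector).
#' @examples
#' cfg <- scenario_config(n_demes = 2,
#'                        deme_centers = list(c(5, 51.5), c(6, 53)),
#'                        n_per_deme = 4, lambda_within = 2,
#'                        lambda_between = 2, seed = 3)
#' coh <- generate_cohort(cfg)
#' rowSums(coh$coancestry)[1:2]
#' @export
generate_cohort <- function(config) {
  validate_scenario_config(config)
  ind <- make_individuals(config)
  coan <- simulate_coancestry(config, ind)
  ibd <- simulate_cohort_ibd(config, ind)
  X <- default_donor_matrix(config)
  anc <- simulate_ancestry_targets(config, X, individuals = ind)
  phen <- simulate_phenotype(config, ind)
  out <- list(individuals = ind, coancestry = coan, ibd = ibd,
              donor_matrix = X, targets = anc$targets,
              true_ancestry = anc$truth, phenotype = phen,
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals in %d demes, %d IBD segments\n",
              nrow(x$individuals), x$config$n_demes, nrow(x$ibd)))
  invisible(x)
}

# Individual ids, deme labels and planar lon/lat coordinates (geography
# substream). Town/province columns exist only to satisfy the geography
# table layout.
make_individuals <- function(config) {
  set.seed(substream_seed(config$seed, "geography"))
  n <- config$n_demes * config$n_per_deme
  deme <- rep(paste0("deme", seq_len(config$n_demes)),
              each = config$n_per_deme)
  ctr <- do.call(rbind, lapply(config$deme_centers, as.numeric))
  idx <- rep(seq_len(config$n_demes), each = config$n_per_deme)
  lon <- ctr[idx, 1] + stats::rnorm(n, 0, config$deme_scatter_sd)
  lat <- ctr[idx, 2] + stats::rnorm(n, 0, config$deme_scatter_sd)
  data.frame(id = sprintf("ind%04d", seq_len(n)),
             deme = deme, longitude = lon, latitude = lat,
             town = sprintf("town_%s_%02d", deme,
                            rep(seq_len(config$n_per_deme), config$n_demes)),
             province = deme, stringsAsFactors = FALSE)
}

# Coancestry rows: expectation exp(-d_ij/rho) * (1 + kappa [same deme]) over
# donors j != i, realised as a Dirichlet draw with concentration alpha * p
# and scaled to the genome length. Diagonal is exactly zero (no self-copying).
simulate_coancestry <- function(config, individuals) {
  set.seed(substream_seed(config$seed, "coancestry"))
  n <- nrow(individuals)
  d <- as.matrix(stats::dist(individuals[, c("longitude", "latitude")]))
  same <- outer(individuals$deme, individuals$deme, "==")
  E <- exp(-d / config$rho) * (1 + config$kappa * same)
  diag(E) <- 0
  m <- matrix(0, n, n, dimnames = list(individuals$id, individuals$id))
  for (i in seq_len(n)) {
    p <- E[i, -i] / sum(E[i, -i])
    g <- stats::rgamma(n - 1, shape = config$alpha * p, rate = 1)
    if (sum(g) == 0) g <- p   # guard against all-zero gamma draws
    m[i, -i] <- config$genome_length_cM * g / sum(g)
  }
  m
}

#' Simulate IBD segments for a set of pairs
#'
#' Per pair the number of segment events is Poisson(`lambda`); each event has
#' a coalescence time `t` drawn from the class Gamma distribution (structured
#' mode) or Uniform(0, `T_max`) (validation mode), and a segment length in cM
#' drawn as Erlang(2, rate t/50) — the length law under which the closed-form
#' expected segment age [expected_tmrca()] is exact. Segments shorter than
#' the detection floor `min_length_cM` are discarded. Surviving segments are
#' placed on a chromosome with probability proportional to map length, with a
#' uniform start position, converting 1 cM = 1 Mb for base-pair coordinates.
#'
#' @param config a `scenario_config`.
#' @param pair_class `"within"` or `"between"`: chooses the event rate and
#'   coalescence-time distribution.
#' @param n_pairs number of pairs to simulate.
#' @param ids optional 2-column character matrix of pair member ids (one row
#'   per pair); autogenerated placeholder ids otherwise.
#' @param validation logical; if `TRUE`, coalescence times are drawn
#'   Uniform(0, `T_max`) instead of the class Gamma (used to validate the
#'   closed-form dating under its own assumptions). Never mixed with the
#'   structured Gamma mode.
#' @param T_max upper bound of the uniform coalescence time (generations);
#'   required in validation mode.
#' @param seed optional integer; defaults to the config's IBD substream.
#' @return an IBD segment data frame (columns id1, id2, chromosome,
#'   start_bp, end_bp, length_cM, lod, tmrca_gen) with canonical id1 < id2.
#' @export
simulate_ibd_pairs <- function(config, pair_class = c("within", "between"),
                               n_pairs, ids = NULL, validation = FALSE,
                               T_max = NULL, seed = NULL) {
  pair_class <- match.arg(pair_class)
  validate_scenario_config(config)
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (is.null(ids)) {
    ids <- cbind(sprintf("pair%05d_a", seq_len(n_pairs)),
                 sprintf("pair%05d_b", seq_len(n_pairs)))
  }
  if (nrow(ids) != n_pairs) stop("ids must have one row per pair",
                                 call. = FALSE)
  if (is.null(seed)) seed <- substream_seed(config$seed, "ibd")
  set.seed(seed)
  lambda <- switch(pair_class, within = config$lambda_within,
                   between = config$lambda_between)
  gp <- switch(pair_class, within = config$tmrca_within,
               between = config$tmrca_between)
  m <- stats::rpois(n_pairs, lambda)
  total <- sum(m)
  if (total == 0) return(empty_ibd())
  pair_idx <- rep(seq_len(n_pairs), m)
  t <- if (validation) {
    if (is.null(T_max) || T_max <= 0)
      stop("validation mode requires a positive T_max", call. = FALSE)
    stats::runif(total, 0, T_max)
  } else {
    stats::rgamma(total, shape = gp[1], scale = gp[2])
  }
  len <- stats::rgamma(total, shape = 2, rate = t / 50)
  keep <- len >= config$min_length_cM
  if (!any(keep)) return(empty_ibd())
  pair_idx <- pair_idx[keep]; t <- t[keep]; len <- len[keep]
  place <- place_segments(len, config$genome_length_cM)
  seg <- data.frame(id1 = ids[pair_idx, 1], id2 = ids[pair_idx, 2],
                    chromosome = place$chromosome,
                    start_bp = place$start_bp, end_bp = place$end_bp,
                    length_cM = len, lod = 10.0, tmrca_gen = t,
                    stringsAsFactors = FALSE)
  canonicalize_pairs(seg)
}

empty_ibd <- function() {
  data.frame(id1 = character(), id2 = character(), chromosome = integer(),
             start_bp = double(), end_bp = double(), length_cM = double(),
             lod = double(), tmrca_gen = double(), stringsAsFactors = FALSE)
}

# Chromosome drawn proportional to map length among chromosomes long enough
# to hold the segment; uniform start in cM, 1 cM = 1 Mb in bp coordinates.
place_segments <- function(len, genome_length_cM) {
  chr_cM <- .AUTOSOME_CM * genome_length_cM / sum(.AUTOSOME_CM)
  n <- length(len)
  chrom <- integer(n); start_cM <- double(n)
  longest <- which.max(chr_cM)
  for (k in seq_len(n)) {
    ok <- which(chr_cM >= len[k])
    if (length(ok) == 0) {           # longer than any chromosome: pin + clip
      chrom[k] <- longest
      start_cM[k] <- 0
      len[k] <- chr_cM[longest]
    } else {
      chrom[k] <- if (length(ok) == 1) ok else
        sample(ok, 1, prob = chr_cM[ok])
      start_cM[k] <- stats::runif(1, 0, chr_cM[chrom[k]] - len[k])
    }
  }
  list(chromosome = chrom,
       start_bp = round(start_cM * 1e6),
       end_bp = round((start_cM + len) * 1e6))
}

canonicalize_pairs <- function(seg) {
  swap <- seg$id1 > seg$id2
  if (any(swap)) {
    tmp <- seg$id1[swap]; seg$id1[swap] <- seg$id2[swap]; seg$id2[swap] <- tmp
  }
  if (any(seg$id1 == seg$id2))
    stop("self-pairs are not allowed in IBD segment sets", call. = FALSE)
  rownames(seg) <- NULL
  seg
}

# All-pairs IBD for a cohort: one within-class and one between-class batch
# on the IBD substream, mapped onto the actual individual pairs.
simulate_cohort_ibd <- function(config, individuals) {
  pairs <- utils::combn(individuals$id, 2)
  deme <- stats::setNames(individuals$deme, individuals$id)
  within <- deme[pairs[1, ]] == deme[pairs[2, ]]
  base <- substream_seed(config$seed, "ibd")
  segs <- list()
  if (any(within) && config$lambda_within > 0)
    segs$w <- simulate_ibd_pairs(config, "within", sum(within),
                                 ids = t(pairs[, within, drop = FALSE]),
                                 seed = base)
  if (any(!within) && config$lambda_between > 0)
    segs$b <- simulate_ibd_pairs(config, "between", sum(!within),
                                 ids = t(pairs[, !within, drop = FALSE]),
                                 seed = (base + 1) %% 2147483587)
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- empty_ibd()
  rownames(out) <- NULL
  out
}

# Default donor-group copying matrix for ancestry targets: diagonally
# dominant so sources are distinguishable but correlated, as painted donor
# groups are.
default_donor_matrix <- function(config) {
  G <- nrow(config$gradient_specs)
  X <- matrix(0.3 / G, G, G,
              dimnames = list(config$gradient_specs$source,
                              config$gradient_specs$source))
  diag(X) <- diag(X) + 0.7
  X
}

#' Simulate ancestry-profile targets with known truth
#'
#' For each individual the true share of source g follows
#' `intercept_g + slope_g * projection` of the individual's centred
#' coordinates on the source's compass bearing, clipped at zero and
#' renormalised to sum to 1. The observed target copying vector is the
#' truth mixed through the donor copying matrix, `Y = beta %*% X`, plus
#' optional zero-mean Gaussian noise (clipped at zero, renormalised).
#' Projections are centred at the cohort centroid so intercepts are mean
#' shares at the centroid.
#'
#' @param config a `scenario_config` (the `gradient_specs` field drives the
#'   truth; its `noise_sd` column sets the target noise).
#' @param donor_matrix G x G donor-group copying matrix with rows summing
#'   to 1; must have full rank.
#' @param individuals optional individual table (id, longitude, latitude);
#'   regenerated from the geography substream when omitted.
#' @return list with `targets` (n x G matrix of observed copying vectors,
#'   rows summing to 1) and `truth` (n x G matrix of true shares, rows
#'   summing to 1).
#' @export
simulate_ancestry_targets <- function(config, donor_matrix,
                                      individuals = NULL) {
  validate_scenario_config(config)
  gs <- config$gradient_specs
  G <- nrow(gs)
  if (!is.matrix(donor_matrix) || nrow(donor_matrix) != G ||
      ncol(donor_matrix) != G)
    stop("donor_matrix must be a square matrix with one row per source",
         call. = FALSE)
  if (qr(donor_matrix)$rank < G)
    stop("donor_matrix is rank-deficient; sources are not distinguishable",
         call. = FALSE)
  if (max(abs(rowSums(donor_matrix) - 1)) > 1e-8)
    stop("donor_matrix rows must sum to 1", call. = FALSE)
  if (is.null(individuals)) individuals <- make_individuals(config)
  set.seed(substream_seed(config$seed, "ancestry"))
  lon <- individuals$longitude - mean(individuals$longitude)
  lat <- individuals$latitude - mean(individuals$latitude)
  theta <- gs$bearing_deg * pi / 180
  proj <- outer(lon, sin(theta)) + outer(lat, cos(theta))   # n x G
  raw <- sweep(sweep(proj, 2, gs$slope_per_deg, "*"), 2, gs$intercept, "+")
  raw[raw < 0] <- 0
  if (any(rowSums(raw) == 0))
    stop("gradient specs give an all-zero share row; increase intercepts",
         call. = FALSE)
  truth <- raw / rowSums(raw)
  targets <- truth %*% donor_matrix
  if (any(gs$noise_sd > 0)) {
    noise <- matrix(stats::rnorm(length(targets), 0,
                                 rep(gs$noise_sd, each = nrow(targets))),
                    nrow = nrow(targets))
    targets <- targets + noise
    targets[targets < 0] <- 0
    targets <- targets / rowSums(targets)
  }
  dimnames(truth) <- dimnames(targets) <- list(individuals$id, gs$source)
  list(targets = targets, truth = truth)
}

#' Simulate a deme-stratified binary phenotype
#'
#' Case probability for an individual in deme d is
#' `plogis(phenotype_baseline + phenotype_intercepts[d])`; draws use the
#' phenotype seed substream, so they are deterministic given the config.
#'
#' @param config a `scenario_config`.
#' @param individuals optional individual table; regenerated when omitted.
#' @return named integer vector of 0/1 labels (1 = case).
#' @export
simulate_phenotype <- function(config, individuals = NULL) {
  validate_scenario_config(config)
  if (is.null(individuals)) individuals <- make_individuals(config)
  set.seed(substream_seed(config$seed, "phenotype"))
  d <- match(individuals$deme, paste0("deme", seq_len(config$n_demes)))
  p <- stats::plogis(config$phenotype_baseline +
                       config$phenotype_intercepts[d])
  stats::setNames(stats::rbinom(nrow(individuals), 1, p), individuals$id)
}

#' Monte-Carlo oracle for the expected age of length-filtered IBD segments
#'
#' Draws coalescence times t uniformly on (0, `T_max`) and segment lengths
#' l ~ Erlang(2, rate t/50 per cM), then averages t over draws whose length
#' falls in [`L1`, `L2`). As `T_max` and the number of draws grow this must
#' approach the closed form `75 (1/L1 + 1/L2)` generations returned by
#' [expected_tmrca()]; it provides an independent simulation check of that
#' formula.
#'
#' @param L1,L2 bin bounds in cM, `0 < L1 < L2`.
#' @param n_draws number of Monte-Carlo draws.
#' @param T_max upper bound of the uniform time prior (generations); must be
#'   at least `100 * 50 / L1` or the truncation visibly biases the mean
#'   (error). Defaults to exactly that bound.
#' @param seed integer seed.
#' @return list with `mean_t` (generations), `n_retained`, and the Monte
#'   Carlo standard error `se`.
#' @export
tmrca_mc_oracle <- function(L1, L2, n_draws = 1e6, T_max = NULL, seed = 1L) {
  if (!(L1 > 0 && L2 > L1)) stop("need 0 < L1 < L2", call. = FALSE)
  min_T <- 100 * 50 / L1
  if (is.null(T_max)) T_max <- min_T
  if (T_max < min_T)
    stop(sprintf("T_max = %g truncates the time prior (need >= %g); the retained mean would be biased",
                 T_max, min_T), call. = FALSE)
  set.seed(as.integer(seed))
  t <- stats::runif(n_draws, 0, T_max)
  l <- stats::rgamma(n_draws, shape = 2, rate = t / 50)
  keep <- l >= L1 & l < L2
  kept <- t[keep]
  list(mean_t = mean(kept), n_retained = length(kept),
       se = stats::sd(kept) / sqrt(length(kept)))
}
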