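#' structkit: haplotype-sharing statistics for fine-scale population structure
#'
#' Tools for validating haplotype-based genetic clusters (total variation
#' distance with permutation tests and merge trees), estimating non-negative
#' least squares ancestry profiles and their spatial gradients, dating
#' length-binned identity-by-descent (IBD) sharing, and quantifying phenotype
#' confounding by structure covariates. A synthetic structured-cohort
#' generator provides fully specified inputs with known truth so every
#' statistic can be exercised without access-controlled genotype data.
#'
#' @keywords internal
"_PACKAGE"

# Approximate autosomal genetic-map lengths (cM, chr1..chr22), used only to
# place synthetic segments on chromosomes proportionally to map length.
.AUTOSOME_CM <- c(284.2, 269.3, 223.4, 214.6, 204.1, 192.6, 187.2, 168.6,
                  166.4, 181.1, 158.2, 174.7, 125.9, 120.2, 141.8, 134.0,
                  128.5, 117.5, 107.9, 108.3, 62.8, 74.1)

#' Specify a synthetic structured-cohort scenario
#'
#' A scenario fully determines a synthetic cohort: a set of demes (discrete
#' subpopulations standing in for geographically localised genetic clusters)
#' with planar longitude/latitude centres, a block-structured coancestry
#' expectation with spatial decay, Poisson/Erlang IBD sharing with
#' deme-dependent coalescence-time distributions, linear spatial ancestry
#' gradients, and deme-stratified binary phenotypes. Identical configuration
#' and seed always reproduce the identical cohort.
#'
#' @param n_demes number of demes.
#' @param deme_centers list of `c(longitude, latitude)` centres in degrees,
#'   one per deme; must be pairwise distinct.
#' @param n_per_deme individuals per deme (at least 2).
#' @param genome_length_cM total genetic map length donated to each recipient
#'   (cM); every coancestry row sums to this value.
#' @param kappa within-deme coancestry boost (dimensionless, >= 0). The
#'   expected donation from donor j to recipient i is proportional to
#'   `exp(-d_ij / rho) * (1 + kappa * [same deme])`.
#' @param rho spatial decay range of coancestry (degrees, > 0).
#' @param alpha Dirichlet concentration of realised coancestry rows (> 0);
#'   large values give near-deterministic rows equal to their expectation.
#' @param lambda_within,lambda_between expected IBD segment-event counts per
#'   within-deme / between-deme pair (before the detection-floor filter).
#' @param tmrca_within,tmrca_between `c(shape, scale)` of the Gamma
#'   distribution of pairwise coalescence times (generations) for the two
#'   pair classes.
#' @param min_length_cM IBD detection floor (cM); shorter segments are
#'   discarded, emulating a detector's length threshold.
#' @param deme_scatter_sd standard deviation (degrees) of individual
#'   coordinates around their deme centre.
#' @param gradient_specs data frame with columns `source`, `bearing_deg`,
#'   `intercept`, `slope_per_deg`, `noise_sd` describing one linear spatial
#'   gradient per ancestry source: the true share of a source grows with the
#'   projection of an individual's (centred) coordinates onto the compass
#'   bearing, at `slope_per_deg` share units per degree.
#' @param phenotype_baseline intercept b0 of the case/control model on the
#'   log-odds scale.
#' @param phenotype_intercepts per-deme log-odds offsets s_d (length
#'   `n_demes`); `P(case | deme d) = plogis(b0 + s_d)`.
#' @param seed integer master seed; expanded internally into independent
#'   substreams for geography, coancestry, IBD, ancestry and phenotype so
#'   that regenerating one component does not perturb the others.
#'
#' @return an object of class `scenario_config` (a validated list).
#' @examples
#' cfg <- scenario_config(n_demes = 2,
#'                        deme_centers = list(c(5, 51.5), c(6, 53)),
#'                        n_per_deme = 5, seed = 7)
#' cfg$kappa
#' @export
scenario_config <- function(n_demes = 3,
                            deme_centers = list(c(5.0, 51.4),
                                                c(5.3, 52.2),
                                                c(6.2, 53.1)),
                            n_per_deme = 15,
                            genome_length_cM = 3500,
                            kappa = 8,
                            rho = 1.5,
                            alpha = 100,
                            lambda_within = 8,
                            lambda_between = 25,
                            tmrca_within = c(shape = 4, scale = 5),
                            tmrca_between = c(shape = 8, scale = 25),
                            min_length_cM = 1,
                            deme_scatter_sd = 0.25,
                            gradient_specs = default_gradient_specs(),
                            phenotype_baseline = 0,
                            phenotype_intercepts = rep(0, n_demes),
                            seed = 1L) {
  cfg <- list(n_demes = as.integer(n_demes),
              deme_centers = deme_centers,
              n_per_deme = as.integer(n_per_deme),
              genome_length_cM = genome_length_cM,
              kappa = kappa, rho = rho, alpha = alpha,
              lambda_within = lambda_within,
              lambda_between = lambda_between,
              tmrca_within = unname(tmrca_within),
              tmrca_between = unname(tmrca_between),
              min_length_cM = min_length_cM,
              deme_scatter_sd = deme_scatter_sd,
              gradient_specs = gradient_specs,
              phenotype_baseline = phenotype_baseline,
              phenotype_intercepts = phenotype_intercepts,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Default ancestry gradient specification
#'
#' Two antipodal gradients of equal slope plus a flat background source. With
#' intercepts summing to 1 and slopes cancelling, raw shares sum to 1 exactly
#' and the truth shares are exactly linear along the injected bearing.
#'
#' @return data frame with one row per ancestry source.
#' @export
default_gradient_specs <- function() {
  data.frame(source = c("EAST", "WEST", "BASE"),
             bearing_deg = c(73, 253, 0),
             intercept = c(0.40, 0.40, 0.20),
             slope_per_deg = c(0.06, 0.06, 0),
             noise_sd = c(0.005, 0.005, 0.005),
             stringsAsFactors = FALSE)
}

validate_scenario_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid scenario_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_demes < 1) fail("n_demes", "must be >= 1")
  if (length(cfg$deme_centers) != cfg$n_demes)
    fail("deme_centers", "length must equal n_demes")
  ctr <- do.call(rbind, lapply(cfg$deme_centers, as.numeric))
  if (ncol(ctr) != 2 || !all(is.finite(ctr)))
    fail("deme_centers", "each centre must be finite c(longitude, latitude)")
  if (anyDuplicated(ctr) > 0) fail("deme_centers", "centres must be distinct")
  if (cfg$n_per_deme < 2) fail("n_per_deme", "must be >= 2")
  pos <- c(genome_length_cM = cfg$genome_length_cM, rho = cfg$rho,
           alpha = cfg$alpha, min_length_cM = cfg$min_length_cM,
           deme_scatter_sd = cfg$deme_scatter_sd)
  for (nm in names(pos))
    if (!is.finite(pos[[nm]]) || pos[[nm]] <= 0)
      fail(nm, "must be strictly positive")
  if (cfg$kappa < 0) fail("kappa", "must be >= 0")
  for (nm in c("lambda_within", "lambda_between"))
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0) fail(nm, "must be >= 0")
  for (nm in c("tmrca_within", "tmrca_between")) {
    v <- cfg[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || any(v <= 0))
      fail(nm, "must be strictly positive c(shape, scale)")
  }
  gs <- cfg$gradient_specs
  need <- c("source", "bearing_deg", "intercept", "slope_per_deg", "noise_sd")
  if (!is.data.frame(gs) || !all(need %in% names(gs)) || nrow(gs) < 1)
    fail("gradient_specs",
         "must be a data frame with columns source, bearing_deg, intercept, slope_per_deg, noise_sd")
  if (anyDuplicated(gs$source) > 0)
    fail("gradient_specs", "source names must be unique")
  if (any(gs$noise_sd < 0)) fail("gradient_specs", "noise_sd must be >= 0")
  if (length(cfg$phenotype_intercepts) != cfg$n_demes)
    fail("phenotype_intercepts", "length must equal n_demes")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort scenario: %d demes x %d individuals (seed %d)\n",
              x$n_demes, x$n_per_deme, x$seed))
  cat(sprintf("  coancestry: kappa = %g, rho = %g deg, alpha = %g, rows sum to %g cM\n",
              x$kappa, x$rho, x$alpha, x$genome_length_cM))
  cat(sprintf("  IBD: lambda within/between = %g/%g, TMRCA Gamma(%g,%g)/Gamma(%g,%g) gen, floor %g cM\n",
              x$lambda_within, x$lambda_between,
              x$tmrca_within[1], x$tmrca_within[2],
              x$tmrca_between[1], x$tmrca_between[2], x$min_length_cM))
  cat(sprintf("  ancestry sources: %s\n",
              paste(x$gradient_specs$source, collapse = ", ")))
  invisible(x)
}

#' Read a scenario configuration from YAML
#'
#' The YAML file mirrors [scenario_config()] field for field; missing fields
#' take the defaults. `deme_centers` is a list of two-element sequences and
#' `gradient_specs` a list of mappings with the spec columns.
#'
#' @param path path to a YAML file.
#' @return a `scenario_config` object.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$gradient_specs))
    raw$gradient_specs <- do.call(rbind, lapply(raw$gradient_specs,
                                                as.data.frame))
  if (!is.null(raw$deme_centers))
    raw$deme_centers <- lapply(raw$deme_centers, as.numeric)
  do.call(scenario_config, raw)
}

# Derive a deterministic per-component substream seed from the master seed,
# kept below 2^31 so set.seed() accepts it.
substream_seed <- function(seed, component) {
  idx <- match(component, c("geography", "coancestry", "ibd",
                            "ancestry", "phenotype", "oracle"))
  if (is.na(idx)) stop("unknown substream component: ", component)
  as.integer((as.double(seed) * 48271 + idx * 16807) %% 2147483587)
}
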