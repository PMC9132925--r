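#' Configuration for a synthetic burial experiment
#'
#' Defaults emulate the design of the real experiment: 59 species (21
#' invasive, 38 naturalized), 3 replicate bags per species per exhumation
#' year, 7 exhumation years on the grid 1.5, 2.5, ..., 7.5 after a November
#' burial, and 100 seeds per bag. Species decline curves are logit-linear
#' in time with phylogenetically correlated species intercepts (and mildly
#' varying slopes), group-level slope differences (invasive declining
#' faster), and bag-level logit noise plus binomial sampling.
#'
#' @param n_invasive,n_naturalized species counts per group.
#' @param n_replicates bags per species per exhumation year.
#' @param exhumation_years strictly increasing positive grid of years.
#' @param seeds_per_bag seeds buried per bag.
#' @param lambda_true phylogenetic proportion of the species-level
#'   intercept variance (Pagel's lambda of the generating process).
#' @param intercept_mean named (invasive, naturalized) logit of viability
#'   at burial.
#' @param slope_mean named group decline rates, logits/year.
#' @param sd_phylo,sd_species,sd_bag standard deviations (logit scale) of
#'   the structured species effect, the iid species effect and the bag
#'   noise.
#' @param sd_slope standard deviation of per-species slope deviations
#'   (same lambda structure as the intercepts).
#' @param g_intercept,g_slope logit-linear germinability of viable seeds
#'   over time.
#' @param spont_frac fraction of germinated seeds germinating without
#'   gibberellic-acid stimulation.
#' @param status_clustering in \[0, 1\]: 0 assigns invasion status by random
#'   interleaving over the tips; larger values cluster invasive species
#'   phylogenetically (rank blend with a Brownian trait).
#' @param rng_seed integer seed controlling every random draw.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_invasive = 21, n_naturalized = 38,
                       n_replicates = 3,
                       exhumation_years = seq(1.5, 7.5, by = 1),
                       seeds_per_bag = 100,
                       lambda_true = 0.8,
                       intercept_mean = c(invasive = 2.5, naturalized = 2.5),
                       slope_mean = c(invasive = -0.80, naturalized = -0.55),
                       sd_phylo = 1.5, sd_species = 0, sd_bag = 1,
                       sd_slope = 0.15,
                       g_intercept = 1.5, g_slope = -0.1,
                       spont_frac = 0.8,
                       status_clustering = 0,
                       rng_seed = 1L) {
  stopifnot(n_invasive + n_naturalized >= 2,
            all(diff(exhumation_years) > 0), all(exhumation_years > 0),
            seeds_per_bag >= 1,
            lambda_true >= 0, lambda_true <= 1,
            sd_phylo >= 0, sd_species >= 0, sd_bag >= 0, sd_slope >= 0,
            spont_frac >= 0, spont_frac <= 1,
            status_clustering >= 0, status_clustering <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the species phylogeny of a burial experiment
#'
#' Pure-birth (Yule, rate 1) ultrametric tree with one tip per species,
#' depth normalised to 1. Invasion status is assigned over the tips by
#' random interleaving (or with phylogenetic clustering when
#' `status_clustering > 0`), so both groups span multiple clades; the
#' assignment is returned in the `invasion_status` attribute.
#'
#' @param config a [sim_config()]. Seed the RNG before calling (or use
#'   [simulate_burial_experiment()], which seeds once for the whole run).
#' @return an [ape::phylo] tree with tips `sp001`, `sp002`, ...; attribute
#'   `invasion_status` is a named character vector.
#' @export
simulate_tree <- function(config) {
  n <- config$n_invasive + config$n_naturalized
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n)])
  tree$edge.length <- tree$edge.length / depth
  cl <- config$status_clustering
  score <- if (cl > 0) {
    bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    cl * as.numeric(scale(bm)) + (1 - cl) * stats::rnorm(n)
  } else stats::rnorm(n)
  status <- rep("naturalized", n)
  status[order(score, decreasing = TRUE)[seq_len(config$n_invasive)]] <-
    "invasive"
  names(status) <- tree$tip.label
  attr(tree, "invasion_status") <- status
  tree
}

#' Simulate per-species decline parameters on a phylogeny
#'
#' Species intercepts are the group mean plus a zero-mean draw with
#' covariance `sd_phylo^2 (lambda C + (1 - lambda) I) + sd_species^2 I`,
#' where `C` is the tree's Brownian correlation matrix; slopes are the
#' group mean plus a draw with covariance
#' `sd_slope^2 (lambda C + (1 - lambda) I)`. Every drawn value is recorded
#' in the returned truth table, including each species' true P50 (the time
#' at which its noise-free generating curve crosses 50% viability).
#'
#' @param tree tree from [simulate_tree()] (with its status attribute).
#' @param config a [sim_config()].
#' @return data frame: `species_id`, `invasion_status`, `intercept`,
#'   `slope`, `intercept_dev`, `slope_dev`, `p50_true`.
#' @export
simulate_species_params <- function(tree, config) {
  status <- attr(tree, "invasion_status")
  if (is.null(status)) stop("tree lacks an invasion_status attribute",
                            call. = FALSE)
  n <- length(tree$tip.label)
  C <- phylo_correlation(tree)[tree$tip.label, tree$tip.label]
  lam <- config$lambda_true
  S_int <- config$sd_phylo^2 * (lam * C + (1 - lam) * diag(n)) +
    config$sd_species^2 * diag(n)
  S_slp <- config$sd_slope^2 * (lam * C + (1 - lam) * diag(n))
  int_dev <- mvn_draw(S_int)
  slp_dev <- mvn_draw(S_slp)
  int <- config$intercept_mean[status] + int_dev
  slp <- config$slope_mean[status] + slp_dev
  data.frame(
    species_id = tree$tip.label,
    invasion_status = unname(status[tree$tip.label]),
    intercept = unname(int), slope = unname(slp),
    intercept_dev = int_dev, slope_dev = slp_dev,
    p50_true = ifelse(slp < 0, -int / slp, Inf),
    stringsAsFactors = FALSE
  )
}

# one draw from N(0, S) via Cholesky with jitter escalation
mvn_draw <- function(S) {
  n <- nrow(S)
  if (all(S == 0)) return(numeric(n))
  L <- tryCatch(chol(S), error = function(e) {
    L2 <- tryCatch(chol(S + diag(1e-8, n)), error = function(e2) NULL)
    if (is.null(L2)) stop("composite covariance not positive definite",
                          call. = FALSE)
    L2
  })
  as.numeric(crossprod(L, stats::rnorm(n)))
}

#' Simulate the bag-level burial experiment
#'
#' For every species x replicate x exhumation year: a bag-level logit
#' deviation is drawn, true viability is the inverse logit of
#' `intercept + slope * t + bag noise`, the viable count is binomial in the
#' seeds buried, germinated seeds are binomial in the viable count with a
#' logit-linear germinability, and germinated seeds are split into
#' spontaneous vs gibberellic-acid-stimulated by `spont_frac`. Dead =
#' buried - viable. Bags are laid out in rows (stripes) of six; each
#' replicate set occupies its own block of rows, so no two members of a
#' triplet ever share a row.
#'
#' @param params truth table from [simulate_species_params()].
#' @param config a [sim_config()].
#' @return list: `records` (a [bag_records] table) and `bag_truth` (per-bag
#'   true viability and germinability probabilities).
#' @export
simulate_experiment <- function(params, config) {
  yrs <- config$exhumation_years
  reps <- seq_len(config$n_replicates)
  grid <- expand.grid(species_id = params$species_id,
                      replicate_id = reps,
                      years_since_burial = yrs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$species_id, params$species_id)
  t <- grid$years_since_burial
  nseed <- config$seeds_per_bag
  noise <- stats::rnorm(nrow(grid), 0, config$sd_bag)
  pv <- stats::plogis(params$intercept[i] + params$slope[i] * t + noise)
  pg <- stats::plogis(config$g_intercept + config$g_slope * t)
  viable <- stats::rbinom(nrow(grid), nseed, pv)
  germ <- stats::rbinom(nrow(grid), viable, pg)
  spont <- stats::rbinom(nrow(grid), germ, config$spont_frac)

  # spatial layout: rows of six bags, one block of rows per replicate so
  # triplet members never share a row
  n_per_rep <- nrow(grid) / config$n_replicates
  rows_per_rep <- ceiling(n_per_rep / 6)
  row_number <- integer(nrow(grid))
  row_sequence <- integer(nrow(grid))
  for (r in reps) {
    ix <- which(grid$replicate_id == r)
    ord <- sample(ix)                      # random placement within block
    pos <- seq_along(ord) - 1L
    row_number[ord] <- (r - 1L) * rows_per_rep + pos %/% 6L + 1L
    row_sequence[ord] <- pos %% 6L + 1L
  }

  records <- bag_records(data.frame(
    species_id = grid$species_id,
    replicate_id = grid$replicate_id,
    years_since_burial = t,
    row_number = row_number,
    row_sequence = row_sequence,
    n_buried = nseed,
    n_germ_spont = spont,
    n_germ_ga = germ - spont,
    n_viable_stained = viable - germ,
    n_dead = nseed - viable,
    stringsAsFactors = FALSE
  ))
  bag_truth <- data.frame(grid, p_viable = pv, p_germinable = pg,
                          bag_noise = noise, stringsAsFactors = FALSE)
  list(records = records, bag_truth = bag_truth)
}

#' Simulate a complete synthetic burial experiment
#'
#' Seeds the RNG once from `config$rng_seed`, then simulates the tree, the
#' species parameters, the trait table and the bag records, returning the
#' same objects the real-data pipeline consumes plus the full ground truth.
#' Seed masses are log-normal (most herb seeds weigh 0.1-10 mg), life form
#' is an even coin flip, the external seed-bank label is
#' persistent/transient/missing with rates 0.5/0.35/0.15, and pre-burial
#' viability is the noise-free generating curve at time zero.
#'
#' @param config a [sim_config()].
#' @return list: `tree`, `traits` ([species_traits]), `records`
#'   ([bag_records]), `species_truth`, `bag_truth`, `config`.
#' @export
simulate_burial_experiment <- function(config = sim_config()) {
  set.seed(config$rng_seed)
  tree <- simulate_tree(config)
  params <- simulate_species_params(tree, config)
  n <- nrow(params)
  traits <- species_traits(data.frame(
    species_id = params$species_id,
    invasion_status = params$invasion_status,
    life_form = sample(c("annual", "perennial"), n, replace = TRUE),
    seed_mass = stats::rlnorm(n, meanlog = log(1e-3), sdlog = 1),
    glossbank_type = sample(c("persistent", "transient", "missing"), n,
                            replace = TRUE, prob = c(0.5, 0.35, 0.15)),
    pre_burial_viability = 100 * stats::plogis(params$intercept),
    stringsAsFactors = FALSE
  ))
  expt <- simulate_experiment(params, config)
  list(tree = tree, traits = traits, records = expt$records,
       species_truth = params, bag_truth = expt$bag_truth, config = config)
}
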