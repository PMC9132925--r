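#' Write a synthetic burial experiment to disk
#'
#' Emits the same delimited tables and Newick tree the real-data pipeline
#' consumes (`records.tsv`, `traits.tsv`, `tree.nwk`) plus the ground truth
#' (`species_truth.tsv`, `bag_truth.tsv`) and the generating configuration
#' (`sim_config.json`). Idempotent for a given seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the list from [simulate_burial_experiment()].
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("run_simulate: created ", out_dir)
  }
  sim <- simulate_burial_experiment(config)
  write_tsv(sim$records, file.path(out_dir, "records.tsv"))
  write_tsv(sim$traits, file.path(out_dir, "traits.tsv"))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  write_tsv(sim$species_truth, file.path(out_dir, "species_truth.tsv"))
  write_tsv(sim$bag_truth, file.path(out_dir, "bag_truth.tsv"))
  cfg <- sim$config
  cfg_json <- lapply(unclass(cfg), function(x) x)
  jsonlite::write_json(cfg_json, file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Run the full burial-experiment analysis
#'
#' Orchestrates every stage on validated inputs: derived seed-fate table,
#' persistence classification, phylogenetic logistic mixed models (effect
#' summaries, Pagel's lambda, 0-10-year prediction curves) for each
#' requested response x covariate pair, per-species viability-equation fits
#' with the group P50 summary, and a run manifest. Species present in the
#' traits but absent from the tree are grafted onto their genus when a
#' congener exists.
#'
#' @param records_path,traits_path,tree_path input files (see
#'   [read_records()], [read_traits()], [read_newick()]).
#' @param out_dir output directory (created if absent).
#' @param models list of `c(response, covariate)` pairs; default fits
#'   viability and germinability against invasion status.
#' @param random random terms passed to [model_spec()].
#' @param chain a [chain_config()]; its seed controls all MCMC randomness.
#' @param k_i_mode,scale forwarded to [fit_viability_all()].
#' @return invisibly, a list with every computed object.
#' @export
run_analyze <- function(records_path, traits_path, tree_path, out_dir,
                        models = list(c("viability", "status"),
                                      c("germinability", "status")),
                        random = c("phylogeny", "species_identity", "triplet",
                                   "row_sequence", "row_number"),
                        chain = chain_config(),
                        k_i_mode = "fixed_full", scale = "probit") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "input validation"
  res <- tryCatch({
    records <- read_records(records_path)
    traits <- read_traits(traits_path)
    sp <- unique(records$species_id)
    absent <- setdiff(sp, traits$species_id)
    if (length(absent))
      stop("records reference species absent from traits: ",
           paste(absent, collapse = ", "))

    stage <- "phylogeny"
    tree <- suppressWarnings(read_newick(tree_path))
    for (s in setdiff(sp, tree$tip.label)) {
      message("run_analyze: grafting ", s, " at genus level")
      tree <- graft_at_genus(tree, s)
    }
    corr <- phylo_correlation(tree)

    stage <- "seed-fate summary"
    fates <- fate_summary(records)
    write_tsv(fates, file.path(out_dir, "fate_summary.tsv"))

    stage <- "persistence classification"
    persist <- classify_persistence_all(records)
    write_tsv(persist, file.path(out_dir, "persistence.tsv"))

    stage <- "phylogenetic logistic models"
    fits <- list()
    for (m in models) {
      tag <- paste(m[1], m[2], sep = "_")
      spec <- model_spec(response = m[1], covariate = m[2], random = random)
      model <- build_model(records, traits, corr, spec)
      post <- sample_posterior(model, chain)
      eff <- summarize_effects(post)
      write_tsv(eff, file.path(out_dir, paste0("effects_", tag, ".tsv")))
      lam <- if ("phylogeny" %in% random) pagel_lambda(post) else NULL
      if (!is.null(lam))
        write_tsv(data.frame(model = tag, lambda_mean = lam$mean,
                             ci_lower = lam$ci[1], ci_upper = lam$ci[2]),
                  file.path(out_dir, paste0("lambda_", tag, ".tsv")))
      crv <- predict_curve(post, model)
      write_tsv(crv, file.path(out_dir, paste0("curve_", tag, ".tsv")))
      fits[[tag]] <- list(posterior = post, effects = eff, lambda = lam,
                          curve = crv)
    }

    stage <- "viability equation"
    vfits <- fit_viability_all(fates, traits, k_i_mode = k_i_mode,
                               scale = scale)
    write_tsv(vfits, file.path(out_dir, "viability_fits.tsv"))
    gp50 <- group_p50(vfits, traits)
    write_tsv(gp50, file.path(out_dir, "group_p50.tsv"))

    stage <- "manifest"
    manifest <- list(
      package = "seedburial",
      version = as.character(utils::packageVersion("seedburial")),
      r_version = R.version.string,
      seed = chain$seed,
      chain = unclass(chain),
      inputs = as.list(tools::md5sum(c(records = records_path,
                                       traits = traits_path,
                                       tree = tree_path))),
      models = lapply(models, paste, collapse = ":")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)

    list(records = records, traits = traits, tree = tree, corr = corr,
         fates = fates, persistence = persist, models = fits,
         viability_fits = vfits, group_p50 = gp50, manifest = manifest)
  }, error = function(e) {
    stop("run_analyze failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

#' Score estimates against simulation ground truth
#'
#' Runs the viability analysis on a synthetic dataset and compares the
#' estimates with the generating values: invasion-status slope-difference
#' bias and CI, Pagel's lambda (on the species-level scale the generator
#' fixes: phylogenetic share of the species intercept variance) against
#' `lambda_true`, and per-species P50 relative error against the generating
#' curve's 50% crossing.
#'
#' @param sim list from [simulate_burial_experiment()] or [run_simulate()].
#' @param chain a [chain_config()].
#' @param out_path optional path for a machine-readable JSON report.
#' @return list with elements `slope_diff` (true, estimate, ci,
#'   significant, sign_correct), `lambda` (true, mean, ci, covered) and
#'   `p50` (median relative error over species finite in both).
#' @export
run_recover <- function(sim, chain = chain_config(), out_path = NULL) {
  truth <- sim$species_truth
  if (is.null(truth)) stop("run_recover: no species_truth in sim",
                           call. = FALSE)
  if (!setequal(truth$species_id, unique(sim$records$species_id)))
    stop("run_recover: truth/record species mismatch", call. = FALSE)
  corr <- phylo_correlation(sim$tree)
  spec <- model_spec("viability", "status",
                     random = c("phylogeny", "species_identity"))
  model <- build_model(sim$records, sim$traits, corr, spec)
  post <- sample_posterior(model, chain)
  eff <- summarize_effects(post)

  ix <- grep("time:", eff$term)  # status x time interaction
  true_diff <- sim$config$slope_mean[["naturalized"]] -
    sim$config$slope_mean[["invasive"]]
  slope_diff <- list(true = true_diff,
                     estimate = eff$posterior_mean[ix],
                     ci = c(eff$ci_lower[ix], eff$ci_upper[ix]),
                     significant = eff$significant[ix],
                     sign_correct = sign(eff$posterior_mean[ix]) ==
                       sign(true_diff))

  lam <- pagel_lambda(post, include_link_variance = FALSE,
                      include_residual = FALSE,
                      denom_terms = "species_identity")
  lam_true <- implied_species_lambda(sim$config)
  lambda <- list(true = lam_true, mean = lam$mean, ci = lam$ci,
                 covered = lam$ci[1] <= lam_true && lam_true <= lam$ci[2])

  fates <- fate_summary(sim$records)
  vfits <- fit_viability_all(fates, sim$traits)
  p50_true <- truth$p50_true[match(vfits$species_id, truth$species_id)]
  fin <- is.finite(vfits$p50) & is.finite(p50_true)
  p50 <- list(
    n_finite = sum(fin),
    median_rel_error = stats::median(abs(vfits$p50[fin] - p50_true[fin]) /
                                       p50_true[fin])
  )

  report <- list(slope_diff = slope_diff, lambda = lambda, p50 = p50)
  if (!is.null(out_path))
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA)
  report
}

# lambda on the species-intercept scale implied by the generator's variance
# decomposition: phylo share = sd_phylo^2 * lambda_true of total
# sd_phylo^2 + sd_species^2
implied_species_lambda <- function(config) {
  tot <- config$sd_phylo^2 + config$sd_species^2
  if (tot == 0) return(0)
  config$sd_phylo^2 * config$lambda_true / tot
}
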