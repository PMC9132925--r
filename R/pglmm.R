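#' Specify a phylogenetic binomial-logistic mixed model
#'
#' One model = one response (seed viability or germinability, per-bag
#' binomial counts), one species-level covariate interacting with time
#' since burial, and an ordered set of random intercept terms. Models for
#' different covariates are fitted separately, not jointly.
#'
#' @param response `"viability"` or `"germinability"`.
#' @param covariate species-level fixed covariate crossed with time: one of
#'   `"status"` (invasion status), `"log_seed_mass"`, `"life_form"`,
#'   `"glossbank_type"`, or `NULL` for an intercept + time model.
#' @param random character vector of random intercept terms, any of
#'   `"phylogeny"` (species effects with phylogenetic correlation),
#'   `"species_identity"` (iid species effects), `"triplet"`
#'   (species-by-year bag triplet), `"row_sequence"`, `"row_number"`.
#' @param ve fixed variance (logit scale) of the per-bag additive
#'   overdispersion term, the binomial analogue of the fixed residual
#'   variance for binary traits; default 1. Set to 0 to drop the term.
#' @param beta_var prior variance of each fixed-effect coefficient.
#' @param hc_scale scale of the half-Cauchy prior on each random-term
#'   standard deviation (parameter-expanded inverse-gamma implementation).
#' @return a `model_spec` list.
#' @export
model_spec <- function(response = c("viability", "germinability"),
                       covariate = "status",
                       random = c("phylogeny", "species_identity", "triplet",
                                  "row_sequence", "row_number"),
                       ve = 1, beta_var = 100, hc_scale = 1) {
  response <- match.arg(response)
  if (!is.null(covariate))
    covariate <- match.arg(covariate, c("status", "log_seed_mass",
                                        "life_form", "glossbank_type"))
  allowed <- c("phylogeny", "species_identity", "triplet", "row_sequence",
               "row_number")
  bad <- setdiff(random, allowed)
  if (length(bad)) stop("unknown random term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(ve >= 0, beta_var > 0, hc_scale > 0)
  structure(list(response = response, covariate = covariate,
                 random = random, ve = ve, beta_var = beta_var,
                 hc_scale = hc_scale),
            class = "model_spec")
}

#' MCMC chain settings
#'
#' Defaults are a desk-scale chain (20,000 steps, 2,000 burn-in, thinning
#' 20, 900 retained samples); production analyses use
#' `chain_config(1e6, 1e4, 100)`, retaining 9,900 samples.
#'
#' @param n_iter total MCMC steps.
#' @param burn_in initial steps discarded (must be < `n_iter`).
#' @param thin thinning interval (>= 1); retained samples =
#'   `floor((n_iter - burn_in) / thin)`.
#' @param seed integer RNG seed; every run with the same seed reproduces
#'   the retained samples exactly.
#' @return a `chain_config` list.
#' @export
chain_config <- function(n_iter = 20000, burn_in = 2000, thin = 20,
                         seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, burn_in >= 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

#' Assemble a phylogenetic logistic mixed model from burial data
#'
#' Builds per-bag binomial responses (viability: viable out of buried;
#' germinability: germinated out of viable exhumed, bags with zero viable
#' seeds dropped), the fixed design matrix (intercept, years since burial
#' kept raw so slopes are in logits/year, covariate main effect and
#' covariate-by-time interaction) and index structures for the random
#' terms. For `covariate = "glossbank_type"`, species without an external
#' seed-bank record (`"missing"`) are excluded from that model.
#'
#' @param records a [bag_records] table.
#' @param traits a [species_traits] table covering every species in
#'   `records`.
#' @param correlation phylogenetic correlation matrix from
#'   [phylo_correlation()]; required when `"phylogeny"` is a random term.
#' @param spec a [model_spec()].
#' @return a `pglmm_model` list (responses, designs, term metadata).
#' @export
build_model <- function(records, traits, correlation = NULL,
                        spec = model_spec()) {
  records <- as_valid_records(records)
  if (!inherits(traits, "species_traits")) traits <- species_traits(traits)
  sp_missing <- setdiff(unique(records$species_id), traits$species_id)
  if (length(sp_missing))
    stop("build_model: species without traits: ",
         paste(sp_missing, collapse = ", "), call. = FALSE)
  df <- merge(as.data.frame(records), as.data.frame(traits),
              by = "species_id", sort = FALSE)

  viable <- with(df, n_germ_spont + n_germ_ga + n_viable_stained)
  germ <- with(df, n_germ_spont + n_germ_ga)
  if (spec$response == "viability") {
    df$.succ <- viable
    df$.size <- df$n_buried
  } else {
    keep <- viable > 0
    df <- df[keep, , drop = FALSE]
    df$.succ <- germ[keep]
    df$.size <- viable[keep]
  }
  if (!is.null(spec$covariate) && spec$covariate == "glossbank_type")
    df <- df[df$glossbank_type != "missing", , drop = FALSE]
  if (nrow(df) == 0L) stop("build_model: no usable rows", call. = FALSE)
  if (all(df$.succ == 0) || all(df$.succ == df$.size))
    stop("build_model: response is all-zero or all-one (quasi-separation)",
         call. = FALSE)

  df$.time <- df$years_since_burial
  cov <- spec$covariate
  if (is.null(cov)) {
    X <- stats::model.matrix(~ .time, df)
  } else {
    df$.cov <- switch(cov,
      status = factor(df$invasion_status, c("invasive", "naturalized")),
      log_seed_mass = log(df$seed_mass),
      life_form = factor(df$life_form, c("annual", "perennial")),
      glossbank_type = factor(df$glossbank_type, c("transient", "persistent")))
    if (anyNA(df$.cov))
      stop("build_model: missing covariate values for ", cov, call. = FALSE)
    X <- stats::model.matrix(~ .time * .cov, df)
    colnames(X) <- gsub("\\.cov", cov_label(cov), colnames(X))
  }
  colnames(X) <- gsub("\\.time", "time", colnames(X))

  re <- list()
  Cinv <- NULL
  sp_f <- factor(df$species_id)
  for (term in spec$random) {
    f <- switch(term,
      phylogeny = sp_f,
      species_identity = sp_f,
      triplet = interaction(df$species_id, df$years_since_burial, drop = TRUE),
      row_sequence = factor(df$row_sequence),
      row_number = factor(df$row_number))
    re[[term]] <- f
  }
  if ("phylogeny" %in% spec$random) {
    if (is.null(correlation))
      stop("build_model: phylogeny term requires a correlation matrix",
         call. = FALSE)
    sp <- levels(sp_f)
    if (length(sp) < 2L)
      stop("build_model: phylogeny term degenerate with a single species",
           call. = FALSE)
    absent <- setdiff(sp, rownames(correlation))
    if (length(absent))
      stop("build_model: species missing from correlation matrix: ",
           paste(absent, collapse = ", "), call. = FALSE)
    C <- correlation[sp, sp]
    C <- C + diag(1e-8, length(sp))  # PSD jitter
    Cinv <- chol2inv(chol(C))
    dimnames(Cinv) <- list(sp, sp)
  }

  structure(list(
    y = as.integer(df$.succ), n = as.integer(df$.size),
    X = X, re = re, Cinv = Cinv, spec = spec,
    data = df[, c("species_id", "replicate_id", "years_since_burial",
                  "row_number", "row_sequence", ".succ", ".size")],
    covariate_levels = if (!is.null(cov) && cov != "log_seed_mass")
      levels(df$.cov) else NULL,
    covariate_values = if (!is.null(cov) && cov == "log_seed_mass")
      stats::setNames(log(traits$seed_mass), traits$species_id) else NULL
  ), class = "pglmm_model")
}

cov_label <- function(cov) {
  switch(cov, status = "status", log_seed_mass = "log_seed_mass",
         life_form = "life_form", glossbank_type = "glossbank_type")
}

#' Draw MCMC samples from the posterior of an assembled model
#'
#' Metropolis-within-Gibbs sampler (compiled): scalar random-walk updates
#' for fixed effects (on a QR-orthogonalised basis), every random-effect
#' level and every per-bag overdispersion deviate; exact inverse-gamma Gibbs
#' steps for the variance components under their parameter-expanded
#' half-Cauchy priors. Proposal scales adapt during burn-in only. Retained
#' samples number exactly `floor((n_iter - burn_in) / thin)`; convergence
#' diagnostics (split-Rhat and effective sample size per fixed effect and
#' variance component) are computed on the retained draws.
#'
#' @param model a `pglmm_model` from [build_model()].
#' @param chain a [chain_config()].
#' @return a `pglmm_posterior` object: matrices `beta` (retained samples x
#'   fixed effects) and `V` (retained samples x variance components, plus
#'   the fixed `ve`), diagnostics, acceptance rates, and the generating
#'   model/chain metadata.
#' @export
sample_posterior <- function(model, chain = chain_config()) {
  stopifnot(inherits(model, "pglmm_model"), inherits(chain, "chain_config"))
  qr_ <- qr(model$X)
  Q <- qr.Q(qr_)
  R <- qr.R(qr_)
  Rinv <- backsolve(R, diag(ncol(R)))

  terms <- names(model$re)
  re_idx <- lapply(model$re, function(f) as.integer(f) - 1L)
  re_q <- vapply(model$re, nlevels, integer(1))
  phylo_i <- match("phylogeny", terms, nomatch = 0L) - 1L
  pair_i <- if (phylo_i >= 0L && "species_identity" %in% terms)
    match("species_identity", terms) - 1L else -1L
  Cinv <- if (!is.null(model$Cinv)) model$Cinv else matrix(0, 1, 1)

  set.seed(chain$seed)
  raw <- pglmm_mcmc(model$y, model$n, Q, Rinv, re_idx, re_q,
                    phylo_i, Cinv, pair_i, model$spec$ve,
                    model$spec$beta_var, model$spec$hc_scale,
                    chain$n_iter, chain$burn_in, chain$thin)
  beta <- raw$beta
  colnames(beta) <- colnames(model$X)
  V <- raw$V
  colnames(V) <- terms
  diag_par <- cbind(beta, V)
  diagn <- data.frame(
    parameter = colnames(diag_par),
    rhat = apply(diag_par, 2, split_rhat),
    ess = apply(diag_par, 2, ess_autocorr)
  )
  structure(list(beta = beta, V = V, ve = model$spec$ve,
                 deviance = raw$deviance,
                 n_retained = raw$n_retained,
                 accept = list(beta = raw$accept_beta, u = raw$accept_u,
                               e = raw$accept_e),
                 diagnostics = diagn, chain = chain, model_spec = model$spec,
                 terms = terms),
            class = "pglmm_posterior")
}

# split-Rhat on one chain split into two halves (Gelman et al.)
split_rhat <- function(x) {
  m <- length(x) %/% 2L
  if (m < 4L) return(NA_real_)
  h <- list(x[1:m], x[(m + 1):(2 * m)])
  W <- mean(vapply(h, stats::var, numeric(1)))
  B <- m * stats::var(vapply(h, mean, numeric(1)))
  if (W <= 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

# effective sample size: initial positive-sum truncation of autocorrelations
ess_autocorr <- function(x) {
  S <- length(x)
  if (S < 8L || stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(S - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  cut <- if (length(pos)) pos[1] - 1L else length(rho)
  S / (1 + 2 * sum(rho[seq_len(cut)]))
}

#' @export
print.pglmm_posterior <- function(x, ...) {
  cat("pglmm_posterior:", x$n_retained, "retained samples\n")
  cat("fixed effects:", paste(colnames(x$beta), collapse = ", "), "\n")
  cat("variance components:", paste(x$terms, collapse = ", "),
      "| fixed ve =", x$ve, "\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Pagel's lambda from the fitted variance components
#'
#' Per retained sample, lambda is the share of the latent-scale variance
#' attributable to the phylogenetic term:
#' \deqn{\lambda = V_{phylo} / (V_{phylo} + \sum_{g} V_g + V_e + \pi^2/3)}
#' where the sum runs over the non-phylogenetic random terms, `Ve` is the
#' fixed overdispersion variance and `pi^2/3` is the logit-link variance
#' (standard latent-scale convention for binary/binomial responses). Both
#' the link term and the denominator scope are adjustable: restricting
#' `denom_terms` to `"species_identity"` with
#' `include_link_variance = FALSE` yields the species-level heritability
#' \eqn{V_{phylo}/(V_{phylo}+V_{species})}, the quantity a
#' phylogenetically-correlated species-effect simulation fixes directly.
#'
#' @param posterior a `pglmm_posterior` containing a phylogeny term.
#' @param include_link_variance add `pi^2/3` to the denominator (default
#'   TRUE).
#' @param include_residual add the fixed overdispersion variance `ve`
#'   (default TRUE).
#' @param denom_terms random terms besides phylogeny entering the
#'   denominator; default all terms in the model.
#' @return list: `samples` (numeric vector of per-draw lambda), `mean`,
#'   `ci` (equal-tailed 95%).
#' @export
pagel_lambda <- function(posterior, include_link_variance = TRUE,
                         include_residual = TRUE, denom_terms = NULL) {
  stopifnot(inherits(posterior, "pglmm_posterior"))
  if (!"phylogeny" %in% posterior$terms)
    stop("pagel_lambda: model has no phylogeny random term", call. = FALSE)
  if (is.null(denom_terms))
    denom_terms <- setdiff(posterior$terms, "phylogeny")
  bad <- setdiff(denom_terms, posterior$terms)
  if (length(bad)) stop("pagel_lambda: unknown terms: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  vp <- posterior$V[, "phylogeny"]
  denom <- vp
  for (g in setdiff(denom_terms, "phylogeny")) denom <- denom + posterior$V[, g]
  if (include_residual) denom <- denom + posterior$ve
  if (include_link_variance) denom <- denom + pi^2 / 3
  lam <- vp / denom
  list(samples = lam, mean = mean(lam),
       ci = stats::quantile(lam, c(0.025, 0.975), names = FALSE))
}

#' Posterior summaries and CI-based significance of fixed effects
#'
#' For every fixed-effect coefficient: posterior mean, posterior mode
#' (kernel-density peak), equal-tailed 95% credible interval, and a
#' significance flag — a parameter is significant exactly when its CI
#' excludes zero.
#'
#' @param posterior a `pglmm_posterior`.
#' @param prob credible mass (default 0.95).
#' @return data frame, one row per coefficient, ordered as in the design.
#' @export
summarize_effects <- function(posterior, prob = 0.95) {
  stopifnot(inherits(posterior, "pglmm_posterior"))
  al <- (1 - prob) / 2
  res <- lapply(colnames(posterior$beta), function(nm) {
    x <- posterior$beta[, nm]
    ci <- stats::quantile(x, c(al, 1 - al), names = FALSE)
    d <- stats::density(x)
    data.frame(term = nm, posterior_mean = mean(x),
               posterior_mode = d$x[which.max(d$y)],
               ci_lower = ci[1], ci_upper = ci[2],
               significant = ci[1] > 0 | ci[2] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Population-level decline curves with credible bands
#'
#' Pushes each retained fixed-effect draw through the inverse-logit at a
#' grid of times (random effects and overdispersion marginalised at zero,
#' i.e. the population-level curve for each covariate level), giving fitted
#' percentages and 2.5/97.5% credible bands over 0-10 years.
#'
#' @param posterior a `pglmm_posterior`.
#' @param model the `pglmm_model` it was fitted to.
#' @param times numeric grid of years; values outside \[0, 10\] warn
#'   (extrapolation beyond the modelled window).
#' @param at for a numeric covariate (log seed mass), values at which to
#'   evaluate the curve; default the observed mean.
#' @return data frame: `group`, `time`, `fit_pct`, `lo_pct`, `hi_pct`.
#' @export
predict_curve <- function(posterior, model, times = seq(0, 10, by = 0.5),
                          at = NULL) {
  stopifnot(inherits(posterior, "pglmm_posterior"),
            inherits(model, "pglmm_model"))
  if (any(times < 0 | times > 10))
    warning("predict_curve: times outside [0, 10] extrapolate beyond the ",
            "modelled window", call. = FALSE)
  cov <- model$spec$covariate
  if (is.null(cov)) {
    grid <- data.frame(.time = times)
    groups <- "all"
    gidx <- rep(1L, length(times))
  } else if (!is.null(model$covariate_levels)) {
    lv <- model$covariate_levels
    grid <- expand.grid(.time = times, .cov = factor(lv, lv))
    groups <- lv
    gidx <- as.integer(grid$.cov)
  } else {
    if (is.null(at)) at <- mean(model$covariate_values, na.rm = TRUE)
    grid <- expand.grid(.time = times, .cov = at)
    groups <- paste0(cov, "=", signif(at, 4))
    gidx <- match(grid$.cov, at)
  }
  Xn <- if (is.null(cov)) stats::model.matrix(~ .time, grid)
        else stats::model.matrix(~ .time * .cov, grid)
  # columns must align with fitted design
  stopifnot(ncol(Xn) == ncol(posterior$beta))
  eta <- Xn %*% t(posterior$beta)          # grid x samples
  pct <- 100 * stats::plogis(eta)
  data.frame(
    group = groups[gidx],
    time = grid$.time,
    fit_pct = rowMeans(pct),
    lo_pct = apply(pct, 1, stats::quantile, 0.025, names = FALSE),
    hi_pct = apply(pct, 1, stats::quantile, 0.975, names = FALSE),
    stringsAsFactors = FALSE
  )
}
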