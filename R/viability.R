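#' Probit (normal equivalent deviate) of a viability percentage
#'
#' Exact 0% and 100% values cannot be probit-transformed; they are clamped
#' to half a seed out of the bag size, i.e. the proportion is restricted to
#' `[0.5/n, 1 - 0.5/n]` before applying the normal quantile.
#'
#' @param v_pct viability on the percent scale.
#' @param n bag size used for clamping (default 100 seeds).
#' @return normal equivalent deviate(s).
#' @export
probit <- function(v_pct, n = 100) {
  p <- pmin(pmax(v_pct / 100, 0.5 / n), 1 - 0.5 / n)
  stats::qnorm(p)
}

#' Fit the Ellis-Roberts viability equation to one species
#'
#' Fits the seed survival line nu = K_i - p/sigma, where nu is bag
#' viability after p years of burial, K_i the viability at burial and sigma
#' the standard deviation (years) of the normal distribution of seed deaths
#' in time. The canonical fit is on the probit scale (nu and K_i as normal
#' equivalent deviates); a literal percent-scale variant is available for
#' sensitivity. All bags of the species are pooled.
#'
#' `k_i_mode` controls the intercept: `"fixed_full"` (default) assumes all
#' seeds viable at burial, K_i = probit of 100% clamped at the bag size;
#' `"fixed_measured"` uses the measured pre-burial viability;
#' `"free"` estimates K_i by least squares.
#'
#' When the fitted slope is non-negative (viability not declining), the fit
#' is flagged and P50 reported as `+Inf` rather than raising an error.
#'
#' @param fates [fate_summary()] rows for one species (>= 3 bags with
#'   defined viability across >= 2 distinct times).
#' @param k_i_mode intercept handling, see above.
#' @param scale `"probit"` (default) or `"percent"`.
#' @param pre_burial_viability percent, used by `"fixed_measured"`.
#' @param bag_size seeds per bag, for probit clamping (default 100).
#' @return a `viability_fit` list: `species_id`, `scale`, `k_i`, `sigma`,
#'   `p50`, `rss`, `n_bags`, `flag` (`"ok"` or `"non_decreasing"`).
#' @export
fit_viability <- function(fates, k_i_mode = c("fixed_full", "fixed_measured",
                                              "free"),
                          scale = c("probit", "percent"),
                          pre_burial_viability = NULL, bag_size = 100) {
  k_i_mode <- match.arg(k_i_mode)
  scale <- match.arg(scale)
  fates <- fates[!is.na(fates$viability_pct), , drop = FALSE]
  if (nrow(fates) < 3L || length(unique(fates$years_since_burial)) < 2L)
    stop("fit_viability: need >= 3 bags across >= 2 distinct times",
         call. = FALSE)
  sp <- unique(as.character(fates$species_id))
  if (length(sp) > 1L)
    stop("fit_viability: fates span multiple species", call. = FALSE)

  p <- fates$years_since_burial
  v <- if (scale == "probit") probit(fates$viability_pct, n = bag_size)
       else fates$viability_pct

  if (k_i_mode == "free") {
    fit <- stats::lm(v ~ p)
    k_i <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
    rss <- sum(stats::resid(fit)^2)
  } else {
    k_i <- if (k_i_mode == "fixed_full") {
      if (scale == "probit") probit(100, n = bag_size) else 100
    } else {
      if (is.null(pre_burial_viability))
        stop("fit_viability: fixed_measured needs pre_burial_viability",
             call. = FALSE)
      if (scale == "probit") probit(pre_burial_viability, n = bag_size)
      else pre_burial_viability
    }
    # least squares through the fixed intercept: v - k_i = b * p
    b <- sum(p * (v - k_i)) / sum(p^2)
    rss <- sum((v - k_i - b * p)^2)
  }

  if (b >= 0) {
    out <- list(species_id = sp, scale = scale, k_i = k_i, sigma = Inf,
                p50 = Inf, rss = rss, n_bags = nrow(fates),
                flag = "non_decreasing")
  } else {
    sigma <- -1 / b
    out <- list(species_id = sp, scale = scale, k_i = k_i, sigma = sigma,
                p50 = p50_closed_form(k_i, sigma, scale), rss = rss,
                n_bags = nrow(fates), flag = "ok")
  }
  structure(out, class = "viability_fit")
}

p50_closed_form <- function(k_i, sigma, scale) {
  if (!is.finite(sigma)) return(Inf)
  if (scale == "probit") sigma * k_i else sigma * (k_i - 50)
}

#' Time for viability to fall to 50% (P50)
#'
#' Solves nu(p) = 50% on the fitted line: on the probit scale the probit of
#' 50% is 0, so P50 = sigma * K_i; on the percent scale
#' P50 = sigma * (K_i - 50). A flagged non-decreasing fit propagates
#' `+Inf`.
#'
#' @param fit a `viability_fit`.
#' @return years (possibly `Inf`).
#' @export
p50 <- function(fit) {
  stopifnot(inherits(fit, "viability_fit"))
  p50_closed_form(fit$k_i, fit$sigma, fit$scale)
}

#' Fit the viability equation to every species in a fate table
#'
#' @param fates full [fate_summary()] table.
#' @param traits optional [species_traits] (needed for
#'   `k_i_mode = "fixed_measured"`).
#' @inheritParams fit_viability
#' @return data frame, one row per fitted species, with columns
#'   `species_id`, `scale`, `k_i`, `sigma`, `p50`, `rss`, `n_bags`, `flag`;
#'   species with too few usable bags are skipped with a message.
#' @export
fit_viability_all <- function(fates, traits = NULL,
                              k_i_mode = "fixed_full", scale = "probit",
                              bag_size = 100) {
  sp <- unique(fates$species_id)
  rows <- lapply(sp, function(s) {
    sub <- fates[fates$species_id == s, , drop = FALSE]
    pv <- if (!is.null(traits))
      traits$pre_burial_viability[match(s, traits$species_id)] else NULL
    f <- tryCatch(
      fit_viability(sub, k_i_mode = k_i_mode, scale = scale,
                    pre_burial_viability = pv, bag_size = bag_size),
      error = function(e) NULL)
    if (is.null(f)) {
      message("fit_viability_all: skipping ", s, " (too few usable bags)")
      return(NULL)
    }
    data.frame(species_id = f$species_id, scale = f$scale, k_i = f$k_i,
               sigma = f$sigma, p50 = f$p50, rss = f$rss, n_bags = f$n_bags,
               flag = f$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level P50 summary (invasive vs naturalized)
#'
#' Summarises the per-species P50 estimates within each invasion-status
#' group: central tendency (median by default, across species) and the
#' across-species min-max range of the finite estimates, plus the count of
#' flagged infinite fits.
#'
#' @param fits data frame from [fit_viability_all()].
#' @param traits [species_traits] providing `invasion_status`.
#' @param central `"median"` (default) or `"mean"`.
#' @return data frame: `group`, `central`, `range_low`, `range_high`,
#'   `n_finite`, `n_infinite`.
#' @export
group_p50 <- function(fits, traits, central = c("median", "mean")) {
  central <- match.arg(central)
  fun <- if (central == "median") stats::median else mean
  grp <- traits$invasion_status[match(fits$species_id, traits$species_id)]
  if (anyNA(grp))
    stop("group_p50: species without invasion_status: ",
         paste(fits$species_id[is.na(grp)], collapse = ", "), call. = FALSE)
  out <- lapply(c("invasive", "naturalized"), function(g) {
    x <- fits$p50[grp == g]
    fin <- x[is.finite(x)]
    if (length(fin) == 0L) {
      message("group_p50: no finite P50 in group ", g)
      return(data.frame(group = g, central = NA_real_, range_low = NA_real_,
                        range_high = NA_real_, n_finite = 0L,
                        n_infinite = sum(!is.finite(x))))
    }
    data.frame(group = g, central = fun(fin), range_low = min(fin),
               range_high = max(fin), n_finite = length(fin),
               n_infinite = sum(!is.finite(x)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
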