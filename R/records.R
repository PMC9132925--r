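#' Validated per-bag exhumation records
#'
#' A `bag_records` object is a data frame with one row per exhumed seed bag.
#' Required columns:
#' \describe{
#'   \item{species_id}{character, species identifier}
#'   \item{replicate_id}{integer 1--3, member of the triplet buried for one
#'     exhumation year}
#'   \item{years_since_burial}{positive numeric, time in years between burial
#'     and exhumation (design grid 1.5, 2.5, ..., 7.5)}
#'   \item{row_number}{integer, spatial row (stripe of six bags) holding the bag}
#'   \item{row_sequence}{integer, position of the bag within its row}
#'   \item{n_buried}{positive integer, seeds buried in the bag}
#'   \item{n_germ_spont}{integer, seeds that germinated in the laboratory test
#'     without gibberellic-acid stimulation}
#'   \item{n_germ_ga}{integer, seeds that germinated only after
#'     gibberellic-acid stimulation}
#'   \item{n_viable_stained}{integer, non-germinated seeds judged viable by
#'     tetrazolium staining or the squeeze test}
#'   \item{n_dead}{integer, dead seeds; decayed and unrecovered seeds are
#'     folded into this count at exhumation}
#' }
#' The four fate counts must sum exactly to `n_buried` in every row.
#'
#' @param df data frame holding the columns above.
#' @return `df` with class `bag_records` prepended, after validation.
#' @seealso [read_records()] for reading (and row-wise screening of) delimited
#'   files, [fate_summary()] for the derived percentages.
#' @export
bag_records <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("species_id", "replicate_id", "years_since_burial", "row_number",
           "row_sequence", "n_buried", "n_germ_spont", "n_germ_ga",
           "n_viable_stained", "n_dead")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("bag_records: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, union(req, names(df))]
  bad <- which(!record_row_ok(df))
  if (length(bad))
    stop("bag_records: ", length(bad), " row(s) violate count invariants ",
         "(rows ", paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", ")", call. = FALSE)
  key <- paste(df$species_id, df$replicate_id, df$years_since_burial, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("bag_records: duplicate (species, replicate, year) keys at rows ",
         paste(d, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("bag_records", class(df))
  df
}

# row-wise invariant check; returns logical vector, NA-safe (NA counts as bad)
record_row_ok <- function(df) {
  cnt <- c("n_buried", "n_germ_spont", "n_germ_ga", "n_viable_stained", "n_dead")
  ok <- rep(TRUE, nrow(df))
  for (cl in cnt) {
    v <- df[[cl]]
    ok <- ok & !is.na(v) & v >= 0 & v == round(v)
  }
  ok <- ok & !is.na(df$n_buried) & df$n_buried > 0
  ok <- ok & !is.na(df$years_since_burial) & df$years_since_burial > 0
  s <- df$n_germ_spont + df$n_germ_ga + df$n_viable_stained + df$n_dead
  ok & !is.na(s) & s == df$n_buried
}

#' Seed viability of a bag (percent of buried seeds)
#'
#' Viability counts every seed alive at exhumation: those that germinated
#' spontaneously, those that germinated after gibberellic-acid stimulation,
#' and non-germinated seeds that stained viable.
#'
#' @param records a `bag_records` object (or data frame with its columns).
#' @return numeric vector, one percentage in \[0, 100\] per bag.
#' @export
compute_viability <- function(records) {
  records <- as_valid_records(records)
  viable <- with(records, n_germ_spont + n_germ_ga + n_viable_stained)
  100 * viable / records$n_buried
}

#' Seed germinability of a bag (percent of viable exhumed seeds)
#'
#' Fraction of the viable seeds recovered from the bag that germinated in the
#' laboratory test (with or without gibberellic-acid stimulation). Undefined
#' (`NA`) when the bag held no viable seed; such bags are excluded from
#' germinability models.
#'
#' @inheritParams compute_viability
#' @return numeric vector; `NA` where no viable seeds were exhumed.
#' @export
compute_germinability <- function(records) {
  records <- as_valid_records(records)
  germ <- with(records, n_germ_spont + n_germ_ga)
  viable <- germ + records$n_viable_stained
  out <- rep(NA_real_, nrow(records))
  pos <- viable > 0
  out[pos] <- 100 * germ[pos] / viable[pos]
  out
}

#' Seed germination of a bag (percent of buried seeds, no stimulation)
#'
#' Seeds that germinated naturally in the laboratory, without
#' gibberellic-acid stimulation, as a percentage of all seeds buried.
#'
#' @inheritParams compute_viability
#' @return numeric vector of percentages.
#' @export
compute_germination <- function(records) {
  records <- as_valid_records(records)
  100 * records$n_germ_spont / records$n_buried
}

as_valid_records <- function(records) {
  if (!inherits(records, "bag_records")) records <- bag_records(records)
  records
}

#' Derived seed-fate summary table
#'
#' Computes, per bag, the three derived variables: seed viability
#' (viable / buried), seed germinability (germinated / viable exhumed,
#' `NA` when no viable seed was exhumed) and seed germination
#' (spontaneously germinated / buried), all on the percent scale.
#'
#' @inheritParams compute_viability
#' @return data frame with columns `species_id`, `replicate_id`,
#'   `years_since_burial`, `viability_pct`, `germinability_pct`,
#'   `germination_pct`.
#' @export
fate_summary <- function(records) {
  records <- as_valid_records(records)
  data.frame(
    species_id = records$species_id,
    replicate_id = records$replicate_id,
    years_since_burial = records$years_since_burial,
    viability_pct = compute_viability(records),
    germinability_pct = compute_germinability(records),
    germination_pct = compute_germination(records),
    stringsAsFactors = FALSE
  )
}

#' Classify seed-bank persistence of one species
#'
#' Classification follows the burial-experiment rule: a seed bank is
#' *transient* when no viable seed is found at any exhumation from 1.5 years
#' since burial onwards; *long-term persistent* when viable seeds are still
#' recorded after 5.5 years (i.e. at the 6.5- or 7.5-year exhumations on the
#' design grid); *short-term persistent* otherwise.
#'
#' @param records `bag_records` rows for a single species (>= 1 exhumation).
#' @return character scalar: `"transient"`, `"short_term_persistent"` or
#'   `"long_term_persistent"`.
#' @export
classify_persistence <- function(records) {
  records <- as_valid_records(records)
  if (nrow(records) == 0L)
    stop("classify_persistence: empty record list", call. = FALSE)
  if (length(unique(records$species_id)) > 1L)
    stop("classify_persistence: records span multiple species; use ",
         "classify_persistence_all()", call. = FALSE)
  viable <- with(records, n_germ_spont + n_germ_ga + n_viable_stained) > 0
  yr <- records$years_since_burial
  if (any(viable & yr > 5.5)) return("long_term_persistent")
  if (!any(viable & yr >= 1.5)) return("transient")
  "short_term_persistent"
}

#' Classify seed-bank persistence for every species in a record table
#'
#' @inheritParams compute_viability
#' @return data frame with columns `species_id` and `class`.
#' @export
classify_persistence_all <- function(records) {
  records <- as_valid_records(records)
  sp <- unique(records$species_id)
  cls <- vapply(sp, function(s)
    classify_persistence(records[records$species_id == s, , drop = FALSE]),
    character(1))
  data.frame(species_id = sp, class = unname(cls), stringsAsFactors = FALSE)
}
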