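#' Read a delimited bag-record table
#'
#' Reads a comma- or tab-delimited text file (UTF-8, mandatory header row)
#' holding one exhumed bag per row, screens every row against the count
#' invariants, and returns the valid rows as a [bag_records] object. Rows
#' failing an invariant (negative or non-integer counts, fate counts not
#' summing to seeds buried, non-positive burial time) are dropped and
#' reported, with their file line numbers, via a `validation` attribute and a
#' message. Duplicate (species, replicate, year) keys are a hard error.
#'
#' @param path path to the delimited file.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return a [bag_records] data frame; attribute `validation` is a data frame
#'   of rejected rows (`line`, `reason`).
#' @export
read_records <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  req <- c("species_id", "replicate_id", "years_since_burial", "row_number",
           "row_sequence", "n_buried", "n_germ_spont", "n_germ_ga",
           "n_viable_stained", "n_dead")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_records: ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cl in setdiff(req, c("species_id")))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  df$species_id <- as.character(df$species_id)

  ok <- record_row_ok(df)
  rejected <- data.frame(line = integer(0), reason = character(0))
  if (any(!ok)) {
    bad <- which(!ok)
    rejected <- data.frame(
      line = bad + 1L,  # +1 for the header line
      reason = vapply(bad, function(i) reject_reason(df[i, ]), character(1)),
      stringsAsFactors = FALSE
    )
    message("read_records: rejected ", length(bad), " row(s) at line(s) ",
            paste(utils::head(rejected$line, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "")
    df <- df[ok, , drop = FALSE]
  }
  key <- paste(df$species_id, df$replicate_id, df$years_since_burial, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("read_records: duplicate (species, replicate, year) keys at line(s) ",
         paste(as.integer(rownames(df))[d] + 1L, collapse = ", "),
         call. = FALSE)
  }
  out <- bag_records(df)
  attr(out, "validation") <- rejected
  out
}

reject_reason <- function(row) {
  cnt <- c("n_buried", "n_germ_spont", "n_germ_ga", "n_viable_stained", "n_dead")
  v <- unlist(row[cnt])
  if (anyNA(v)) return("non-numeric count")
  if (any(v != round(v))) return("non-integer count")
  if (any(v < 0)) return("negative count")
  if (is.na(row$n_buried) || row$n_buried <= 0) return("n_buried not positive")
  if (is.na(row$years_since_burial) || row$years_since_burial <= 0)
    return("years_since_burial not positive")
  "fate counts do not sum to n_buried"
}

#' Read a species-trait table
#'
#' Expected columns: `species_id`, `invasion_status` (invasive/naturalized),
#' `life_form` (annual/perennial), `seed_mass` (grams, > 0),
#' `glossbank_type` (transient/persistent/missing) and
#' `pre_burial_viability` (percent). Levels are checked; `glossbank_type`
#' may be empty or `"missing"` for species without an external seed-bank
#' record.
#'
#' @inheritParams read_records
#' @return data frame of species traits (class `species_traits`).
#' @export
read_traits <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  species_traits(df)
}

#' Validate a species-trait data frame
#'
#' @param df data frame with the columns described in [read_traits()].
#' @return `df` with class `species_traits`.
#' @export
species_traits <- function(df) {
  req <- c("species_id", "invasion_status", "life_form", "seed_mass",
           "glossbank_type", "pre_burial_viability")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("species_traits: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)
  df$species_id <- as.character(df$species_id)
  if (anyDuplicated(df$species_id))
    stop("species_traits: duplicated species_id", call. = FALSE)
  chk_enum <- function(x, levels, what, allow_missing = FALSE) {
    x <- as.character(x)
    if (allow_missing) x[is.na(x) | x == ""] <- "missing"
    bad <- !(x %in% levels)
    if (any(bad))
      stop("species_traits: invalid ", what, ": ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    x
  }
  df$invasion_status <- chk_enum(df$invasion_status,
                                 c("invasive", "naturalized"), "invasion_status")
  df$life_form <- chk_enum(df$life_form, c("annual", "perennial"), "life_form")
  df$glossbank_type <- chk_enum(df$glossbank_type,
                                c("transient", "persistent", "missing"),
                                "glossbank_type", allow_missing = TRUE)
  df$seed_mass <- as.numeric(df$seed_mass)
  if (any(!is.na(df$seed_mass) & df$seed_mass <= 0))
    stop("species_traits: seed_mass must be > 0", call. = FALSE)
  df$pre_burial_viability <- as.numeric(df$pre_burial_viability)
  pv <- df$pre_burial_viability
  if (any(!is.na(pv) & (pv < 0 | pv > 100)))
    stop("species_traits: pre_burial_viability outside [0, 100]", call. = FALSE)
  class(df) <- c("species_traits", class(df))
  df
}

read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8", comment.char = "")
}

#' Write a data frame as tab-delimited text
#'
#' Shared writer for all pipeline outputs: UTF-8, header row, tab separator,
#' no quoting, no row names, numbers at 6 significant digits for
#' reproducible diffs.
#'
#' @param df data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
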