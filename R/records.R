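# record-level data model: one row per identified blood-fed specimen

RECORD_COLUMNS <- c("specimen_id", "mosquito_taxon", "host_species",
                    "site_id", "collection_date", "trap_method", "land_use")

# Auto-detect comma vs tab separation from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Construct a survey dataset of blood-meal records
#'
#' The unit of observation is one engorged mosquito specimen whose blood-meal
#' host has been identified. `host_group` is derived from `host_species` via
#' the taxonomy, never supplied directly.
#'
#' @param records data frame with columns `specimen_id`, `mosquito_taxon`,
#'   `host_species`, `site_id`, `collection_date` (ISO-8601 or `Date`),
#'   `trap_method`, `land_use`.
#' @param taxonomy a [host_taxonomy()] used to derive `host_group`.
#' @param sites optional site metadata (data frame with `site_id` plus e.g.
#'   land-cover proportions). Defaults to the distinct sites in `records`.
#' @return An object of class `survey_dataset`: a list with elements
#'   `records` (the validated record table, plus derived columns
#'   `host_group` and `period`) and `sites`.
#' @examples
#' tx <- host_taxonomy(c("Homo sapiens", "Capreolus capreolus"),
#'                     c("human", "non-human mammal"))
#' rec <- data.frame(specimen_id = c("s1", "s2"),
#'                   mosquito_taxon = "Aedes vexans",
#'                   host_species = c("Homo sapiens", "Capreolus capreolus"),
#'                   site_id = "site1", collection_date = "2014-07-01",
#'                   trap_method = "EVS", land_use = "rural")
#' ds <- survey_dataset(rec, tx)
#' nrow(ds$records)
#' @export
survey_dataset <- function(records, taxonomy, sites = NULL) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(RECORD_COLUMNS, names(records))
  if (length(miss) > 0) {
    stop("records are missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (anyDuplicated(records$specimen_id)) {
    dup <- unique(records$specimen_id[duplicated(records$specimen_id)])
    stop("duplicated specimen_id(s): ", paste(head(dup, 5), collapse = ", "))
  }
  dates <- as.Date(records$collection_date)
  if (anyNA(dates)) {
    bad <- which(is.na(dates))
    stop("unparseable collection_date at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  records$collection_date <- dates
  bad_trap <- setdiff(unique(records$trap_method), TRAP_METHODS)
  if (length(bad_trap) > 0) {
    stop("unknown trap_method(s): ", paste(bad_trap, collapse = ", "))
  }
  bad_lu <- setdiff(unique(records$land_use), LAND_USES)
  if (length(bad_lu) > 0) {
    stop("unknown land_use(s): ", paste(bad_lu, collapse = ", "))
  }
  records$host_group <- lookup_host_group(taxonomy, records$host_species)
  records$period <- assign_period(records$collection_date)
  if (is.null(sites)) {
    sites <- unique(records[, c("site_id", "land_use")])
    rownames(sites) <- NULL
  }
  orphan <- setdiff(unique(records$site_id), sites$site_id)
  if (length(orphan) > 0) {
    stop("site_id(s) absent from site table: ", paste(orphan, collapse = ", "))
  }
  structure(list(records = records, sites = sites, taxonomy = taxonomy),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  n_excl <- sum(is.na(x$records$host_group))
  cat("survey_dataset:", nrow(x$records), "blood-meal records,",
      length(unique(x$records$mosquito_taxon)), "mosquito taxa,",
      length(unique(x$records$site_id)), "sites\n")
  if (n_excl > 0) {
    cat("  (", n_excl, " records with unidentified hosts,",
        " excluded from tabulations)\n", sep = "")
  }
  invisible(x)
}

#' Read blood-meal records from a delimited text file
#'
#' Comma- or tab-separated, auto-detected from the header. Required columns:
#' `specimen_id`, `mosquito_taxon`, `host_species`, `site_id`,
#' `collection_date`, `trap_method`, `land_use`.
#'
#' @inheritParams survey_dataset
#' @param path file path.
#' @return A [survey_dataset()].
#' @export
read_records <- function(path, taxonomy, sites = NULL) {
  tab <- read_delim_auto(path)
  miss <- setdiff(RECORD_COLUMNS, names(tab))
  if (length(miss) > 0) {
    stop("file ", basename(path), " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0) stop("empty dataset: ", basename(path))
  dates <- as.Date(tab$collection_date)
  if (anyNA(dates)) {
    stop("unparseable collection_date in ", basename(path), " at line(s): ",
         paste(head(which(is.na(dates)) + 1L, 5), collapse = ", "))
  }
  survey_dataset(tab, taxonomy, sites = sites)
}

#' Write blood-meal records to a delimited text file
#'
#' Writes the seven input columns (derived columns are omitted) so that
#' `read_records()` round-trips the file.
#'
#' @param dataset a [survey_dataset()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_records <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "survey_dataset"))
  out <- dataset$records[, RECORD_COLUMNS]
  out$collection_date <- format(out$collection_date, "%Y-%m-%d")
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# records with an identified host, as used by every tabulation
identified_records <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dataset$records[!is.na(dataset$records$host_group), , drop = FALSE]
}
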