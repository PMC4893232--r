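# survey-wide tabulations: per-mosquito-species and per-host-species summaries

# Percentages are kept at full precision; this helper reproduces the
# half-up one-decimal rounding used for display.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-mosquito-taxon summary of blood-meal records
#'
#' For each mosquito taxon: number of specimens, share of all specimens,
#' counts per host-feeding group and number of distinct host species.
#' Records with unidentified hosts are excluded.
#'
#' @param dataset a [survey_dataset()].
#' @return data frame with columns `mosquito_taxon`, `n_specimens`,
#'   `pct_specimens` (full precision), `pct_display` (half-up, one decimal),
#'   `birds`, `non_human_mammals`, `humans`, `n_host_species`. The grand
#'   total is attached as attribute `grand_total`.
#' @export
tabulate_species_summary <- function(dataset) {
  rec <- identified_records(dataset)
  if (nrow(rec) == 0) stop("empty dataset: no records with identified hosts")
  taxa <- sort(unique(rec$mosquito_taxon))
  total <- nrow(rec)
  rows <- lapply(taxa, function(tx) {
    r <- rec[rec$mosquito_taxon == tx, , drop = FALSE]
    data.frame(
      mosquito_taxon = tx,
      n_specimens = nrow(r),
      pct_specimens = 100 * nrow(r) / total,
      birds = sum(r$host_group == "bird"),
      non_human_mammals = sum(r$host_group == "non-human mammal"),
      humans = sum(r$host_group == "human"),
      n_host_species = length(unique(r$host_species)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$pct_display <- round_half_up(out$pct_specimens, 1)
  out <- out[, c("mosquito_taxon", "n_specimens", "pct_specimens",
                 "pct_display", "birds", "non_human_mammals", "humans",
                 "n_host_species")]
  rownames(out) <- NULL
  attr(out, "grand_total") <- total
  out
}

#' Per-host-species summary of blood-meal records
#'
#' For each host species: number of specimens, share of all specimens and
#' host-feeding group; per-group totals are attached as attribute
#' `group_totals`.
#'
#' @param dataset a [survey_dataset()].
#' @return data frame with columns `host_species`, `host_group`,
#'   `n_specimens`, `pct_specimens`, `pct_display`; attributes
#'   `group_totals` (data frame) and `grand_total`.
#' @export
tabulate_host_summary <- function(dataset) {
  rec <- identified_records(dataset)
  if (nrow(rec) == 0) stop("empty dataset: no records with identified hosts")
  total <- nrow(rec)
  counts <- aggregate(list(n_specimens = rec$specimen_id),
                      by = list(host_species = rec$host_species,
                                host_group = rec$host_group),
                      FUN = length)
  counts <- counts[order(counts$host_group, counts$host_species), ]
  counts$pct_specimens <- 100 * counts$n_specimens / total
  counts$pct_display <- round_half_up(counts$pct_specimens, 1)
  counts <- counts[, c("host_species", "host_group", "n_specimens",
                       "pct_specimens", "pct_display")]
  rownames(counts) <- NULL
  gt <- aggregate(list(n_specimens = counts$n_specimens),
                  by = list(host_group = counts$host_group), FUN = sum)
  gt$pct_specimens <- 100 * gt$n_specimens / total
  gt$pct_display <- round_half_up(gt$pct_specimens, 1)
  attr(counts, "group_totals") <- gt
  attr(counts, "grand_total") <- total
  counts
}

#' Host-range breadth: share of mosquito taxa feeding on each host species
#'
#' For each host species, the percentage of a stated denominator set of
#' mosquito taxa with at least one blood-meal record on that host. Aggregate
#' taxa (e.g. species complexes) are conventionally excluded from the
#' denominator, which is why it is explicit.
#'
#' @param dataset a [survey_dataset()].
#' @param denominator_taxa character vector of mosquito taxon names forming
#'   the denominator.
#' @return data frame with columns `host_species`, `n_taxa`, `pct_taxa`.
#' @export
host_range_breadth <- function(dataset, denominator_taxa) {
  if (length(denominator_taxa) == 0) stop("denominator_taxa must be non-empty")
  rec <- identified_records(dataset)
  rec <- rec[rec$mosquito_taxon %in% denominator_taxa, , drop = FALSE]
  hosts <- sort(unique(identified_records(dataset)$host_species))
  n_taxa <- vapply(hosts, function(h) {
    length(unique(rec$mosquito_taxon[rec$host_species == h]))
  }, integer(1))
  data.frame(host_species = hosts,
             n_taxa = as.integer(n_taxa),
             pct_taxa = 100 * n_taxa / length(denominator_taxa),
             row.names = NULL, stringsAsFactors = FALSE)
}
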