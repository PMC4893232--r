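# host-feeding-based transmission-risk index: feeding fractions per taxon
# combined with relative abundance.
#
# risk(bird -> human)   = Ap * Fa * Fh
# risk(mammal -> human) = Ap * Fm * Fh
#
# with Ap the taxon's relative abundance (fraction of all surveyed
# specimens), Fa/Fm/Fh its fractions of avian / non-human-mammal / human
# blood meals. Vector competence is deliberately not a factor: the index
# captures host-contact potential only.

#' Host-group feeding fractions of one mosquito taxon
#'
#' @param dataset a [survey_dataset()].
#' @param taxon mosquito taxon name.
#' @return list with `mosquito_taxon`, `n` (blood meals with identified
#'   hosts), `Fa`, `Fm`, `Fh` (fractions summing to 1).
#' @export
feeding_fractions <- function(dataset, taxon) {
  rec <- identified_records(dataset)
  rec <- rec[rec$mosquito_taxon == taxon, , drop = FALSE]
  if (nrow(rec) == 0) stop("taxon not present in dataset: ", taxon)
  n <- nrow(rec)
  list(mosquito_taxon = taxon, n = n,
       Fa = sum(rec$host_group == "bird") / n,
       Fm = sum(rec$host_group == "non-human mammal") / n,
       Fh = sum(rec$host_group == "human") / n)
}

#' Transmission-risk estimate for one mosquito taxon
#'
#' @param fractions feeding fractions from [feeding_fractions()] (or any
#'   list with `mosquito_taxon`, `Fa`, `Fm`, `Fh`).
#' @param Ap relative abundance of the taxon as a fraction in `[0, 1]` of
#'   all surveyed specimens. Percentages must be divided by 100 first (see
#'   [read_abundance()]).
#' @return list with `mosquito_taxon`, `Ap`, `risk_bird_to_human`,
#'   `risk_mammal_to_human`.
#' @examples
#' fr <- list(mosquito_taxon = "Culex torrentium",
#'            Fa = 8 / 15, Fm = 1 / 15, Fh = 6 / 15)
#' transmission_risk(fr, Ap = 0.01)
#' @export
transmission_risk <- function(fractions, Ap) {
  if (!is.numeric(Ap) || length(Ap) != 1 || is.na(Ap) || Ap < 0 || Ap > 1) {
    stop("Ap must be a single fraction in [0, 1]")
  }
  list(mosquito_taxon = fractions$mosquito_taxon, Ap = Ap,
       risk_bird_to_human = Ap * fractions$Fa * fractions$Fh,
       risk_mammal_to_human = Ap * fractions$Fm * fractions$Fh)
}

#' Rank mosquito taxa by transmission risk
#'
#' @param estimates list of estimates from [transmission_risk()].
#' @return list of two data frames, `bird_to_human` and `mammal_to_human`,
#'   each sorted by decreasing risk with ties broken alphabetically.
#' @export
rank_species <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  df <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(mosquito_taxon = e$mosquito_taxon, Ap = e$Ap,
               risk_bird_to_human = e$risk_bird_to_human,
               risk_mammal_to_human = e$risk_mammal_to_human,
               stringsAsFactors = FALSE)
  }))
  rank_one <- function(col) {
    out <- df[order(-df[[col]], df$mosquito_taxon), ]
    rownames(out) <- NULL
    out
  }
  list(bird_to_human = rank_one("risk_bird_to_human"),
       mammal_to_human = rank_one("risk_mammal_to_human"))
}

#' Read a relative-abundance table
#'
#' Two-column delimited text (`mosquito_taxon`, `abundance`). Values may be
#' fractions or percentages; set `percent = TRUE` to divide by 100.
#' An optional `shared_with` column names an aggregate taxon whose abundance
#' is assigned unchanged to member taxa that could not be separated in the
#' abundance survey (e.g. morphologically inseparable sibling species).
#'
#' @param path file path.
#' @param percent are the values percentages? Default `FALSE` (fractions).
#' @return data frame with columns `mosquito_taxon`, `Ap` (fraction) and,
#'   when present in the file, `shared_with`.
#' @export
read_abundance <- function(path, percent = FALSE) {
  tab <- read_delim_auto(path)
  need <- c("mosquito_taxon", "abundance")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("abundance file is missing column(s): ", paste(miss, collapse = ", "))
  }
  tab$Ap <- as.numeric(tab$abundance) / if (percent) 100 else 1
  if (any(tab$Ap < 0 | tab$Ap > 1)) {
    stop("abundance values outside [0, 1] after scaling; check `percent`")
  }
  keep <- c("mosquito_taxon", "Ap",
            intersect("shared_with", names(tab)))
  tab[, keep]
}

#' Transmission-risk table for a whole survey
#'
#' Convenience wrapper: feeding fractions for every taxon in the abundance
#' table, combined into ranked risk estimates. Taxa marked `shared_with`
#' receive the named aggregate's abundance unchanged, and the sharing is
#' recorded in the output.
#'
#' @param dataset a [survey_dataset()].
#' @param abundance data frame from [read_abundance()] (columns
#'   `mosquito_taxon`, `Ap`, optional `shared_with`).
#' @return as [rank_species()], with an extra `Ap_shared_from` column.
#' @export
survey_risk <- function(dataset, abundance) {
  ests <- lapply(seq_len(nrow(abundance)), function(i) {
    tx <- abundance$mosquito_taxon[i]
    fr <- feeding_fractions(dataset, tx)
    e <- transmission_risk(fr, abundance$Ap[i])
    e$Ap_shared_from <- if (!is.null(abundance$shared_with) &&
                            !is.na(abundance$shared_with[i]) &&
                            nzchar(abundance$shared_with[i]))
      abundance$shared_with[i] else NA_character_
    e
  })
  ranked <- rank_species(ests)
  shared <- vapply(ests, function(e) e$Ap_shared_from, character(1))
  names(shared) <- vapply(ests, function(e) e$mosquito_taxon, character(1))
  for (ch in names(ranked)) {
    ranked[[ch]]$Ap_shared_from <- unname(shared[ranked[[ch]]$mosquito_taxon])
  }
  ranked
}
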