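#' Host taxonomy: mapping host species to host-feeding groups
#'
#' A host taxonomy maps vertebrate host species (Latin binomials) to one of
#' the three host-feeding groups used throughout the analysis: `"bird"`,
#' `"non-human mammal"` and `"human"`. Lookups of species absent from the
#' taxonomy are errors, never silent defaults, so that typos in input data
#' surface immediately.
#'
#' @param host_species character vector of species names.
#' @param host_group character vector of the same length, each element one
#'   of `"bird"`, `"non-human mammal"`, `"human"`.
#' @param provenance optional character vector noting where each entry comes
#'   from; recycled if length 1.
#'
#' @return An object of class `host_taxonomy`: a data frame with columns
#'   `host_species`, `host_group`, `provenance`.
#' @examples
#' tx <- host_taxonomy(c("Homo sapiens", "Turdus merula"),
#'                     c("human", "bird"))
#' lookup_host_group(tx, "Turdus merula")
#' @export
host_taxonomy <- function(host_species, host_group, provenance = "user") {
  stopifnot(length(host_species) == length(host_group))
  host_species <- as.character(host_species)
  host_group <- as.character(host_group)
  bad <- setdiff(unique(host_group), HOST_GROUPS)
  if (length(bad) > 0) {
    stop("unknown host group(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(HOST_GROUPS, collapse = ", "), ")")
  }
  if (anyDuplicated(host_species)) {
    dup <- unique(host_species[duplicated(host_species)])
    stop("duplicated host species in taxonomy: ", paste(dup, collapse = ", "))
  }
  if ("Homo sapiens" %in% host_species &&
      host_group[host_species == "Homo sapiens"] != "human") {
    stop("Homo sapiens must map to host group 'human'")
  }
  out <- data.frame(host_species = host_species,
                    host_group = host_group,
                    provenance = rep_len(as.character(provenance),
                                         length(host_species)),
                    stringsAsFactors = FALSE)
  class(out) <- c("host_taxonomy", "data.frame")
  out
}

#' Look up the host group of one or more host species
#'
#' @param taxonomy a [host_taxonomy()].
#' @param species character vector of species names. `"unidentified"` is
#'   passed through as `NA` (records with unidentified hosts are stored but
#'   excluded from tabulations).
#' @return character vector of host groups (`NA` for `"unidentified"`).
#' @export
lookup_host_group <- function(taxonomy, species) {
  stopifnot(inherits(taxonomy, "host_taxonomy"))
  idx <- match(species, taxonomy$host_species)
  unknown <- setdiff(unique(species[is.na(idx)]), "unidentified")
  if (length(unknown) > 0) {
    stop("host species not in taxonomy: ", paste(unknown, collapse = ", "))
  }
  out <- taxonomy$host_group[idx]
  out[species == "unidentified"] <- NA_character_
  out
}

#' Built-in host taxonomy covering the packaged survey fixtures
#'
#' The 32 vertebrate host species recorded in the packaged German blood-meal
#' survey fixtures (11 birds, 20 non-human mammals, humans), each assigned to
#' its host-feeding group.
#'
#' @return A [host_taxonomy()] with 32 entries.
#' @export
default_host_taxonomy <- function() {
  path <- system.file("extdata", "host_species_counts.tsv",
                      package = "hostfeedr", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  host_taxonomy(tab$host_species, tab$host_group, provenance = "survey fixture")
}

#' Read a host taxonomy from a two-column delimited file
#'
#' The file must have a header with columns `host_species` and `host_group`
#' (comma- or tab-separated, auto-detected).
#'
#' @param path file path.
#' @return A [host_taxonomy()].
#' @export
read_taxonomy <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("host_species", "host_group")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("taxonomy file is missing column(s): ", paste(miss, collapse = ", "))
  }
  host_taxonomy(tab$host_species, tab$host_group,
                provenance = paste0("file:", basename(path)))
}
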