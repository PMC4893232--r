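# in-silico host identification from cytochrome-b amplicons: degenerate
# primer search, amplicon extraction, and best-identity assignment against
# a reference panel, with a two-tier primer fallback

#' Primer pair for in-silico PCR
#'
#' Both sequences are given 5'->3' as synthesized; the reverse primer is the
#' reverse complement of the template top strand and is reverse-complemented
#' internally before top-strand scanning.
#'
#' @param name primer-pair name.
#' @param forward,reverse IUPAC nucleotide strings, 5'->3'.
#' @param expected_length approximate amplicon length in bp (informational).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_length = NA_integer_) {
  forward <- toupper(gsub("[^A-Za-z]", "", forward))
  reverse <- toupper(gsub("[^A-Za-z]", "", reverse))
  ok <- function(s) nchar(s) > 0 &&
    grepl("^[ACGTRYSWKMBDHVN]+$", s)
  if (!ok(forward) || !ok(reverse)) {
    stop("primer sequences must be non-empty IUPAC nucleotide strings")
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_length = as.integer(expected_length)),
            class = "primer_pair")
}

#' Cytochrome-b primer pairs for vertebrate host identification
#'
#' The standard two-tier vertebrate cytochrome-b barcoding primers used for
#' blood-meal host identification: a short ~244 bp fragment
#' (L2513/H2714) tried first, and a ~358 bp fragment
#' (L14841/H15149) as fallback when the first PCR yields no product.
#'
#' @return named list of two [primer_pair()]s, `tier1` and `tier2`.
#' @export
cytb_primers <- function() {
  list(
    tier1 = primer_pair("L2513/H2714",
                        forward = "GCCTGTTTACCAAAAACATCAC",
                        reverse = "CTCCATAGGGTCTTCTCGTCTT",
                        expected_length = 244L),
    tier2 = primer_pair("L14841/H15149",
                        forward = "CCATCCAACATCTCAGCATGATGAAA",
                        reverse = "CCCTCAGAATGATATTTGTCCTCA",
                        expected_length = 358L)
  )
}

# IUPAC-aware comparison: degeneracy only on the primer side
iupac_base_sets <- function() {
  strsplit(Biostrings::IUPAC_CODE_MAP, "")
}

# mismatch count of `primer` laid on `window` (equal lengths)
iupac_mismatches <- function(primer_chars, window_chars, sets) {
  sum(!mapply(function(p, w) w %in% sets[[p]], primer_chars, window_chars))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# normalize a panel/query set to an uppercase named character vector
as_named_seqs <- function(x) {
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  x
}

#' Find primer binding sites on a template
#'
#' Scans both strands of the template for the primer under IUPAC-aware
#' comparison (a degenerate primer code matches any base in its set; plain
#' template bases only match codes containing them). A hit on the minus
#' strand means the reverse complement of the primer matches the top strand
#' at the reported coordinates. Coordinates are 0-based, half-open, on the
#' top strand.
#'
#' @param template nucleotide string.
#' @param primer IUPAC nucleotide string, 5'->3'.
#' @param max_mismatches maximum mismatches allowed (default 2).
#' @return data frame with columns `start`, `end`, `strand` (`"+"`/`"-"`),
#'   `mismatches`; zero rows when there is no site (including when the
#'   primer is longer than the template).
#' @export
find_primer_site <- function(template, primer, max_mismatches = 2) {
  template <- toupper(as.character(template))
  primer <- toupper(as.character(primer))
  if (nchar(template) == 0) stop("template must be non-empty")
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(primer) > nchar(template)) return(empty)
  subject <- Biostrings::DNAString(template)
  sets <- iupac_base_sets()
  tchars <- strsplit(template, "")[[1]]

  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(pat), subject,
      max.mismatch = max_mismatches,
      fixed = c(pattern = FALSE, subject = TRUE))
    if (length(hits) == 0) return(empty)
    st <- Biostrings::start(hits) - 1L
    en <- Biostrings::end(hits)
    pchars <- strsplit(pat, "")[[1]]
    mm <- vapply(seq_along(st), function(k) {
      iupac_mismatches(pchars, tchars[(st[k] + 1L):en[k]], sets)
    }, numeric(1))
    data.frame(start = st, end = en, strand = strand,
               mismatches = as.integer(mm), stringsAsFactors = FALSE)
  }

  out <- rbind(scan_one(primer, "+"), scan_one(revcomp(primer), "-"))
  out <- out[out$mismatches <= max_mismatches, , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the PCR amplicon a primer pair would produce
#'
#' Searches the template for a forward-primer site and a reverse-primer site
#' in amplifying orientation (forward on one strand, reverse downstream on
#' the other) and returns the primer-to-primer inclusive product, read
#' 5'->3' from the forward primer. If several products are possible the
#' shortest is returned (PCR strongly favours the shortest competing
#' product); absence of either site yields `NULL`.
#'
#' @param template nucleotide string.
#' @param pair a [primer_pair()].
#' @param max_mismatches maximum mismatches per primer (default 2).
#' @return amplicon string, or `NULL` when there is no product.
#' @export
extract_amplicon <- function(template, pair, max_mismatches = 2) {
  stopifnot(inherits(pair, "primer_pair"))
  template <- toupper(as.character(template))
  f <- find_primer_site(template, pair$forward, max_mismatches)
  r <- find_primer_site(template, pair$reverse, max_mismatches)
  cand <- list()
  # plus-strand product: forward(+) ... revcomp(reverse)(-)
  fp <- f[f$strand == "+", , drop = FALSE]
  rm_ <- r[r$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(rm_))) {
    if (fp$start[i] < rm_$start[j] && fp$end[i] <= rm_$end[j]) {
      cand[[length(cand) + 1L]] <-
        list(len = rm_$end[j] - fp$start[i],
             seq = substr(template, fp$start[i] + 1L, rm_$end[j]))
    }
  }
  # minus-strand product: reverse(+) ... revcomp(forward)(-)
  rp <- r[r$strand == "+", , drop = FALSE]
  fm <- f[f$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(rp))) for (j in seq_len(nrow(fm))) {
    if (rp$start[i] < fm$start[j] && rp$end[i] <= fm$end[j]) {
      cand[[length(cand) + 1L]] <-
        list(len = fm$end[j] - rp$start[i],
             seq = revcomp(substr(template, rp$start[i] + 1L, fm$end[j])))
    }
  }
  if (length(cand) == 0) return(NULL)
  lens <- vapply(cand, `[[`, numeric(1), "len")
  cand[[which.min(lens)]]$seq
}

#' Assign a host taxon to a query amplicon by best sequence identity
#'
#' The query is globally aligned (match +1, mismatch 0, linear gap penalty
#' -1) against every panel sequence; identity is the fraction of identical
#' aligned columns. The call is `"assigned"` when the best identity reaches
#' `min_identity` and exceeds the runner-up by at least `min_margin`;
#' `"ambiguous"` when the threshold is met but the margin is not (including
#' exact ties); `"unassigned"` when no panel sequence reaches the threshold.
#'
#' @param query nucleotide string.
#' @param panel named character vector (or `DNAStringSet`) of reference
#'   sequences; names are taxon names.
#' @param min_identity assignment threshold (default 0.95).
#' @param min_margin required identity gap to the second-best taxon
#'   (default 0.02).
#' @param query_id identifier carried into the result.
#' @return one-row data frame (a host call): `query_id`, `best_taxon`,
#'   `identity`, `margin`, `status`.
#' @export
assign_host <- function(query, panel, min_identity = 0.95,
                        min_margin = 0.02, query_id = "query") {
  query <- toupper(as.character(query))
  if (nchar(query) == 0) stop("empty query sequence")
  panel <- as_named_seqs(panel)
  if (length(panel) == 0) stop("reference panel is empty")
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("panel sequences must be named by taxon")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  ids <- vapply(panel, function(ref) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 1)
    Biostrings::pid(aln, type = "PID1") / 100
  }, numeric(1))
  ord <- order(-ids, names(panel))
  best <- ids[ord[1]]
  second <- if (length(ids) > 1) ids[ord[2]] else 0
  margin <- best - second
  status <- if (best < min_identity) "unassigned"
  else if (margin < min_margin) "ambiguous"
  else "assigned"
  data.frame(query_id = query_id,
             best_taxon = if (status == "unassigned") NA_character_
             else names(panel)[ord[1]],
             identity = unname(best), margin = unname(margin),
             status = status, stringsAsFactors = FALSE)
}

#' Two-tier host identification of a query set
#'
#' Every query is first assigned against the tier-1 reference panel
#' (amplicons of the first primer pair); only queries unassigned at tier 1
#' are re-tried against the tier-2 panel, mirroring the wet-lab fallback of
#' a second PCR when the first yields no product. The tier used is recorded
#' per call and input order is preserved.
#'
#' @param queries named character vector (or `DNAStringSet`) of query
#'   amplicons.
#' @param panels list with elements `tier1` and `tier2`, each a named
#'   reference panel.
#' @param min_identity,min_margin thresholds passed to [assign_host()].
#' @return data frame of host calls with an extra `tier` column (1 or 2;
#'   a query unassigned at both tiers carries the tier-2 call).
#' @export
two_tier_identify <- function(queries, panels, min_identity = 0.95,
                              min_margin = 0.02) {
  stopifnot(all(c("tier1", "tier2") %in% names(panels)))
  queries <- as_named_seqs(queries)
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- sprintf("q%d", seq_along(queries))
  }
  rows <- lapply(names(queries), function(id) {
    call1 <- assign_host(queries[[id]], panels$tier1, min_identity,
                         min_margin, query_id = id)
    if (call1$status != "unassigned") {
      call1$tier <- 1L
      return(call1)
    }
    call2 <- assign_host(queries[[id]], panels$tier2, min_identity,
                         min_margin, query_id = id)
    call2$tier <- 2L
    call2
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers around Biostrings' FASTA IO returning plain named
#' character vectors, the panel/query representation used across the
#' host-identification functions.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector, uppercase.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
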