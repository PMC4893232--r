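# shared builders and independent oracles for the test suite

tiny_taxonomy <- function() {
  host_taxonomy(
    c("Homo sapiens", "Capreolus capreolus", "Bos taurus", "Turdus merula",
      "Passer domesticus"),
    c("human", "non-human mammal", "non-human mammal", "bird", "bird"))
}

make_records <- function(host_species,
                         mosquito_taxon = "Aedes vexans",
                         site_id = "S1",
                         collection_date = "2014-07-01",
                         trap_method = "EVS",
                         land_use = "rural") {
  n <- length(host_species)
  data.frame(specimen_id = sprintf("id%03d", seq_len(n)),
             mosquito_taxon = rep_len(mosquito_taxon, n),
             host_species = host_species,
             site_id = rep_len(site_id, n),
             collection_date = rep_len(collection_date, n),
             trap_method = rep_len(trap_method, n),
             land_use = rep_len(land_use, n),
             stringsAsFactors = FALSE)
}

tiny_dataset <- function(...) {
  survey_dataset(make_records(...), tiny_taxonomy())
}

# ---- independent oracle: exact fixed-equiprobable null distribution -------
# Enumerates every equally likely placement of each row's 1s over the
# columns and tabulates the exact C-score distribution. Feasible for small
# matrices only; written from the definition, independently of the
# package's randomizer.

oracle_cscore <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sum(m[i, ] == 1 & m[j, ] == 1)
    tot <- tot + (sum(m[i, ]) - s) * (sum(m[j, ]) - s)
  }
  tot / choose(n, 2)
}

oracle_null_distribution <- function(m) {
  nc <- ncol(m)
  row_choices <- lapply(rowSums(m), function(r) {
    if (r == 0) return(list(integer(0)))
    combn(nc, r, simplify = FALSE)
  })
  grids <- expand.grid(lapply(row_choices, seq_along))
  vals <- apply(grids, 1, function(pick) {
    mm <- matrix(0L, nrow(m), nc)
    for (i in seq_len(nrow(m))) mm[i, row_choices[[i]][[pick[i]]]] <- 1L
    oracle_cscore(mm)
  })
  vals  # each outcome equally likely
}

oracle_exact_tails <- function(m) {
  vals <- oracle_null_distribution(m)
  obs <- oracle_cscore(m)
  eps <- 1e-9
  list(p_low = mean(vals <= obs + eps), p_high = mean(vals >= obs - eps))
}

# ---- independent oracle: naive all-offsets IUPAC primer scan --------------

oracle_iupac <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_primer_scan <- function(template, primer, max_mismatches) {
  tc <- strsplit(toupper(template), "")[[1]]
  hits <- data.frame(start = integer(), end = integer(),
                     strand = character(), mismatches = integer(),
                     stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    p <- if (strand == "+") toupper(primer) else oracle_revcomp(toupper(primer))
    pc <- strsplit(p, "")[[1]]
    L <- length(pc)
    if (L > length(tc)) next
    for (off in 0:(length(tc) - L)) {
      mm <- 0
      for (k in seq_len(L)) {
        if (!(tc[off + k] %in% oracle_iupac[[pc[k]]])) mm <- mm + 1
        if (mm > max_mismatches) break
      }
      if (mm <= max_mismatches) {
        hits <- rbind(hits, data.frame(start = off, end = off + L,
                                       strand = strand, mismatches = mm,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
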