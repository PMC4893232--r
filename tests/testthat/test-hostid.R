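pp <- cytb_primers()

test_that("primer sites are found verbatim and on the minus strand", {
  tpl <- paste0("AAAAGGGG", pp$tier1$forward, "TTTTCCCC")
  hits <- find_primer_site(tpl, pp$tier1$forward, max_mismatches = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 8)
  expect_equal(hits$end, 8 + nchar(pp$tier1$forward))
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  rc <- oracle_revcomp(tpl)
  hits_rc <- find_primer_site(rc, pp$tier1$forward, max_mismatches = 0)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
})

test_that("IUPAC degeneracy is honoured on the primer side", {
  # R matches A and G but not C/T; N matches everything
  expect_equal(nrow(find_primer_site("TTTAGGTTT", "ARG", 0)), 1)
  expect_equal(nrow(find_primer_site("TTTAAGTTT", "ARG", 0)), 1)
  expect_equal(nrow(find_primer_site("TTTACGTTT", "ARG", 0)), 0)
  # ANG hits ACG on the plus strand and (as CNT) CGT on the minus strand
  hits <- find_primer_site("TTTACGTTT", "ANG", 0)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("a primer longer than the template yields no sites, not an error", {
  expect_equal(nrow(find_primer_site("ACGT", pp$tier1$forward)), 0)
})

test_that("primer search agrees with the naive all-offsets scan oracle", {
  withr::local_seed(4021)
  for (rep in 1:25) {
    tpl <- random_dna(sample(60:400, 1))
    primer <- c(pp$tier1$forward, pp$tier1$reverse, pp$tier2$forward,
                "GCNTGYTTACCRAAAAACATCAC")[sample.int(4, 1)]
    mm <- sample(0:2, 1)
    got <- find_primer_site(tpl, primer, mm)
    want <- oracle_primer_scan(tpl, primer, mm)
    expect_equal(got, want, info = sprintf("rep %d", rep))
  }
})

test_that("amplicon extraction returns the primer-to-primer product", {
  insert <- withr::with_seed(1, random_dna(200))
  tpl <- paste0("GATTACA", pp$tier1$forward, insert,
                oracle_revcomp(pp$tier1$reverse), "TTTTT")
  amp <- extract_amplicon(tpl, pp$tier1)
  expect_equal(nchar(amp), 244)  # 22 + 200 + 22
  expect_true(startsWith(amp, pp$tier1$forward))

  insert2 <- withr::with_seed(2, random_dna(308))
  tpl2 <- paste0("CC", pp$tier2$forward, insert2,
                 oracle_revcomp(pp$tier2$reverse))
  expect_equal(nchar(extract_amplicon(tpl2, pp$tier2)), 358)
})

test_that("a missing reverse site means no product", {
  tpl <- paste0("GATTACA", pp$tier1$forward,
                withr::with_seed(3, random_dna(200)))
  expect_null(extract_amplicon(tpl, pp$tier1))
})

test_that("reverse-complementing the template reverse-complements the product", {
  insert <- withr::with_seed(5, random_dna(120))
  tpl <- paste0("AC", pp$tier1$forward, insert,
                oracle_revcomp(pp$tier1$reverse), "GGTT")
  amp <- extract_amplicon(tpl, pp$tier1)
  amp_rc <- extract_amplicon(oracle_revcomp(tpl), pp$tier1)
  expect_equal(amp_rc, amp)  # read 5'->3' from the forward primer either way
  expect_equal(nchar(amp_rc), nchar(amp))
})

test_that("assignment recovers exact matches, flags ties, matches Hamming", {
  panel <- synthetic_reference_panel(pp$tier1)
  call <- assign_host(panel[["Homo sapiens"]], panel, query_id = "self")
  expect_equal(call$best_taxon, "Homo sapiens")
  expect_equal(call$identity, 1)
  expect_equal(call$status, "assigned")

  # query equidistant from two identical panel sequences is ambiguous
  twin <- setNames(c(panel[[1]], panel[[1]]), c("taxon A", "taxon B"))
  call2 <- assign_host(panel[[1]], twin)
  expect_equal(call2$status, "ambiguous")
  expect_equal(call2$margin, 0)

  # 5 substitutions in a 244-nt sequence: identity = 239/244 (Hamming)
  ref <- panel[[2]]
  chars <- strsplit(ref, "")[[1]]
  pos <- c(30, 60, 90, 120, 150)
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  call3 <- assign_host(paste(chars, collapse = ""), panel,
                       min_identity = 0.95)
  expect_equal(call3$identity, 239 / 244)
  expect_equal(call3$status, "assigned")
  expect_equal(call3$best_taxon, names(panel)[2])
})

test_that("queries below the identity threshold are unassigned", {
  panel <- synthetic_reference_panel(pp$tier1)
  call <- assign_host(withr::with_seed(9, random_dna(244)), panel)
  expect_equal(call$status, "unassigned")
  expect_true(is.na(call$best_taxon))
})

test_that("two-tier identification touches tier 2 only for tier-1 failures", {
  panel1 <- synthetic_reference_panel(pp$tier1)
  panel2 <- synthetic_reference_panel(pp$tier2, seed = 202)
  # two queries resolvable at tier 1, one only at tier 2, one at neither
  queries <- c(q1 = panel1[[1]], q2 = panel1[[5]], q3 = panel2[[3]],
               q4 = withr::with_seed(8, random_dna(244)))
  calls <- two_tier_identify(queries, list(tier1 = panel1, tier2 = panel2))
  expect_equal(nrow(calls), 4)
  expect_equal(calls$query_id, c("q1", "q2", "q3", "q4"))
  expect_equal(calls$tier, c(1L, 1L, 2L, 2L))
  expect_equal(calls$status, c("assigned", "assigned", "assigned",
                               "unassigned"))
  expect_equal(calls$best_taxon[3], names(panel2)[3])
})

test_that("mutated queries are recovered at >= 99 % from a divergent panel", {
  panel <- synthetic_reference_panel(pp$tier1)
  # panel members must be mutually divergent well beyond 10 %
  dvg <- outer(seq_along(panel), seq_along(panel), Vectorize(function(i, j) {
    mean(strsplit(panel[[i]], "")[[1]] != strsplit(panel[[j]], "")[[1]])
  }))
  expect_true(all(dvg[upper.tri(dvg)] >= 0.10))

  qs <- generate_amplicons(panel, per_taxon = 10, substitution_rate = 0.02,
                           seed = 77)
  calls <- two_tier_identify(qs$queries,
                             list(tier1 = panel, tier2 = panel))
  truth <- qs$truth$true_taxon[match(calls$query_id, qs$truth$query_id)]
  expect_gte(mean(calls$status == "assigned" & calls$best_taxon == truth),
             0.99)
})

test_that("FASTA round-trip preserves names and sequences", {
  panel <- synthetic_reference_panel(pp$tier1)[1:3]
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(panel, path)
  back <- read_fasta(path)
  expect_equal(back, panel)
})
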