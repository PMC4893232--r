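# synthetic blood-meal surveys with known ground truth, plus generators for
# co-occurrence scenario matrices and mutated amplicon query sets.
#
# Host choice is modelled as preference x availability x trap bias
# (elementwise, renormalized): with uniform preferences the realized feeding
# pattern is purely availability-driven, which is the hypothesis the
# analysis is designed to probe.

#' Configuration for a synthetic blood-meal survey
#'
#' Defaults emulate a multi-site German survey: 52 sites classified
#' urban/rural/natural (11/36/5), three dominant mosquito taxa with
#' abundances in the observed proportions, a 12-species host community, a
#' summer-peaked season, and the observed mix of trapping methods with no
#' capture bias.
#'
#' @param n total number of blood-fed specimens (default 775).
#' @param sites data frame with `site_id`, `land_use`, `weight`.
#' @param taxa data frame with `mosquito_taxon`, `weight`.
#' @param hosts character vector of host species (must be resolvable by
#'   `taxonomy`).
#' @param availability named host-availability weights (recycled across
#'   sites), or a sites x hosts matrix for site-specific communities.
#' @param preferences taxa x hosts matrix of host-choice preference weights
#'   (default uniform: availability-driven feeding).
#' @param seasonal length-12 positive weights over months.
#' @param traps data frame with `trap_method`, `weight`.
#' @param trap_bias traps x host-group matrix of multiplicative capture
#'   bias factors (default all 1).
#' @param taxonomy a [host_taxonomy()] resolving `hosts`.
#' @return object of class `survey_config`.
#' @export
survey_config <- function(n = 775,
                          sites = NULL, taxa = NULL, hosts = NULL,
                          availability = NULL, preferences = NULL,
                          seasonal = NULL, traps = NULL, trap_bias = NULL,
                          taxonomy = default_host_taxonomy()) {
  if (is.null(sites)) {
    sites <- data.frame(
      site_id = sprintf("site%02d", 1:52),
      land_use = rep(c("urban", "rural", "natural"), c(11, 36, 5)),
      weight = 1, stringsAsFactors = FALSE)
  }
  if (is.null(taxa)) {
    taxa <- data.frame(
      mosquito_taxon = c("Aedes vexans", "Culex pipiens pipiens form pipiens",
                         "Ochlerotatus cantans"),
      weight = c(363, 100, 99), stringsAsFactors = FALSE)
  }
  if (is.null(hosts)) {
    hosts <- c("Capreolus capreolus", "Bos taurus", "Sus scrofa",
               "Ovis aries", "Lepus europaeus", "Homo sapiens",
               "Turdus merula", "Turdus philomelos", "Passer domesticus",
               "Corvus corone", "Sylvia atricapilla", "Cyanistes caeruleus")
  }
  if (is.null(availability)) {
    # mammal-dominated host community, as in rural central Europe
    availability <- setNames(c(6, 3, 3, 1.5, 1, 4.5,
                               0.6, 0.2, 0.2, 0.15, 0.1, 0.15), hosts)
  }
  if (is.matrix(availability)) {
    stopifnot(nrow(availability) == nrow(sites),
              ncol(availability) == length(hosts))
    avail <- availability
  } else {
    stopifnot(length(availability) == length(hosts))
    if (!is.null(names(availability))) availability <- availability[hosts]
    avail <- matrix(rep(as.numeric(availability), each = nrow(sites)),
                    nrow = nrow(sites))
  }
  dimnames(avail) <- list(sites$site_id, hosts)
  if (is.null(preferences)) {
    preferences <- matrix(1, nrow(taxa), length(hosts))
  }
  dimnames(preferences) <- list(taxa$mosquito_taxon, hosts)
  if (is.null(seasonal)) {
    seasonal <- c(0, 0, 0.02, 0.05, 0.13, 0.2, 0.25, 0.2, 0.1, 0.04, 0.01, 0)
  }
  stopifnot(length(seasonal) == 12, all(seasonal >= 0), any(seasonal > 0))
  if (is.null(traps)) {
    traps <- data.frame(
      trap_method = c("EVS", "BG-Sentinel", "gravid", "aspirator",
                      "sweep-net", "human-bait"),
      weight = c(602, 37, 42, 20, 71, 3), stringsAsFactors = FALSE)
  }
  if (is.null(trap_bias)) {
    trap_bias <- matrix(1, nrow(traps), length(HOST_GROUPS))
  }
  dimnames(trap_bias) <- list(traps$trap_method, HOST_GROUPS)
  host_group <- lookup_host_group(taxonomy, hosts)
  stopifnot(n >= 1, all(sites$weight >= 0), all(taxa$weight >= 0),
            all(avail >= 0), all(preferences >= 0), all(trap_bias >= 0))
  structure(list(n = as.integer(n), sites = sites, taxa = taxa,
                 hosts = hosts, host_group = host_group,
                 availability = avail, preferences = preferences,
                 seasonal = as.numeric(seasonal), traps = traps,
                 trap_bias = trap_bias, taxonomy = taxonomy),
            class = "survey_config")
}

#' Generate a synthetic blood-meal survey with known ground truth
#'
#' Each record draws taxon, site, trap method and month independently from
#' their weight vectors; the host is then drawn from the taxon's preference
#' weights times the site's host availability times the trap's host-group
#' bias, renormalized. Fully reproducible from `seed`.
#'
#' @param config a [survey_config()].
#' @param seed integer seed (required).
#' @return list with `dataset` (a [survey_dataset()]) and `truth` (list:
#'   `expected_group_fractions` — the exact per-taxon generating host-group
#'   fractions marginalized over sites and traps; `realized_group_fractions`;
#'   `preferences`).
#' @export
generate_survey <- function(config, seed) {
  stopifnot(inherits(config, "survey_config"))
  if (missing(seed)) stop("an explicit integer seed is required")
  cf <- config
  n_sites <- nrow(cf$sites); n_taxa <- nrow(cf$taxa); n_traps <- nrow(cf$traps)
  group_idx <- match(cf$host_group, HOST_GROUPS)

  # per (taxon, site, trap): renormalized host distribution
  host_dist <- function(t, s, tr) {
    w <- cf$preferences[t, ] * cf$availability[s, ] *
      cf$trap_bias[tr, group_idx]
    tot <- sum(w)
    if (tot <= 0) {
      stop("all-zero host distribution for taxon '",
           cf$taxa$mosquito_taxon[t], "' at site '", cf$sites$site_id[s],
           "' (trap '", cf$traps$trap_method[tr], "')")
    }
    w / tot
  }
  # validate every combination up front so errors name taxon and site
  for (t in seq_len(n_taxa)) for (s in seq_len(n_sites))
    for (tr in seq_len(n_traps)) host_dist(t, s, tr)

  rec <- withr::with_seed(seed, {
    t_i <- sample.int(n_taxa, cf$n, replace = TRUE, prob = cf$taxa$weight)
    s_i <- sample.int(n_sites, cf$n, replace = TRUE, prob = cf$sites$weight)
    tr_i <- sample.int(n_traps, cf$n, replace = TRUE, prob = cf$traps$weight)
    m_i <- sample.int(12, cf$n, replace = TRUE, prob = cf$seasonal)
    h_i <- vapply(seq_len(cf$n), function(k) {
      sample.int(length(cf$hosts), 1, prob = host_dist(t_i[k], s_i[k], tr_i[k]))
    }, integer(1))
    data.frame(
      specimen_id = sprintf("syn%05d", seq_len(cf$n)),
      mosquito_taxon = cf$taxa$mosquito_taxon[t_i],
      host_species = cf$hosts[h_i],
      site_id = cf$sites$site_id[s_i],
      collection_date = as.Date(sprintf("2014-%02d-15", m_i)),
      trap_method = cf$traps$trap_method[tr_i],
      land_use = cf$sites$land_use[s_i],
      stringsAsFactors = FALSE)
  })
  dataset <- survey_dataset(rec, cf$taxonomy,
                            sites = cf$sites[, c("site_id", "land_use")])

  # exact generating host-group fractions per taxon, marginalized over the
  # site and trap weights
  p_site <- cf$sites$weight / sum(cf$sites$weight)
  p_trap <- cf$traps$weight / sum(cf$traps$weight)
  expected <- t(vapply(seq_len(n_taxa), function(t) {
    acc <- numeric(3)
    for (s in seq_len(n_sites)) for (tr in seq_len(n_traps)) {
      hd <- host_dist(t, s, tr)
      for (g in 1:3) {
        acc[g] <- acc[g] + p_site[s] * p_trap[tr] * sum(hd[group_idx == g])
      }
    }
    acc
  }, numeric(3)))
  dimnames(expected) <- list(cf$taxa$mosquito_taxon, HOST_GROUPS)

  realized <- t(vapply(cf$taxa$mosquito_taxon, function(tx) {
    r <- rec[rec$mosquito_taxon == tx, , drop = FALSE]
    if (nrow(r) == 0) return(rep(NA_real_, 3))
    g <- lookup_host_group(cf$taxonomy, r$host_species)
    vapply(HOST_GROUPS, function(hg) mean(g == hg), numeric(1))
  }, numeric(3)))
  dimnames(realized) <- dimnames(expected)

  list(dataset = dataset,
       truth = list(expected_group_fractions = expected,
                    realized_group_fractions = realized,
                    preferences = cf$preferences))
}

#' Generate a co-occurrence scenario matrix with known pattern
#'
#' `"aggregated"`: every host row occupies one universal column plus one
#' uniformly placed extra column (sparse noise), so all row pairs share at
#' least the universal column. `"segregated"`: rows occupy pairwise disjoint
#' column blocks (maximal checkerboarding for the row sums).
#' `"random"`: fixed row sums (2 per row where possible) placed uniformly —
#' i.e. a draw from the fixed-equiprobable null itself.
#'
#' @param kind `"aggregated"`, `"segregated"` or `"random"`.
#' @param n_hosts number of rows (>= 2).
#' @param n_columns number of columns (>= 2; for `"segregated"` at least
#'   `n_hosts`).
#' @param seed integer seed.
#' @return binary matrix with `n_hosts` rows and `n_columns` columns.
#' @export
generate_feeding_scenario <- function(kind = c("aggregated", "segregated",
                                               "random"),
                                      n_hosts, n_columns, seed) {
  kind <- match.arg(kind)
  stopifnot(n_hosts >= 2, n_columns >= 2)
  if (missing(seed)) stop("an explicit integer seed is required")
  m <- matrix(0L, n_hosts, n_columns,
              dimnames = list(sprintf("host%02d", seq_len(n_hosts)),
                              sprintf("col%02d", seq_len(n_columns))))
  if (kind == "segregated") {
    if (n_hosts > n_columns) {
      stop("segregated scenario infeasible: more hosts (", n_hosts,
           ") than columns (", n_columns, ")")
    }
    share <- diff(floor(seq(0, n_columns, length.out = n_hosts + 1)))
    stop_at <- cumsum(share)
    start_at <- c(1, head(stop_at, -1) + 1)
    for (i in seq_len(n_hosts)) m[i, start_at[i]:stop_at[i]] <- 1L
    return(m)
  }
  withr::with_seed(seed, {
    if (kind == "aggregated") {
      m[, 1] <- 1L
      if (n_columns > 1) {
        for (i in seq_len(n_hosts)) {
          m[i, 1 + sample.int(n_columns - 1, 1)] <- 1L
        }
      }
    } else {
      r <- min(2L, n_columns)
      for (i in seq_len(n_hosts)) m[i, sample.int(n_columns, r)] <- 1L
    }
  })
  m
}

#' Synthetic cytochrome-b reference panel
#'
#' Builds reference sequences for a 12-species host community (6 mammals
#' including humans, 6 birds): each reference carries the primer pair's
#' binding sites flanking a species-specific random insert, so the pair
#' amplifies every panel member and inserts are mutually divergent far
#' beyond the 10 % separation the assignment step assumes.
#'
#' @param pair a [primer_pair()] (default the tier-1 cytochrome-b pair).
#' @param insert_length insert length in bp; the default yields the pair's
#'   expected amplicon length.
#' @param taxa taxon names (default the 12-species host community).
#' @param seed integer seed (default 101).
#' @return named character vector of reference sequences.
#' @export
synthetic_reference_panel <- function(pair = cytb_primers()$tier1,
                                      insert_length = NULL, taxa = NULL,
                                      seed = 101) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.null(insert_length)) {
    insert_length <- pair$expected_length - nchar(pair$forward) -
      nchar(pair$reverse)
  }
  if (is.null(taxa)) {
    taxa <- c("Homo sapiens", "Capreolus capreolus", "Bos taurus",
              "Sus scrofa", "Ovis aries", "Lepus europaeus",
              "Turdus merula", "Turdus philomelos", "Passer domesticus",
              "Corvus corone", "Sylvia atricapilla", "Cyanistes caeruleus")
  }
  withr::with_seed(seed, {
    seqs <- vapply(taxa, function(tx) {
      insert <- paste(sample(c("A", "C", "G", "T"), insert_length,
                             replace = TRUE), collapse = "")
      paste0(pair$forward, insert, revcomp(pair$reverse))
    }, character(1))
  })
  seqs
}

#' Generate mutated amplicon queries from a reference panel
#'
#' Each query is a panel sequence with i.i.d. substitutions at the stated
#' rate (substituted bases are drawn from the three alternatives), with the
#' true taxon recorded.
#'
#' @param panel named character vector of reference sequences.
#' @param per_taxon number of queries per panel member.
#' @param substitution_rate per-base substitution probability in `[0, 0.2]`.
#' @param seed integer seed.
#' @return list with `queries` (named character vector) and `truth`
#'   (data frame `query_id`, `true_taxon`).
#' @export
generate_amplicons <- function(panel, per_taxon = 1, substitution_rate = 0.02,
                               seed) {
  if (length(panel) == 0) stop("reference panel is empty")
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.2)
  if (missing(seed)) stop("an explicit integer seed is required")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    out <- list(); truth <- list()
    for (tx in names(panel)) {
      chars <- strsplit(panel[[tx]], "")[[1]]
      for (k in seq_len(per_taxon)) {
        hit <- which(stats::runif(length(chars)) < substitution_rate)
        q <- chars
        for (i in hit) q[i] <- sample(setdiff(bases, chars[i]), 1)
        id <- sprintf("%s|%d", gsub(" ", "_", tx), k)
        out[[id]] <- paste(q, collapse = "")
        truth[[id]] <- tx
      }
    }
  })
  list(queries = unlist(out),
       truth = data.frame(query_id = names(out),
                          true_taxon = unlist(truth),
                          row.names = NULL, stringsAsFactors = FALSE))
}
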