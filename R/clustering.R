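# host-feeding-group identification: binary host-group profiles per mosquito
# taxon, Jaccard dissimilarity, UPGMA dendrogram, zero-height group extraction

#' Binary host-group profiles per mosquito taxon
#'
#' For each mosquito taxon, a presence/absence triple over the host-feeding
#' groups (bird, non-human mammal, human): a bit is set iff the taxon has at
#' least one blood-meal record in that group. This is the "normalized"
#' presence-absence view: abundances are deliberately discarded.
#'
#' Accepts either a [survey_dataset()] or a per-taxon count table like
#' [survey_species_counts()] (columns `mosquito_taxon`, `birds`,
#' `non_human_mammals`, `humans`).
#'
#' @param x dataset or count table.
#' @return integer 0/1 matrix, one row per taxon, columns `bird`,
#'   `non-human mammal`, `human`.
#' @export
group_profiles <- function(x) {
  if (inherits(x, "survey_dataset")) {
    rec <- identified_records(x)
    tab <- table(rec$mosquito_taxon,
                 factor(rec$host_group, levels = HOST_GROUPS))
    m <- matrix(as.integer(tab > 0), nrow = nrow(tab), dimnames = dimnames(tab))
  } else if (is.data.frame(x) &&
             all(c("mosquito_taxon", "birds", "non_human_mammals",
                   "humans") %in% names(x))) {
    m <- cbind(as.integer(x$birds > 0), as.integer(x$non_human_mammals > 0),
               as.integer(x$humans > 0))
    dimnames(m) <- list(x$mosquito_taxon, HOST_GROUPS)
  } else {
    stop("x must be a survey_dataset or a per-taxon host-group count table")
  }
  if (any(rowSums(m) == 0)) {
    stop("taxa with no host-group records: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  m[order(rownames(m)), , drop = FALSE]
}

#' Jaccard dissimilarity between two binary profiles
#'
#' `1 - |intersection| / |union|` over set bits. Both profiles must have at
#' least one bit set.
#'
#' @param a,b binary vectors of equal length.
#' @return number in `[0, 1]`.
#' @examples
#' jaccard_dissimilarity(c(1, 1, 1), c(0, 1, 1))  # 1/3
#' @export
jaccard_dissimilarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  if (!any(a) || !any(b)) stop("all-zero profile has no Jaccard dissimilarity")
  1 - sum(a & b) / sum(a | b)
}

# full pairwise Jaccard matrix over profile rows
jaccard_matrix <- function(profiles) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- jaccard_dissimilarity(profiles[i, ], profiles[j, ])
    }
  }
  d
}

#' UPGMA (average-linkage) dendrogram of host-group profiles
#'
#' Agglomerative clustering under unweighted pair-group average linkage:
#' at each step the pair of clusters with the smallest mean pairwise
#' dissimilarity merges. Ties are broken deterministically: the pair whose
#' (sorted) cluster label pair is lexicographically smallest merges first,
#' so the tree does not depend on input order. The result is a standard
#' `hclust` object (with `method = "average"`), so it plots and converts
#' (e.g. via [ape::as.phylo()]) like any other.
#'
#' @param profiles binary profile matrix from [group_profiles()], or any
#'   matrix whose rows are observations; dissimilarity is Jaccard.
#' @return an object of class `hclust`.
#' @export
upgma <- function(profiles) {
  n <- nrow(profiles)
  if (n < 2) stop("need at least 2 profiles")
  labels <- rownames(profiles)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- jaccard_matrix(profiles)

  # active clusters: list of member leaf indices; label = smallest member label
  members <- as.list(seq_len(n))
  clab <- labels
  node <- -seq_len(n)          # hclust convention: negative = leaf
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  dd <- d                      # between-cluster average dissimilarities
  active <- rep(TRUE, n)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in (ii + 1):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        cand <- dd[i, j]
        key <- sort(c(clab[i], clab[j]))
        if (is.null(best) || cand < best$h - 1e-12 ||
            (abs(cand - best$h) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, h = cand, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- best$h
    # average-linkage update weighted by cluster sizes (unweighted over leaves)
    for (k in idx) {
      if (k == i || k == j) next
      dd[i, k] <- dd[k, i] <-
        (sizes[i] * dd[i, k] + sizes[j] * dd[j, k]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    clab[i] <- min(clab[i], clab[j])
    node[i] <- step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height,
                 order = order_leaves(merge, n),
                 labels = labels, method = "average",
                 dist.method = "jaccard",
                 call = match.call()),
            class = "hclust")
}

# leaf order for plotting: depth-first through the merge matrix
order_leaves <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' Extract host-feeding groups from profiles
#'
#' Host-feeding groups are the equivalence classes of identical binary
#' host-group profiles — equivalently, the zero-height clusters of the UPGMA
#' dendrogram, since Jaccard dissimilarity is zero iff profiles coincide.
#' Each group is labelled by its host-group combination.
#'
#' @param profiles binary profile matrix from [group_profiles()].
#' @return data frame with columns `mosquito_taxon`, `combination` (e.g.
#'   `"non-human mammal + human"`), `group_id`. Groups are numbered in
#'   decreasing size, ties broken by combination label.
#' @export
extract_feeding_groups <- function(profiles) {
  if (is.null(colnames(profiles))) {
    colnames(profiles) <- if (ncol(profiles) == 3) HOST_GROUPS
    else sprintf("group%d", seq_len(ncol(profiles)))
  }
  combo <- apply(profiles, 1, function(p) {
    paste(colnames(profiles)[p > 0], collapse = " + ")
  })
  sizes <- table(combo)
  lev <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  group_id <- match(combo, lev)
  data.frame(mosquito_taxon = rownames(profiles),
             combination = unname(combo),
             group_id = group_id,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a dendrogram to a Newick file
#'
#' @param tree an `hclust` object (e.g. from [upgma()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
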