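test_that("group profiles set a bit iff the taxon fed on the group", {
  counts <- survey_species_counts()
  pr <- group_profiles(counts)
  expect_equal(unname(pr["Ochlerotatus cantans", ]), c(0L, 1L, 1L))
  expect_equal(unname(pr["Culex spp.", ]), c(1L, 0L, 0L))
  expect_equal(unname(pr["Aedes vexans", ]), c(1L, 1L, 1L))
  ds <- tiny_dataset(host_species = "Homo sapiens")
  expect_equal(unname(group_profiles(ds)[1, ]), c(0L, 0L, 1L))
})

test_that("Jaccard dissimilarity matches set arithmetic and is a metric", {
  expect_equal(jaccard_dissimilarity(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(jaccard_dissimilarity(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_equal(jaccard_dissimilarity(c(1, 1, 1), c(0, 1, 1)), 1 / 3)
  expect_error(jaccard_dissimilarity(c(0, 0, 0), c(1, 0, 0)), "all-zero")
  # metric axioms over all 7 x 7 non-degenerate binary triples
  profiles <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, ]
  n <- nrow(profiles)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d[i, j] <- jaccard_dissimilarity(profiles[i, ], profiles[j, ])
  }
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))  # distinct profiles never at 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("Jaccard agrees with vegan's binary Jaccard distance", {
  skip_if_not_installed("vegan")
  pr <- group_profiles(survey_species_counts())
  ref <- as.matrix(vegan::vegdist(pr, method = "jaccard", binary = TRUE))
  expect_equal(unname(jaccard_matrix(pr)), unname(ref), tolerance = 1e-12)
})

test_that("UPGMA reproduces a hand-traced average-linkage merge sequence", {
  # profiles: a=(1,0,0) b=(1,1,0) c=(0,1,1) d=(0,0,1)
  pr <- rbind(a = c(1, 0, 0), b = c(1, 1, 0), c = c(0, 1, 1), d = c(0, 0, 1))
  # pairwise: ab=1/2, ac=1, ad=1, bc=2/3, bd=1, cd=1/2
  # step 1: merge a,b at 1/2 (tie with c,d broken lexicographically)
  # step 2: merge c,d at 1/2
  # step 3: d({a,b},{c,d}) = mean(ac, ad, bc, bd) = mean(1,1,2/3,1) = 11/12
  tree <- upgma(pr)
  expect_equal(tree$height, c(1 / 2, 1 / 2, 11 / 12))
  expect_equal(tree$merge[1, ], c(-2L, -1L))
  expect_equal(tree$merge[2, ], c(-4L, -3L))
  expect_equal(tree$merge[3, ], c(1L, 2L))
  expect_equal(sort(tree$order), 1:4)
})

test_that("UPGMA heights match stats::hclust average linkage", {
  pr <- group_profiles(survey_species_counts())
  tree <- upgma(pr)
  ref <- hclust(as.dist(jaccard_matrix(pr)), method = "average")
  expect_equal(sort(tree$height), sort(ref$height), tolerance = 1e-12)
  expect_false(is.unsorted(tree$height))  # no inversions
})

test_that("identical profiles merge at height zero before anything else", {
  pr <- rbind(x = c(0, 1, 1), y = c(0, 1, 1), z = c(1, 1, 1))
  tree <- upgma(pr)
  expect_equal(tree$height[1], 0)
  expect_equal(sort(tree$merge[1, ]), c(-2L, -1L))  # x and y first
  tree2 <- upgma(rbind(p = c(1, 0, 0), q = c(1, 0, 0)))
  expect_equal(tree2$height, 0)
})

test_that("UPGMA is invariant to input row order", {
  pr <- group_profiles(survey_species_counts())
  withr::local_seed(3)
  shuffled <- pr[sample(nrow(pr)), ]
  t1 <- upgma(pr); t2 <- upgma(shuffled)
  expect_equal(t1$height, t2$height)
  # the same clusters form at the same heights regardless of input order
  cluster_sets <- function(tree) {
    members <- list()
    out <- character(nrow(tree$merge))
    for (s in seq_len(nrow(tree$merge))) {
      kids <- lapply(tree$merge[s, ], function(k) {
        if (k < 0) tree$labels[-k] else members[[k]]
      })
      members[[s]] <- sort(unlist(kids))
      out[s] <- paste(signif(tree$height[s], 10),
                      paste(members[[s]], collapse = "|"))
    }
    sort(out)
  }
  expect_equal(cluster_sets(t1), cluster_sets(t2))
})

test_that("feeding groups are the distinct host-group combinations", {
  pr <- rbind(a = c(0, 1, 1), b = c(0, 1, 1), c = c(1, 1, 1))
  gr <- extract_feeding_groups(pr)
  expect_equal(length(unique(gr$group_id)), 2)
  expect_setequal(as.integer(table(gr$combination)), c(2L, 1L))

  pr2 <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  expect_equal(length(unique(extract_feeding_groups(pr2)$group_id)), 3)

  # the packaged survey: the two multi-species groups plus singleton combos
  gr3 <- extract_feeding_groups(group_profiles(survey_species_counts()))
  expect_true("non-human mammal + human" %in% gr3$combination)
  expect_true("bird + non-human mammal + human" %in% gr3$combination)
  # groups partition the taxa
  expect_equal(nrow(gr3), nrow(group_profiles(survey_species_counts())))
  expect_false(any(duplicated(gr3$mosquito_taxon)))
})

test_that("dendrogram exports to Newick with all leaves", {
  pr <- group_profiles(survey_species_counts())
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(upgma(pr), path)
  phy <- ape::read.tree(path)
  # Newick-unsafe characters in taxon labels are sanitized on export
  normalize <- function(x) gsub("[^A-Za-z0-9]", "", x)
  expect_setequal(normalize(phy$tip.label), normalize(rownames(pr)))
  expect_equal(ape::Ntip(phy), nrow(pr))
})
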