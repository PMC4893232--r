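test_that("records round-trip through delimited text field-for-field", {
  ds <- tiny_dataset(host_species = c("Homo sapiens", "Capreolus capreolus",
                                      "Turdus merula"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(ds, path)
  ds2 <- read_records(path, tiny_taxonomy())
  expect_equal(ds2$records[, colnames(ds$records)], ds$records)
  expect_equal(nrow(ds2$records), 3)
})

test_that("host groups are derived from the taxonomy, never guessed", {
  ds <- tiny_dataset(host_species = "Capreolus capreolus")
  expect_equal(ds$records$host_group, "non-human mammal")
  expect_error(tiny_dataset(host_species = "Martes martes"),
               "not in taxonomy.*Martes martes")
  expect_error(host_taxonomy("Homo sapiens", "bird"), "Homo sapiens")
})

test_that("reading a file with a missing column names it in the error", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_records("Homo sapiens")
  rec$collection_date <- NULL
  write.csv(rec, path, row.names = FALSE)
  expect_error(read_records(path, tiny_taxonomy()), "collection_date")
})

test_that("separator auto-detection handles comma and tab files", {
  rec <- make_records(c("Homo sapiens", "Turdus merula"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, csv, row.names = FALSE)
  expect_equal(nrow(read_records(csv, tiny_taxonomy())$records), 2)
})

test_that("assign_period splits the year into disjoint covering halves", {
  expect_equal(assign_period(as.Date("2014-06-15")), "early")
  expect_equal(assign_period(as.Date("2014-07-01")), "late")
  expect_equal(assign_period(as.Date("2014-12-31")), "late")
  expect_equal(assign_period(as.Date("2014-01-01")), "early")
  days <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = "day")
  p <- assign_period(days)
  expect_true(all(p %in% c("early", "late")))
  expect_equal(sum(p == "early"), sum(months(days) %in% month.name[1:6]))
})

test_that("Corine class codes collapse into the three aggregate classes", {
  expect_equal(aggregate_corine(c(112, 231, 311)),
               c("urban", "rural", "natural"))
  expect_equal(aggregate_corine(c(111, 142, 211, 244, 423)),
               c("urban", "urban", "rural", "rural", "natural"))
  expect_error(aggregate_corine(999), "999")
  expect_error(aggregate_corine(200), "200")
})

test_that("land-use classification picks the dominant class and refuses ties", {
  expect_equal(classify_land_use(c(urban = 0.1, rural = 0.7, natural = 0.2)),
               "rural")
  expect_equal(classify_land_use(c(urban = 1, rural = 0, natural = 0)),
               "urban")
  expect_error(classify_land_use(c(urban = 0.4, rural = 0.4, natural = 0.2)),
               "tie")
  expect_equal(classify_land_use(c(urban = 0.4, rural = 0.4, natural = 0.2),
                                 tie_break = TRUE), "urban")
  expect_error(classify_land_use(c(urban = 0.9, rural = 0.3, natural = 0)),
               "more than 1")
})

test_that("species and host tabulations conserve record counts", {
  ds <- tiny_dataset(
    host_species = c("Homo sapiens", "Homo sapiens", "Capreolus capreolus",
                     "Turdus merula", "Bos taurus"),
    mosquito_taxon = c("Aedes vexans", "Aedes vexans", "Aedes vexans",
                       "Culex torrentium", "Culex torrentium"))
  sp <- tabulate_species_summary(ds)
  expect_equal(sum(sp$n_specimens), 5)
  expect_equal(sp$birds + sp$non_human_mammals + sp$humans, sp$n_specimens)
  expect_equal(sum(sp$pct_specimens), 100)
  ho <- tabulate_host_summary(ds)
  expect_equal(sum(ho$n_specimens), 5)
  gt <- attr(ho, "group_totals")
  expect_equal(sum(gt$n_specimens), 5)
  expect_setequal(gt$host_group, c("bird", "human", "non-human mammal"))
})

test_that("a single-record dataset carries 100 % of the total", {
  ds <- tiny_dataset(host_species = "Homo sapiens")
  sp <- tabulate_species_summary(ds)
  expect_equal(sp$pct_specimens, 100)
  ho <- tabulate_host_summary(ds)
  expect_equal(attr(ho, "group_totals")$pct_specimens, 100)
})

test_that("unidentified hosts are stored but excluded from tabulations", {
  ds <- tiny_dataset(host_species = c("Homo sapiens", "unidentified"))
  expect_equal(nrow(ds$records), 2)
  sp <- tabulate_species_summary(ds)
  expect_equal(sum(sp$n_specimens), 1)
})

test_that("host-range breadth counts denominator taxa with at least one feed", {
  ds <- tiny_dataset(
    host_species = c("Homo sapiens", "Homo sapiens", "Capreolus capreolus"),
    mosquito_taxon = c("Aedes vexans", "Culex torrentium", "Aedes vexans"))
  br <- host_range_breadth(ds, c("Aedes vexans", "Culex torrentium"))
  expect_equal(br$pct_taxa[br$host_species == "Homo sapiens"], 100)
  expect_equal(br$pct_taxa[br$host_species == "Capreolus capreolus"], 50)
  br1 <- host_range_breadth(ds, "Aedes vexans")
  expect_equal(br1$pct_taxa[br1$host_species == "Capreolus capreolus"], 100)
})

test_that("display percentages round half-up to one decimal", {
  expect_equal(round_half_up(46.83871, 1), 46.8)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(19.6129, 1), 19.6)
})
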