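# BarSeq count filtering, enrichment fractions and origin classification.

test_that("the count filter removes strictly-below-threshold rows", {
  counts <- data.frame(sample_id = "s1", barcode = c("b1", "b2", "b3"),
                       count = c(5L, 6L, 100L))
  fc <- filter_counts(counts)
  expect_setequal(fc$counts$barcode, c("b2", "b3"))  # 5 removed, 6 kept
  expect_equal(fc$retained$retained_fraction, 106 / 111)

  all_kept <- data.frame(sample_id = "s1", barcode = c("b1", "b2"),
                         count = c(6L, 10L))
  fc2 <- filter_counts(all_kept)
  expect_identical(fc2$counts$count, all_kept$count)
  expect_equal(fc2$retained$retained_fraction, 1)

  part <- data.frame(sample_id = "s1", barcode = c("b1", "b2", "b3"),
                     count = c(10L, 5L, 85L))
  expect_equal(filter_counts(part)$retained$retained_fraction, 0.95)
})

test_that("filtering is idempotent and flags emptied samples", {
  set.seed(3)
  counts <- data.frame(sample_id = rep(c("s1", "s2"), each = 50),
                       barcode = rep(random_dna(50, 12), 2),
                       count = rpois(100, 8))
  once <- filter_counts(counts)
  twice <- filter_counts(once$counts)
  expect_identical(twice$counts, once$counts)
  expect_true(all(twice$retained$retained_fraction == 1))

  low <- data.frame(sample_id = "s1", barcode = c("b1", "b2"), count = c(2L, 3L))
  expect_warning(fc <- filter_counts(low), "emptied")
  expect_identical(fc$retained$retained_fraction, 0)
  expect_identical(nrow(fc$counts), 0L)
})

test_that("enrichment fractions normalize per sample, unmapped included", {
  assoc <- data.frame(barcode = c("x", "y", "z", "w"),
                      part1 = c("A", "A", "A", "B"),
                      part2 = "p", part3 = "r",
                      support1 = 2L, support2 = 2L, support3 = 2L,
                      status = "mapped", stringsAsFactors = FALSE)
  class(assoc) <- c("assoc_table", "data.frame")

  counts <- data.frame(sample_id = "s1", barcode = c("x", "w"),
                       count = c(30L, 70L))
  enr <- origin_enrichment(counts, assoc)
  fr <- enr$fractions
  expect_equal(fr$fraction[fr$origin == "A"], 0.3)
  expect_equal(fr$fraction[fr$origin == "B"], 0.7)
  expect_equal(enr$per_sample$unmapped_fraction, 0)

  counts2 <- data.frame(sample_id = "s1", barcode = c("x", "unknown_bc"),
                        count = c(50L, 50L))
  enr2 <- origin_enrichment(counts2, assoc)
  expect_equal(enr2$fractions$fraction[enr2$fractions$origin == "A"], 0.5)
  expect_equal(enr2$per_sample$unmapped_fraction, 0.5)
  # mapped-only denominator is available
  enr3 <- origin_enrichment(counts2, assoc, denominator = "mapped")
  expect_equal(enr3$fractions$fraction[enr3$fractions$origin == "A"], 1)

  counts4 <- data.frame(sample_id = "s1", barcode = c("x", "y", "z"),
                        count = c(10L, 20L, 30L))
  enr4 <- origin_enrichment(counts4, assoc)
  expect_identical(enr4$fractions$n_barcodes[enr4$fractions$origin == "A"], 3L)
})

test_that("fractions plus the unmapped fraction sum to one in every sample", {
  set.seed(11)
  for (rep in 1:5) {
    barcodes <- random_dna(60, 10)
    assoc <- data.frame(barcode = barcodes[1:40],
                        part1 = sample(LETTERS[1:6], 40, TRUE),
                        part2 = "p", part3 = "r", support1 = 2L,
                        support2 = 2L, support3 = 2L, status = "mapped",
                        stringsAsFactors = FALSE)
    class(assoc) <- c("assoc_table", "data.frame")
    counts <- expand.grid(sample_id = c("s1", "s2", "s3"),
                          barcode = barcodes, stringsAsFactors = FALSE)
    counts$count <- rpois(nrow(counts), 40)
    enr <- origin_enrichment(counts, assoc)
    sums <- tapply(enr$fractions$fraction, enr$fractions$sample_id, sum) +
      enr$per_sample$unmapped_fraction[
        match(names(tapply(enr$fractions$fraction, enr$fractions$sample_id, sum)),
              enr$per_sample$sample_id)]
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("the monotone-decline detector is strict and order-checked", {
  expect_true(strictly_declining(c(0.04, 0.02, 0.01, 0.005)))
  expect_false(strictly_declining(c(0.04, 0.04, 0.01)))
  expect_false(strictly_declining(c(0.01, 0.02, 0.005)))
  expect_false(strictly_declining(c(0, 0, 0)))
  expect_true(is.na(strictly_declining(0.5)))
})

test_that("origin calls follow the diversity/fraction/trend heuristics", {
  # hand-crafted counts: one host, plate + 4 liquid timepoints
  samples <- data.frame(
    sample_id = c("p", "t1", "t2", "t3", "t4"),
    host = "h", selection = c("plate", rep("liquid", 4)),
    timepoint = c(NA, 1:4))
  lib <- data.frame(
    barcode = c("b1", "b2", "b3",   # FUN: 3 barcodes, strong on plate
                "b4",               # ART: single barcode, strong
                "b5", "b6",         # CAR: declining, low, abundant pool
                "b7"),              # DUD: nothing
    origin = c("FUN", "FUN", "FUN", "ART", "CAR", "CAR", "DUD"))
  assoc <- data.frame(barcode = lib$barcode, part1 = lib$origin,
                      part2 = "p", part3 = "r", support1 = 2L, support2 = 2L,
                      support3 = 2L, status = "mapped",
                      stringsAsFactors = FALSE)
  class(assoc) <- c("assoc_table", "data.frame")
  mk <- function(sid, b1, b2, b3, b4, b5, b6, b7) {
    data.frame(sample_id = sid, barcode = paste0("b", 1:7),
               count = c(b1, b2, b3, b4, b5, b6, b7))
  }
  counts <- rbind(
    mk("p",  300, 250, 200, 150, 20, 20, 0),
    mk("t1", 320, 260, 210, 160, 15, 15, 0),
    mk("t2", 330, 270, 220, 170, 10, 9, 0),
    mk("t3", 340, 280, 230, 180, 7, 6, 0),
    mk("t4", 350, 290, 240, 190, 0, 6, 0))
  enr <- origin_enrichment(counts, assoc, samples = samples)
  pool <- data.frame(origin = c("FUN", "ART", "CAR", "DUD"),
                     n_barcodes = c(10L, 2L, 40L, 3L))
  calls <- classify_origins(enr, pool)
  got <- setNames(calls$call, calls$origin)
  expect_identical(got[["FUN"]], "functional")
  expect_identical(got[["ART"]], "artifact_single_barcode")
  expect_identical(got[["CAR"]], "carryover")
  expect_identical(got[["DUD"]], "not_detected")
  expect_false(any(calls$partial_evidence))
  # every screened origin gets exactly one call for the host
  expect_identical(sort(unique(calls$origin)), sort(pool$origin))
  expect_identical(anyDuplicated(calls[c("origin", "host")]), 0L)
})

test_that("a declining origin outside the abundant pool is not carryover", {
  samples <- data.frame(sample_id = c("p", "t1", "t2", "t3"),
                        host = "h", selection = c("plate", rep("liquid", 3)),
                        timepoint = c(NA, 1:3))
  assoc <- data.frame(barcode = c("b1", "b2", "b3"),
                      part1 = c("X", "X", "Y"), part2 = "p", part3 = "r",
                      support1 = 2L, support2 = 2L, support3 = 2L,
                      status = "mapped", stringsAsFactors = FALSE)
  class(assoc) <- c("assoc_table", "data.frame")
  counts <- rbind(
    data.frame(sample_id = "p", barcode = c("b1", "b2", "b3"), count = c(20, 20, 960)),
    data.frame(sample_id = "t1", barcode = c("b1", "b2", "b3"), count = c(15, 15, 970)),
    data.frame(sample_id = "t2", barcode = c("b1", "b2", "b3"), count = c(10, 10, 980)),
    data.frame(sample_id = "t3", barcode = c("b1", "b2", "b3"), count = c(7, 6, 987)))
  enr <- origin_enrichment(counts, assoc, samples = samples)
  pool_low <- data.frame(origin = c("X", "Y"), n_barcodes = c(2L, 50L))
  calls <- classify_origins(enr, pool_low)
  expect_identical(calls$call[calls$origin == "X"], "not_detected")
  pool_high <- data.frame(origin = c("X", "Y"), n_barcodes = c(60L, 50L))
  calls2 <- classify_origins(enr, pool_high)
  expect_identical(calls2$call[calls2$origin == "X"], "carryover")
})

test_that("short liquid series abstain from the trend test and are flagged", {
  samples <- data.frame(sample_id = c("p", "t1", "t2"), host = "h",
                        selection = c("plate", "liquid", "liquid"),
                        timepoint = c(NA, 1, 2))
  assoc <- data.frame(barcode = c("b1", "b2"), part1 = "X", part2 = "p",
                      part3 = "r", support1 = 2L, support2 = 2L,
                      support3 = 2L, status = "mapped",
                      stringsAsFactors = FALSE)
  class(assoc) <- c("assoc_table", "data.frame")
  counts <- rbind(
    data.frame(sample_id = "p", barcode = c("b1", "b2"), count = c(60, 40)),
    data.frame(sample_id = "t1", barcode = c("b1", "b2"), count = c(50, 30)),
    data.frame(sample_id = "t2", barcode = c("b1", "b2"), count = c(40, 20)))
  enr <- origin_enrichment(counts, assoc, samples = samples)
  calls <- classify_origins(enr, data.frame(origin = "X", n_barcodes = 5L))
  # declining but only 2 timepoints: trend abstains, plate evidence rules
  expect_identical(calls$call, "functional")
  expect_true(calls$partial_evidence)
  expect_true(is.na(calls$liquid_declining))
})

test_that("the rendered matrix TSV round-trips to full precision", {
  assoc <- data.frame(barcode = c("b1", "b2"), part1 = c("A", "B"),
                      part2 = "p", part3 = "r", support1 = 2L, support2 = 2L,
                      support3 = 2L, status = "mapped",
                      stringsAsFactors = FALSE)
  class(assoc) <- c("assoc_table", "data.frame")
  counts <- data.frame(sample_id = rep(c("s1", "s2"), each = 1),
                       barcode = c("b1", "b1"), count = c(7L, 13L))
  enr <- origin_enrichment(counts, assoc)
  path <- withr::local_tempfile(fileext = ".tsv")
  render_matrix(enr, path)
  back <- read_matrix_tsv(path)
  expect_identical(nrow(back), 4L)  # 2 origins x 2 samples
  key <- paste(enr$fractions$origin, enr$fractions$sample_id)
  bkey <- paste(back$origin, back$sample_id)
  expect_true(all(abs(back$fraction - enr$fractions$fraction[match(bkey, key)]) < 1e-9))
  # the all-zero origin B is present with fraction 0 and no barcodes
  expect_true(all(back$fraction[back$origin == "B"] == 0))
  expect_true(all(back$n_barcodes[back$origin == "B"] == 0L))
})

test_that("invalid count tables and sample metadata are rejected", {
  expect_error(filter_counts(data.frame(sample_id = "s", barcode = "b",
                                        count = -1)), "non-negative")
  dup <- data.frame(sample_id = "s", barcode = c("b", "b"), count = c(1L, 2L))
  expect_error(filter_counts(dup), "unique")
  bad_samples <- data.frame(sample_id = "s", host = "h", selection = "liquid",
                            timepoint = NA)
  counts <- data.frame(sample_id = "s", barcode = "b", count = 10L)
  assoc <- structure(data.frame(barcode = "b", part1 = "A", part2 = "p",
                                part3 = "r", support1 = 2L, support2 = 2L,
                                support3 = 2L, status = "mapped",
                                stringsAsFactors = FALSE),
                     class = c("assoc_table", "data.frame"))
  expect_error(origin_enrichment(counts, assoc, samples = bad_samples),
               "timepoint")
})
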