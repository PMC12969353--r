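# Long-read deconvolution: barcode extraction, part identification, and the
# association table's support/conflict rules.

test_that("barcode extraction finds the cassette on either strand, strictly", {
  d <- tiny_design()
  bc <- strrep("ACGT", 5)
  read <- paste0(random_dna(1, 150), d$flank_left, bc, d$flank_right,
                 random_dna(1, 150))
  expect_identical(extract_barcode(read, d)$barcode, bc)
  # minus strand canonicalizes to the same barcode
  expect_identical(extract_barcode(revcomp(read), d)$barcode, bc)
  # intervening length 19 -> none (strict length, indel-shifted dropped)
  short <- paste0(random_dna(1, 150), d$flank_left, substr(bc, 1, 19),
                  d$flank_right, random_dna(1, 150))
  expect_identical(extract_barcode(short, d)$status, "none")
  expect_true(is.na(extract_barcode(short, d)$barcode))
  # ...unless a length tolerance is granted
  expect_identical(extract_barcode(short, d, length_tolerance = 1)$barcode,
                   substr(bc, 1, 19))
})

test_that("flank matching tolerates the allowed edit distance and no more", {
  d <- tiny_design()
  bc <- strrep("TGCA", 5)
  fl <- d$flank_left
  substr(fl, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(fl, 3, 3))[1]
  substr(fl, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(fl, 11, 11))[1]
  read2 <- paste0(random_dna(1, 80), fl, bc, d$flank_right, random_dna(1, 80))
  expect_identical(extract_barcode(read2, d, max_flank_mismatches = 2)$barcode, bc)
  expect_identical(extract_barcode(read2, d, max_flank_mismatches = 1)$status,
                   "none")
})

test_that("two distinct cassettes in one read are flagged ambiguous", {
  d <- tiny_design()
  read <- paste0(random_dna(1, 50),
                 d$flank_left, strrep("A", 20), d$flank_right,
                 random_dna(1, 60),
                 d$flank_left, strrep("C", 20), d$flank_right,
                 random_dna(1, 50))
  res <- extract_barcode(read, d)
  expect_identical(res$status, "ambiguous")
  expect_true(is.na(res$barcode))
})

test_that("a cassette split across the circular junction is still found", {
  d <- tiny_design()
  bc <- strrep("GATC", 5)
  p <- assemble_plasmid(d, tiny_selection, bc)
  n <- nchar(p$sequence)
  rot <- paste0(substr(p$sequence, 31, n), substr(p$sequence, 1, 30))
  expect_identical(extract_barcode(rot, d, circular = TRUE)$barcode, bc)
  expect_identical(extract_barcode(rot, d, circular = FALSE)$status, "none")
})

test_that("an error-free read identifies each part at identity 1", {
  d <- tiny_design()
  p <- assemble_plasmid(d, tiny_selection, strrep("A", 20))
  h <- identify_parts(p$sequence, d)
  expect_identical(vapply(h, `[[`, character(1), "part_id"),
                   c(origin = "oriA", promoter = "promA", resistance = "resA"))
  expect_equal(unname(vapply(h, `[[`, numeric(1), "identity")), rep(1, 3))
  expect_false(any(vapply(h, `[[`, logical(1), "ambiguous")))
  # and on the reverse strand
  h2 <- identify_parts(revcomp(p$sequence), d)
  expect_identical(h2$origin$part_id, "oriA")
})

test_that("planted interior substitutions give the arithmetic identity", {
  # With interior substitutions only, the optimal local alignment keeps all
  # columns, so identity is exactly (len - k) / len; this pins the aligner
  # to the exhaustive-DP answer computable by counting.
  d <- tiny_design()
  p <- assemble_plasmid(d, tiny_selection, strrep("A", 20))
  body <- d$parts$body_seq[d$parts$part_id == "oriA"]
  at <- regexpr(body, p$sequence, fixed = TRUE)[1]
  set.seed(5)
  for (k in c(2L, 5L)) {
    seqc <- strsplit(p$sequence, "")[[1]]
    pos <- at + sample(10:(nchar(body) - 10), k)
    for (i in pos) seqc[i] <- setdiff(c("A", "C", "G", "T"), seqc[i])[1]
    h <- identify_parts(paste(seqc, collapse = ""), d)
    expect_equal(h$origin$identity, (nchar(body) - k) / nchar(body),
                 tolerance = 1e-12)
  }
})

test_that("heavily mutated parts fall below the acceptance thresholds", {
  d <- tiny_design()
  p <- assemble_plasmid(d, tiny_selection, strrep("A", 20))
  seqc <- strsplit(p$sequence, "")[[1]]
  set.seed(17)
  pos <- sample(length(seqc), round(0.12 * length(seqc)))  # 12% substitutions
  for (i in pos) seqc[i] <- setdiff(c("A", "C", "G", "T"), seqc[i])[1]
  h <- identify_parts(paste(seqc, collapse = ""), d)
  expect_null(h$origin)   # expected identity ~0.88 < 0.90 default
})

test_that("a promoter sharing a 160-bp backbone block is flagged ambiguous", {
  d <- example_design(n_origins = 3, n_promoters = 4, n_resistance = 2,
                      confound_promoter = TRUE)
  p <- assemble_plasmid(d, c(origin = "o1", promoter = "p4",
                             resistance = "r1"), strrep("ACGT", 5))
  h <- identify_parts(p$sequence, d)
  expect_true(h$promoter$ambiguous)
  expect_false(h$origin$ambiguous)
  # a clean promoter in the same design is still assigned unambiguously,
  # even though the backbone-derived variant matches every read
  p2 <- assemble_plasmid(d, c(origin = "o2", promoter = "p2",
                              resistance = "r2"), strrep("TTGA", 5))
  h2 <- identify_parts(p2$sequence, d)
  expect_identical(h2$promoter$part_id, "p2")
  expect_false(h2$promoter$ambiguous)
  # and the ambiguous hit never votes in the association
  obs <- map_reads(c(r1 = p$sequence, r2 = p$sequence), d)
  tab <- build_association(obs)
  expect_identical(tab$part2, "UNMAPPED")
  expect_identical(tab$status, "mapped")
})

test_that("support rules: one read is not enough, two are, conflicts kill", {
  tab <- build_association(list(
    # barcode B1: two reads agree on oriA -> mapped
    obs_stub("r1", "B1_AAAAAAAAAAAAAAAAAA", origin = "oriA", promoter = "promA"),
    obs_stub("r2", "B1_AAAAAAAAAAAAAAAAAA", origin = "oriA"),
    # barcode B2: single read -> insufficient support
    obs_stub("r3", "B2_CCCCCCCCCCCCCCCCCC", origin = "oriA"),
    # barcode B3: 2 reads oriA vs 2 reads oriB -> conflict, eliminated
    obs_stub("r4", "B3_GGGGGGGGGGGGGGGGGG", origin = "oriA"),
    obs_stub("r5", "B3_GGGGGGGGGGGGGGGGGG", origin = "oriA"),
    obs_stub("r6", "B3_GGGGGGGGGGGGGGGGGG", origin = "oriB"),
    obs_stub("r7", "B3_GGGGGGGGGGGGGGGGGG", origin = "oriB")),
    drop_error_variants = FALSE)
  tab <- tab[order(tab$barcode), ]
  expect_identical(tab$status,
                   c("mapped", "insufficient_support", "conflict_eliminated"))
  expect_identical(tab$part1, c("oriA", "UNASSIGNED", "UNASSIGNED"))
  # part2 may stay unmapped on a mapped row (support 1 < 2)
  expect_identical(tab$part2[1], "UNMAPPED")
  expect_identical(tab$support1, c(2L, 1L, 2L))
})

test_that("duplicate votes from one read count once", {
  tab <- build_association(list(
    obs_stub("r1", strrep("A", 20), origin = "oriA"),
    obs_stub("r1", strrep("A", 20), origin = "oriA")),
    drop_error_variants = FALSE)
  expect_identical(tab$status, "insufficient_support")
})

test_that("association tallying is order-independent", {
  obs <- list(
    obs_stub("r1", strrep("A", 20), origin = "oriA", promoter = "pA"),
    obs_stub("r2", strrep("A", 20), origin = "oriA", resistance = "rA"),
    obs_stub("r3", strrep("C", 20), origin = "oriB"),
    obs_stub("r4", strrep("C", 20), origin = "oriB"),
    obs_stub("r5", strrep("G", 20), origin = "oriA"))
  t1 <- build_association(obs)
  set.seed(9)
  for (i in 1:5) {
    t2 <- build_association(sample(obs))
    expect_identical(t2, t1)
  }
})

test_that("phantom barcodes one edit from a real one are filtered", {
  real <- strrep("ACGT", 5)
  phantom <- paste0("T", substr(real, 2, 20))
  obs <- c(lapply(1:5, function(i) obs_stub(paste0("t", i), real, origin = "oriA")),
           lapply(1:2, function(i) obs_stub(paste0("p", i), phantom, origin = "oriA")))
  tab <- build_association(obs)
  expect_identical(tab$barcode, real)
  # exact-key behaviour is recoverable
  tab2 <- build_association(obs, drop_error_variants = FALSE)
  expect_setequal(tab2$barcode, c(real, phantom))
  expect_identical(tab2$status, rep("mapped", 2))
})

test_that("no mapped barcode carries two origins; summaries tally statuses", {
  obs <- list(
    obs_stub("r1", strrep("A", 20), origin = "oriA"),
    obs_stub("r2", strrep("A", 20), origin = "oriA"),
    obs_stub("r3", strrep("C", 20), origin = "oriB"),
    obs_stub("r4", strrep("C", 20), origin = "oriB"),
    obs_stub("r5", strrep("G", 20), origin = "oriB"),
    obs_stub("r6", strrep("G", 20), origin = "oriB"))
  tab <- build_association(obs, drop_error_variants = FALSE)
  expect_identical(anyDuplicated(tab$barcode[tab$status == "mapped"]), 0L)
  s <- summarize_map(tab)
  expect_identical(s$per_origin,
                   data.frame(origin = c("oriA", "oriB"),
                              n_barcodes = c(1L, 2L)))
  expect_identical(unname(s$status_counts["mapped"]), 3L)
  expect_warning(empty <- build_association(list()), "no observations")
  expect_identical(nrow(empty), 0L)
})

test_that("association tables survive a TSV round trip", {
  obs <- list(obs_stub("r1", strrep("A", 20), origin = "oriA", promoter = "pX"),
              obs_stub("r2", strrep("A", 20), origin = "oriA", promoter = "pX"))
  tab <- build_association(obs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assoc_tsv(tab, path)
  back <- read_assoc_tsv(path)
  expect_identical(back$barcode, tab$barcode)
  expect_identical(back$part1, tab$part1)
  expect_identical(back$status, tab$status)
})

test_that("small-pool deconvolution recovers the truth end to end", {
  d <- example_design(n_origins = 5, n_promoters = 3, n_resistance = 2,
                      origin_length = 150, backbone_stuffer = 500)
  sim <- simulate_library(d, 25, skew = 0, seed = 31, assemble = TRUE)
  lr <- simulate_long_reads(sim$plasmids, sim$truth, depth_per_barcode = 8,
                            sub_rate = 0.01, indel_rate = 0.005,
                            chimera_rate = 0.02, weight_by_abundance = FALSE,
                            seed = 32)
  tab <- build_association(map_reads(lr$reads, d))
  sc <- score_association(tab, sim$truth)
  expect_gte(sc$precision, 0.99)
  expect_gte(sc$recall, 0.9)
})
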