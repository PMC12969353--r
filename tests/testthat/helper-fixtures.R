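# Shared fixtures, built in code at test time.

# A minimal hand-built design with known sequences: four 100-nt bodies and
# chained 4-nt junctions; the backbone carries the barcode slot.
tiny_design <- function(barcode_length = 20L) {
  set.seed(424242)
  fl <- random_dna(1, 20)
  fr <- random_dna(1, 20)
  bb_body <- paste0(random_dna(1, 30), fl, fr, random_dna(1, 30))
  parts <- rbind(
    pool_part("oriA", "origin", random_dna(1, 100), "AAAA", "CCCC"),
    pool_part("oriB", "origin", random_dna(1, 100), "AAAA", "CCCC"),
    pool_part("promA", "promoter", random_dna(1, 100), "CCCC", "GGGG"),
    pool_part("resA", "resistance", random_dna(1, 100), "GGGG", "TTTT"),
    pool_part("bb", "backbone", bb_body, "TTTT", "AAAA"))
  library_design(parts, fl, fr, barcode_length)
}

tiny_selection <- c(origin = "oriA", promoter = "promA", resistance = "resA")

# Observation stubs for build_association tests: one observation per
# (read_id, barcode, origin vote).
obs_stub <- function(read_id, barcode, origin = NULL, promoter = NULL,
                     resistance = NULL) {
  hit <- function(p) if (is.null(p)) NULL else
    list(part_id = p, identity = 1, ambiguous = FALSE)
  list(read_id = read_id, barcode = barcode, barcode_status = "ok",
       part_hits = list(origin = hit(origin), promoter = hit(promoter),
                        resistance = hit(resistance)),
       complete = !is.null(origin) && !is.null(promoter) && !is.null(resistance))
}

# A mapped-only association table mapping each barcode to its true parts.
assoc_from_truth <- function(truth) {
  lib <- truth$library
  out <- data.frame(barcode = lib$barcode, part1 = lib$origin,
                    part2 = lib$promoter, part3 = lib$resistance,
                    support1 = 2L, support2 = 2L, support3 = 2L,
                    status = "mapped", stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

# Ground truth for the origin-classification scenario: origins planted as
# functional (multi-barcode, fit), donor-carryover (nonfunctional but
# abundant in the pool), dud (nonfunctional, scarce), and a single-barcode
# artifact (fit but represented by one abundant barcode).
classification_truth <- function(seed) {
  set.seed(seed)
  origins <- c(paste0("F", 1:4), paste0("C", 1:3), paste0("D", 1:2), "ART")
  nbc <- c(rep(8, 4), rep(15, 3), rep(5, 2), 1)
  lib <- data.frame(barcode = random_dna(sum(nbc), 20),
                    origin = rep(origins, nbc), promoter = "p1",
                    resistance = "r1", stringsAsFactors = FALSE)
  ab <- stats::rlnorm(nrow(lib), 0, 0.3)
  carry <- lib$origin %in% c("C1", "C2", "C3")
  # Boost chosen so each planted carryover origin lands at ~3% of plate
  # counts: clearly low (the class is defined by sub-threshold fractions)
  # yet abundant enough that its barcodes survive the count filter through
  # the late liquid timepoints.
  ab[carry] <- ab[carry] * 2.5
  ab[lib$origin == "ART"] <- sum(ab) * 0.12
  lib$abundance <- ab / sum(ab)
  structure(list(library = lib, seed = seed, config = list(),
                 host_profiles = NULL, carryover = NULL,
                 true_copy_numbers = NULL), class = "ground_truth")
}

classification_profiles <- data.frame(
  host = "hostA", origin = c("F1", "F2", "F3", "F4", "ART"), fitness = 1,
  stringsAsFactors = FALSE)

classification_expected <- c(
  F1 = "functional", F2 = "functional", F3 = "functional", F4 = "functional",
  C1 = "carryover", C2 = "carryover", C3 = "carryover",
  D1 = "not_detected", D2 = "not_detected", ART = "artifact_single_barcode")

# One classification run: simulate counts, filter, enrich, classify; returns
# named calls.
run_classification <- function(seed) {
  tr <- classification_truth(1000 + seed)
  bs <- simulate_barseq(tr, classification_profiles, seed = 2000 + seed)
  fc <- filter_counts(bs$counts)
  enr <- origin_enrichment(fc$counts, assoc_from_truth(tr), samples = bs$samples)
  pool <- as.data.frame(table(origin = tr$library$origin),
                        stringsAsFactors = FALSE)
  names(pool)[2] <- "n_barcodes"
  calls <- classify_origins(enr, pool)
  stats::setNames(calls$call, calls$origin)
}

# Logistic amplification curve with baseline and noise, for efficiency
# estimator tests.
logistic_curve <- function(A, f0 = 1e-6, cycles = 40, baseline = 0.02,
                           mult_noise = 0, baseline_sd = 0) {
  cyc <- seq_len(cycles)
  sig <- 1 / (1 + (1 / f0 - 1) * A^(-cyc))
  baseline + sig * (1 + stats::rnorm(cycles, 0, mult_noise)) +
    stats::rnorm(cycles, 0, baseline_sd)
}
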