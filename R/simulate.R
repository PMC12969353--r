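# Ground-truthed synthetic data for every pipeline stage: a skewed barcoded
# library, error-bearing long reads of the circular plasmids, BarSeq count
# dynamics under host-specific origin fitness with donor carryover, and
# qPCR amplification curves. Each generator is fully reproducible from its
# arguments plus `seed`, and records both in its output.

BASES <- c("A", "C", "G", "T")

#' Simulate a barcoded magic pool library
#'
#' Draws `n_barcodes` unique random barcodes, assigns each a uniformly
#' random part selection, and gives each member a log-normal relative
#' abundance. Abundances of members whose origin is in `high_copy_origins`
#' are multiplied by `boost` before renormalization, emulating the
#' disproportionate abundance of high-copy origins (e.g. colE1) in a real
#' pool.
#'
#' @param design An [library_design()] object.
#' @param n_barcodes Number of library members (>= 1).
#' @param skew Log-normal sigma of the abundance distribution (0 = uniform).
#' @param high_copy_origins Character vector of origin part_ids whose
#'   members are boosted.
#' @param boost Abundance multiplier for high-copy members (default 10).
#' @param seed RNG seed.
#' @param assemble If `TRUE` (default) also assemble full plasmid records.
#' @return A list with `truth` (class `ground_truth`: `$library` is a
#'   `data.frame` of barcode, origin, promoter, resistance, abundance) and
#'   `plasmids` (list of `oripool_plasmid`, or `NULL`).
#' @export
simulate_library <- function(design, n_barcodes, skew = 0.5,
                             high_copy_origins = character(0), boost = 10,
                             seed = 1L, assemble = TRUE) {
  stopifnot(inherits(design, "oripool_design"), n_barcodes >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  barcodes <- character(0)
  tries <- 0L
  while (length(barcodes) < n_barcodes) {
    need <- n_barcodes - length(barcodes)
    barcodes <- unique(c(barcodes, random_dna(need, design$barcode_length)))
    tries <- tries + 1L
    if (tries > 100L)
      .stopf("could not draw %d unique barcodes of length %d", n_barcodes,
             design$barcode_length)
  }

  pick <- function(cat) sample(.parts_of(design, cat)$part_id, n_barcodes, replace = TRUE)
  lib <- data.frame(barcode = barcodes, origin = pick("origin"),
                    promoter = pick("promoter"), resistance = pick("resistance"),
                    stringsAsFactors = FALSE)
  ab <- stats::rlnorm(n_barcodes, 0, skew)
  ab[lib$origin %in% high_copy_origins] <- ab[lib$origin %in% high_copy_origins] * boost
  lib$abundance <- ab / sum(ab)

  plasmids <- NULL
  if (assemble) {
    plasmids <- lapply(seq_len(n_barcodes), function(i) {
      assemble_plasmid(design,
                       c(origin = lib$origin[i], promoter = lib$promoter[i],
                         resistance = lib$resistance[i]),
                       lib$barcode[i], plasmid_id = sprintf("mp%04d", i))
    })
  }
  truth <- structure(list(library = lib, seed = seed,
                          config = list(n_barcodes = n_barcodes, skew = skew,
                                        high_copy_origins = high_copy_origins,
                                        boost = boost),
                          host_profiles = NULL, carryover = NULL,
                          true_copy_numbers = NULL),
                     class = "ground_truth")
  list(truth = truth, plasmids = plasmids)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d barcodes over %d origins (seed %s)\n",
              nrow(x$library), length(unique(x$library$origin)),
              format(x$seed)))
  invisible(x)
}

# Apply substitutions and indels to a character vector of single bases;
# insertions become two-character elements, resolved by the final paste.
.mutate_chars <- function(chars, sub_rate, indel_rate) {
  n <- length(chars)
  if (sub_rate > 0) {
    subs <- which(stats::runif(n) < sub_rate)
    if (length(subs))
      chars[subs] <- vapply(chars[subs],
                            function(b) sample(setdiff(BASES, b), 1L), character(1))
  }
  if (indel_rate > 0) {
    ind <- stats::runif(n) < indel_rate
    if (any(ind)) {
      del <- ind & stats::runif(n) < 0.5
      ins <- ind & !del
      if (any(ins))
        chars[ins] <- paste0(chars[ins], sample(BASES, sum(ins), replace = TRUE))
      if (any(del)) chars <- chars[!del]
    }
  }
  chars
}

#' Simulate long reads of the pooled circular library
#'
#' Each read picks a library member (by abundance, or uniformly), takes its
#' full circular sequence at a uniform random rotation on a random strand,
#' and applies per-base substitutions and indels. With probability
#' `chimera_rate` the first half of the read is spliced to the second half
#' of a different member's read. Per-member read counts are Poisson with
#' total expectation `n_barcodes * depth_per_barcode`.
#'
#' @param plasmids Assembled plasmid records from [simulate_library()].
#' @param truth The matching `ground_truth`.
#' @param depth_per_barcode Expected reads per library member.
#' @param sub_rate,indel_rate,chimera_rate Error rates in [0, 0.2].
#' @param weight_by_abundance If `TRUE` (default) read counts follow member
#'   abundance; if `FALSE` every member has expectation
#'   `depth_per_barcode` regardless of abundance.
#' @param seed RNG seed.
#' @param path Optional FASTQ output path (gz-transparent via extension).
#' @return A list with `reads` (named `DNAStringSet`) and `read_info`
#'   (`data.frame`: read_id, barcode, strand, rotation, chimera,
#'   chimera_partner).
#' @export
simulate_long_reads <- function(plasmids, truth, depth_per_barcode = 10,
                                sub_rate = 0.01, indel_rate = 0.005,
                                chimera_rate = 0.02,
                                weight_by_abundance = TRUE, seed = 1L,
                                path = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (sub_rate < 0 || sub_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2)
    .stopf("sub_rate and indel_rate must lie in [0, 0.2]")
  if (chimera_rate < 0 || chimera_rate > 1)
    .stopf("chimera_rate must lie in [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  lib <- truth$library
  n <- nrow(lib)
  lambda <- if (weight_by_abundance) n * depth_per_barcode * lib$abundance
            else rep(depth_per_barcode, n)
  n_reads_per <- stats::rpois(n, lambda)
  src <- rep(seq_len(n), n_reads_per)
  total <- length(src)
  if (total == 0) .stopf("no reads drawn; increase depth_per_barcode")
  src <- sample(src)  # shuffle read order

  seqs <- vapply(plasmids, `[[`, character(1), "sequence")
  info <- data.frame(read_id = sprintf("read%06d", seq_len(total)),
                     barcode = lib$barcode[src],
                     strand = sample(c("+", "-"), total, replace = TRUE),
                     rotation = NA_integer_, chimera = FALSE,
                     chimera_partner = NA_character_, stringsAsFactors = FALSE)
  out <- character(total)
  for (k in seq_len(total)) {
    i <- src[k]
    s <- seqs[i]
    rot <- sample.int(nchar(s), 1L)
    info$rotation[k] <- rot
    r <- .rotate_seq(s, rot)
    if (n > 1 && stats::runif(1) < chimera_rate) {
      j <- sample(setdiff(seq_len(n), i), 1L)
      s2 <- seqs[j]
      r2 <- .rotate_seq(s2, sample.int(nchar(s2), 1L))
      r <- paste0(substr(r, 1L, nchar(r) %/% 2L),
                  substr(r2, nchar(r2) %/% 2L + 1L, nchar(r2)))
      info$chimera[k] <- TRUE
      info$chimera_partner[k] <- lib$barcode[j]
    }
    if (info$strand[k] == "-") r <- revcomp(r)
    chars <- strsplit(r, "", fixed = TRUE)[[1]]
    out[k] <- paste(.mutate_chars(chars, sub_rate, indel_rate), collapse = "")
  }
  reads <- Biostrings::DNAStringSet(stats::setNames(out, info$read_id))
  if (!is.null(path)) Biostrings::writeXStringSet(reads, path, format = "fastq")
  list(reads = reads, read_info = info)
}

#' Simulate BarSeq count dynamics under selection
#'
#' Models the screen at the founder level: for each host, roughly
#' `n_colonies` founders are drawn multinomially with probability
#' proportional to `abundance * functional + carryover_fraction * abundance`
#' (members nonfunctional in the host contribute only passive donor
#' carryover). Plate-mode samples draw read counts over the founders;
#' liquid-mode samples update replicating founder frequencies each passage
#' by `p <- p*w / sum(p*w)` with a multinomial bottleneck (back-dilution),
#' while the carryover component decays geometrically by `carryover_decay`
#' per passage. Read counts per sample are multinomial with total
#' `reads_per_sample`.
#'
#' @param truth A `ground_truth` from [simulate_library()].
#' @param host_profiles `data.frame` with columns `host`, `origin`,
#'   `fitness` (w >= 0; an origin is functional in a host iff w > 0;
#'   origins absent from the table are nonfunctional).
#' @param n_colonies Founder colonies per experiment (default 5000).
#' @param reads_per_sample Reads per BarSeq sample. The default 1e5 is a
#'   scaled-down setting so the whole pipeline runs in seconds; the
#'   full-scale screen depth of 4e6 reads/sample (~800x per colony) is
#'   supported by setting this argument accordingly.
#' @param passages Number of liquid serial passages (timepoints; default 4,
#'   i.e. 24/48/72/96 h).
#' @param bottleneck_frac Fraction of the grown population transferred at
#'   each back-dilution (default 1/21, i.e. 500 uL into 10 mL + 500 uL).
#' @param pop_size Grown population size before back-dilution (sets drift
#'   strength; default 2.1e6 so the bottleneck passes 1e5 cells).
#' @param carryover_fraction Scalar or per-origin named vector: passive
#'   donor-material weight relative to abundance (default 0.05).
#' @param carryover_decay Geometric decay of the carryover component per
#'   passage (default 0.3).
#' @param seed RNG seed.
#' @return A list with `counts` (`sample_id`, `barcode`, `count`; nonzero
#'   rows), `samples` (metadata: `sample_id`, `host`, `selection`,
#'   `timepoint`) and `truth` (input truth with `host_profiles` and
#'   `carryover` recorded).
#' @export
simulate_barseq <- function(truth, host_profiles, n_colonies = 5000,
                            reads_per_sample = 1e5, passages = 4L,
                            bottleneck_frac = 1 / 21, pop_size = 2.1e6,
                            carryover_fraction = 0.05, carryover_decay = 0.3,
                            seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), passages >= 1)
  if (!all(c("host", "origin", "fitness") %in% names(host_profiles)))
    .stopf("host_profiles must have columns host, origin, fitness")
  if (any(host_profiles$fitness < 0)) .stopf("fitness must be >= 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  lib <- truth$library
  nb <- nrow(lib)
  gamma <- if (length(carryover_fraction) == 1 && is.null(names(carryover_fraction))) {
    rep(carryover_fraction, nb)
  } else {
    g <- carryover_fraction[lib$origin]
    g[is.na(g)] <- 0
    as.numeric(g)
  }
  n_bottle <- max(1L, round(pop_size * bottleneck_frac))

  counts_rows <- list(); samples_rows <- list()
  add_sample <- function(sid, host, selection, timepoint, probs) {
    cnt <- as.integer(stats::rmultinom(1, reads_per_sample, probs))
    keep <- cnt > 0
    counts_rows[[length(counts_rows) + 1L]] <<- data.frame(
      sample_id = sid, barcode = lib$barcode[keep], count = cnt[keep],
      stringsAsFactors = FALSE)
    samples_rows[[length(samples_rows) + 1L]] <<- data.frame(
      sample_id = sid, host = host, selection = selection,
      timepoint = timepoint, stringsAsFactors = FALSE)
  }

  for (host in unique(host_profiles$host)) {
    hp <- host_profiles[host_profiles$host == host, ]
    w <- stats::setNames(hp$fitness, hp$origin)[lib$origin]
    w[is.na(w)] <- 0
    func <- w > 0
    p0 <- lib$abundance * as.numeric(func) + gamma * lib$abundance
    if (sum(p0) == 0) .stopf("no viable founders for host '%s'", host)
    p0 <- p0 / sum(p0)

    draw_founders <- function() as.numeric(stats::rmultinom(1, n_colonies, p0))

    # Plate-derived samples: direct harvest, then one liquid outgrowth.
    Fp <- draw_founders()
    add_sample(paste0(host, "_plate"), host, "plate", NA_integer_, Fp / sum(Fp))
    m0 <- sum(Fp[!func]) / sum(Fp)
    g <- if (any(func) && sum(Fp[func]) > 0) {
      x <- Fp * as.numeric(func) * w; if (sum(x) > 0) x / sum(x) else Fp * as.numeric(func) / sum(Fp[func])
    } else rep(0, nb)
    cvec <- if (sum(Fp[!func]) > 0) Fp * as.numeric(!func) / sum(Fp[!func]) else rep(0, nb)
    u <- (1 - m0) * g + m0 * carryover_decay * cvec
    add_sample(paste0(host, "_outgrowth"), host, "plate_outgrowth", NA_integer_,
               u / sum(u))

    # Liquid serial passages from an independent founder draw.
    Fl <- draw_founders()
    m0 <- sum(Fl[!func]) / sum(Fl)
    g <- if (sum(Fl[func]) > 0) Fl * as.numeric(func) / sum(Fl[func]) else rep(0, nb)
    cvec <- if (sum(Fl[!func]) > 0) Fl * as.numeric(!func) / sum(Fl[!func]) else rep(0, nb)
    for (t in seq_len(passages)) {
      if (sum(g * w) > 0) g <- g * w / sum(g * w)
      u <- (1 - m0) * g + m0 * carryover_decay^t * cvec
      add_sample(paste0(host, "_T", t), host, "liquid", t, u / sum(u))
      if (sum(g) > 0) {
        G <- as.numeric(stats::rmultinom(1, n_bottle, g))
        g <- G / sum(G)
      }
    }
  }
  truth$host_profiles <- host_profiles
  truth$carryover <- list(fraction = carryover_fraction, decay = carryover_decay)
  list(counts = do.call(rbind, counts_rows),
       samples = do.call(rbind, samples_rows), truth = truth)
}

#' Simulate paired qPCR amplification curves for a copy-number experiment
#'
#' Generates gDNA and plasmid amplification curves for each (biological
#' replicate, dilution, technical replicate) well under the
#' efficiency-corrected delta-Ct model: each curve grows by its target's
#' per-cycle factor from a starting level chosen so that, at the nominal
#' threshold, the plasmid/gDNA Ct difference encodes
#' `-log2(true_cn * a_gdna / a_plasmid)`. Growth saturates at `plateau` via
#' a logistic cap; measurement adds a flat baseline with additive noise and
#' multiplicative signal noise; per-well Ct jitter is injected by perturbing
#' the starting level by `A^N(0, ct_noise_sd)` (i.e. an SD of
#' `ct_noise_sd` cycles).
#'
#' @param true_cn True relative copy number (> 0).
#' @param a_gdna,a_plasmid Per-cycle amplification factors in (1, 2.2].
#' @param f0_gdna Undiluted gDNA starting signal (relative to plateau 1).
#' @param plateau Saturation level.
#' @param baseline,baseline_sd Flat measurement baseline and its additive
#'   noise SD.
#' @param mult_noise Multiplicative signal noise SD (fraction).
#' @param ct_noise_sd Per-well Ct jitter SD in cycles (default 0.15).
#' @param cycles Number of cycles (default 40).
#' @param n_replicates,dilutions,tech_reps Plate design: biological
#'   replicates x dilution series x technical replicates (defaults 3 x
#'   (1, 1/2, 1/4, 1/8) x 3).
#' @param sample Sample label.
#' @param seed RNG seed.
#' @return A list with `curves` (long `data.frame`: well_id, cycle, value),
#'   `wells` (annotation: well_id, target, sample, replicate, dilution),
#'   and `truth` (arguments incl. seed).
#' @export
simulate_qpcr <- function(true_cn, a_gdna = 2, a_plasmid = 2, f0_gdna = 5e-8,
                          plateau = 1, baseline = 0.02, baseline_sd = 2e-4,
                          mult_noise = 0.01, ct_noise_sd = 0.15, cycles = 40L,
                          n_replicates = 3L, dilutions = c(1, 1/2, 1/4, 1/8),
                          tech_reps = 3L, sample = "sample1", seed = 1L) {
  stopifnot(true_cn > 0)
  for (a in c(a_gdna, a_plasmid))
    if (a <= 1 || a > 2.2) .stopf("amplification factors must lie in (1, 2.2]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  t0 <- 0.05 * plateau  # nominal threshold used to anchor the Ct geometry
  cyc <- seq_len(cycles)
  wells <- list(); curves <- list()
  for (rep_i in seq_len(n_replicates)) for (d in seq_along(dilutions)) {
    f0g <- f0_gdna * dilutions[d]
    ct_g_ideal <- log(t0 / f0g) / log(a_gdna)
    ct_p_ideal <- ct_g_ideal - log2(true_cn * a_plasmid / a_gdna)
    f0p <- t0 * a_plasmid^(-ct_p_ideal)
    for (tech in seq_len(tech_reps)) for (tg in c("gDNA", "plasmid")) {
      A <- if (tg == "gDNA") a_gdna else a_plasmid
      f0 <- (if (tg == "gDNA") f0g else f0p) * A^stats::rnorm(1, 0, ct_noise_sd)
      signal <- plateau / (1 + (plateau / f0 - 1) * A^(-cyc))
      value <- baseline + signal * (1 + stats::rnorm(cycles, 0, mult_noise)) +
        stats::rnorm(cycles, 0, baseline_sd)
      wid <- sprintf("%s_r%d_d%d_t%d_%s", sample, rep_i, d, tech, tg)
      wells[[length(wells) + 1L]] <- data.frame(
        well_id = wid, target = tg, sample = sample, replicate = rep_i,
        dilution = dilutions[d], tech_rep = tech, stringsAsFactors = FALSE)
      curves[[length(curves) + 1L]] <- data.frame(
        well_id = wid, cycle = cyc, value = value, stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, curves), wells = do.call(rbind, wells),
       truth = list(true_cn = true_cn, a_gdna = a_gdna, a_plasmid = a_plasmid,
                    ct_noise_sd = ct_noise_sd, seed = seed))
}

#' Simulate an instrument-exported colony-qPCR well table
#'
#' Direct Ct + per-well efficiency records (the instrument-export entry
#' path of [estimate_copy_number()]) for one or more samples with known
#' true copy numbers, on the standard 3 biological replicates x 4 dilutions
#' x 3 technical replicates design. This is a synthetic stand-in table: it
#' emulates the schema and structure of a real colony-qPCR export for
#' samples whose true copy numbers are chosen by the caller.
#'
#' @param true_cn Named numeric vector: sample label -> true copy number.
#' @param a_gdna,a_plasmid Amplification factors (recycled over samples).
#' @param ct_gdna_base Undiluted gDNA Ct (cycles).
#' @param ct_noise_sd Per-well Ct noise SD in cycles.
#' @param efficiency_sd Per-well noise SD of the reported efficiency factor.
#' @param n_replicates,dilutions,tech_reps Plate design.
#' @param seed RNG seed.
#' @return A wells `data.frame` ready for [estimate_copy_number()].
#' @export
simulate_colony_qpcr_table <- function(true_cn, a_gdna = 1.95, a_plasmid = 1.9,
                                       ct_gdna_base = 22, ct_noise_sd = 0.02,
                                       efficiency_sd = 0.01, n_replicates = 3L,
                                       dilutions = c(1, 1/2, 1/4, 1/8),
                                       tech_reps = 3L, seed = 1L) {
  stopifnot(!is.null(names(true_cn)), all(true_cn > 0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a_g <- rep_len(a_gdna, length(true_cn))
  a_p <- rep_len(a_plasmid, length(true_cn))
  rows <- list()
  for (si in seq_along(true_cn)) {
    sm <- names(true_cn)[si]
    for (rep_i in seq_len(n_replicates)) for (d in seq_along(dilutions)) {
      ct_g0 <- ct_gdna_base - log(dilutions[d]) / log(a_g[si])
      ct_p0 <- ct_g0 - log2(true_cn[si] * a_p[si] / a_g[si])
      for (tech in seq_len(tech_reps)) for (tg in c("gDNA", "plasmid")) {
        ct <- (if (tg == "gDNA") ct_g0 else ct_p0) + stats::rnorm(1, 0, ct_noise_sd)
        A <- (if (tg == "gDNA") a_g[si] else a_p[si]) + stats::rnorm(1, 0, efficiency_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          well_id = sprintf("%s_r%d_d%d_t%d_%s", sm, rep_i, d, tech, tg),
          target = tg, sample = sm, replicate = rep_i,
          dilution = dilutions[d], Ct = ct, efficiency = A,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
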