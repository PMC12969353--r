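# Long-read deconvolution: locate the barcode cassette in each read, identify
# which part variants the read carries, and tally reads into a
# barcode -> (part1, part2, part3) association table under the support and
# conflict-elimination rules.
#
# Part identification is seed-and-extend: exact k-mer tags drawn from each
# part body are matched against the read (PDict), and each candidate part is
# then scored by a full local dynamic-programming alignment (Biostrings) of
# the part body against the tagged read window. On reads of a few kb this is
# equivalent to aligning against the whole read, at a fraction of the cost.

UNASSIGNED <- "UNASSIGNED"
UNMAPPED <- "UNMAPPED"

#' Build a part-matching index for a design
#'
#' Precomputes the exact-match seed tags used to shortlist candidate parts
#' per read. Built automatically by [map_reads()]; exposed so repeated calls
#' to [identify_parts()] can share one index.
#'
#' @param design An [library_design()] object.
#' @param tag_width Seed tag length (nt).
#' @param tag_step Spacing between consecutive tags along a part body (nt).
#' @return An opaque index object.
#' @export
part_index <- function(design, tag_width = 24L, tag_step = 32L) {
  stopifnot(inherits(design, "oripool_design"))
  tags <- character(0); owner <- character(0); offset <- integer(0)
  for (i in seq_len(nrow(design$parts))) {
    body <- design$parts$body_seq[i]
    n <- nchar(body)
    if (n < tag_width) next
    starts <- unique(c(seq(1L, n - tag_width + 1L, by = tag_step), n - tag_width + 1L))
    tags <- c(tags, substring(body, starts, starts + tag_width - 1L))
    owner <- c(owner, rep(design$parts$part_id[i], length(starts)))
    offset <- c(offset, starts - 1L)
  }
  # Parts sharing sequence (e.g. a promoter carrying a backbone block) share
  # tags: the dictionary holds each distinct tag once, and tag_idx maps every
  # (part, offset) claim onto it, so a shared tag seeds all its owners.
  uniq <- unique(tags)
  structure(list(pdict = Biostrings::PDict(Biostrings::DNAStringSet(uniq)),
                 tag_idx = match(tags, uniq), owner = owner, offset = offset,
                 tag_width = as.integer(tag_width),
                 submat = Biostrings::nucleotideSubstitutionMatrix(
                   match = 1, mismatch = -1, baseOnly = FALSE),
                 category = stats::setNames(design$parts$category, design$parts$part_id),
                 body = stats::setNames(design$parts$body_seq, design$parts$part_id),
                 backbone_id = design$parts$part_id[design$parts$category == "backbone"]),
            class = "oripool_part_index")
}

# Collapse overlapping approximate matches of a flank into one representative
# range per site (the first reported).
.collapse_matches <- function(m) {
  if (length(m) == 0) return(data.frame(start = integer(0), end = integer(0)))
  r <- IRanges::reduce(IRanges::IRanges(Biostrings::start(m), Biostrings::end(m)),
                       with.revmap = TRUE)
  first <- vapply(S4Vectors::mcols(r)$revmap, `[`, integer(1), 1L)
  data.frame(start = Biostrings::start(m)[first], end = Biostrings::end(m)[first])
}

#' Extract the barcode from one long read
#'
#' Locates the two priming sites flanking the random barcode (each allowing
#' up to `max_flank_mismatches` substitutions or indels by edit distance) on
#' either strand, and returns the intervening sequence on the canonical
#' (flank_left -> flank_right) strand. The intervening length must equal the
#' design barcode length within `length_tolerance` (default 0: indel-shifted
#' barcodes are dropped, not corrected).
#'
#' @param read Read sequence (character) or a `DNAString`.
#' @param design An [library_design()] object.
#' @param max_flank_mismatches Edit-distance allowance per flank.
#' @param length_tolerance Allowed deviation of the intervening length from
#'   `design$barcode_length` (default 0, strict).
#' @param circular If `TRUE`, also search across the read's end-to-start
#'   junction (appropriate for full-length reads of circular molecules).
#' @return A list with `barcode` (`NA_character_` if not found) and `status`
#'   (`"ok"`, `"none"`, or `"ambiguous"` when several distinct flank-pair
#'   matches occur in one read).
#' @export
extract_barcode <- function(read, design, max_flank_mismatches = 2L,
                            length_tolerance = 0L, circular = FALSE) {
  stopifnot(inherits(design, "oripool_design"))
  read <- as.character(read)
  if (!.is_dna(read, allow_n = TRUE))
    return(list(barcode = NA_character_, status = "none"))
  bl <- design$barcode_length
  lfl <- nchar(design$flank_left); lfr <- nchar(design$flank_right)
  wrap <- lfl + bl + length_tolerance + lfr + 2L * max_flank_mismatches

  found <- character(0)
  for (s in c(read, revcomp(read))) {
    subj <- if (circular && nchar(s) > wrap) paste0(s, substr(s, 1L, wrap)) else s
    subj <- Biostrings::DNAString(subj)
    ml <- .collapse_matches(Biostrings::matchPattern(
      design$flank_left, subj, max.mismatch = max_flank_mismatches,
      with.indels = TRUE))
    if (!nrow(ml)) next
    mr <- .collapse_matches(Biostrings::matchPattern(
      design$flank_right, subj, max.mismatch = max_flank_mismatches,
      with.indels = TRUE))
    if (!nrow(mr)) next
    for (i in seq_len(nrow(ml))) {
      if (circular && ml$start[i] > nchar(s)) next  # only anchor in the original copy
      gaps <- mr$start - ml$end[i] - 1L
      ok <- which(gaps >= 1L & abs(gaps - bl) <= length_tolerance)
      for (j in ok) {
        found <- c(found, substr(as.character(subj), ml$end[i] + 1L, mr$start[j] - 1L))
      }
    }
  }
  found <- found[.is_dna(found)]  # non-ACGT (e.g. N) invalidates a barcode
  if (length(found) == 0) return(list(barcode = NA_character_, status = "none"))
  if (length(unique(found)) > 1) return(list(barcode = NA_character_, status = "ambiguous"))
  list(barcode = found[1], status = "ok")
}

# Local alignment of a part body against a read window; returns identity
# (matches / alignment columns, gaps counted) and coverage (aligned fraction
# of the part body).
.score_alignment <- function(body, window, submat = NULL) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(body), Biostrings::DNAString(window), type = "local",
    substitutionMatrix = submat %||% Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 1)
  ind <- Biostrings::nindel(aln)
  ncol_aln <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ind)[, "WidthSum"] + Biostrings::deletion(ind)[, "WidthSum"]
  identity <- if (ncol_aln > 0) unname(Biostrings::nmatch(aln) / ncol_aln) else 0
  p <- Biostrings::pattern(aln)
  cov <- (Biostrings::end(p) - Biostrings::start(p) + 1L) / nchar(body)
  list(identity = identity, coverage = cov,
       subject_start = Biostrings::start(Biostrings::subject(aln)),
       subject_end = Biostrings::end(Biostrings::subject(aln)))
}

#' Identify the parts carried by one long read
#'
#' For each variable category (origin, promoter, resistance) reports the
#' best-matching part whose local alignment covers at least `min_coverage` of
#' the part body at identity at least `min_identity`. A hit whose matched
#' read interval also matches the backbone at `min_identity` over at least
#' `backbone_overlap` nt is flagged ambiguous and the category reported
#' unmapped — this reproduces the promoter/backbone confound in which a
#' promoter variant sharing a 160-bp block with the backbone cannot be
#' distinguished from it. A read carrying two distinct passing parts in one
#' category (a chimera signature) votes for neither.
#'
#' @param read Read sequence (character or `DNAString`).
#' @param design An [library_design()] object.
#' @param min_identity,min_coverage Acceptance thresholds (fractions).
#' @param backbone_overlap Minimum backbone-similarity length (nt) that
#'   triggers the ambiguity flag.
#' @param index Optional prebuilt [part_index()].
#' @param circular Search across the read end-to-start junction.
#' @return Named list over categories; each element is `NULL` (no retained
#'   hit) or a list with `part_id`, `identity` and `ambiguous`.
#' @export
identify_parts <- function(read, design, min_identity = 0.90,
                           min_coverage = 0.90, backbone_overlap = 100L,
                           index = NULL, circular = TRUE) {
  stopifnot(inherits(design, "oripool_design"))
  idx <- index %||% part_index(design)
  read <- as.character(read)
  out <- stats::setNames(vector("list", 3), ASSEMBLY_ORDER[1:3])
  if (!.is_dna(read, allow_n = TRUE)) return(out)

  hits <- list()  # per candidate part: best scored alignment across strands
  bb_starts <- list()  # backbone tag hit positions, per strand
  strands <- c(read, revcomp(read))
  for (k in seq_along(strands)) {
    s <- strands[k]
    subj_chr <- if (circular) paste0(s, s) else s
    subj <- Biostrings::DNAString(subj_chr)
    m <- Biostrings::matchPDict(idx$pdict, subj)
    si <- Biostrings::startIndex(m)
    cnt <- lengths(si)
    hit_claim <- cnt[idx$tag_idx] > 0  # per (part, offset) claim
    is_bb <- idx$owner == idx$backbone_id
    bb_starts[[k]] <- unlist(si[idx$tag_idx[hit_claim & is_bb]]) %||% integer(0)
    cand <- unique(idx$owner[hit_claim & !is_bb])
    for (pid in cand) {
      sel <- which(idx$owner == pid & hit_claim)
      starts <- unlist(si[idx$tag_idx[sel]])
      offs <- rep(idx$offset[sel], lengths(si[idx$tag_idx[sel]]))
      # Anchor on tag hits starting in the first copy of a doubled read, and
      # infer the part's start from each tag's offset within the part body.
      keep <- starts <= nchar(s)
      starts <- starts[keep]; offs <- offs[keep]
      if (!length(starts)) next
      body <- idx$body[[pid]]
      margin <- 30L + ceiling(0.1 * nchar(body))
      anchors <- starts - offs
      # A part wrapped across the linearization point infers negative starts
      # from its tail tags; in the doubled subject the same locus also lives
      # one read-length to the right, which keeps the window contiguous.
      if (circular) anchors[anchors < 1L] <- anchors[anchors < 1L] + nchar(s)
      w0 <- max(1L, min(anchors) - margin)
      w1 <- min(nchar(subj_chr), max(anchors) + nchar(body) + margin)
      sc <- .score_alignment(body, substr(subj_chr, w0, w1), idx$submat)
      sc$strand <- k
      sc$istart <- w0 + sc$subject_start - 1L
      sc$iend <- w0 + sc$subject_end - 1L
      if (is.null(hits[[pid]]) || sc$identity > hits[[pid]]$identity) hits[[pid]] <- sc
    }
  }
  if (!length(hits)) return(out)

  bb_body <- idx$body[[idx$backbone_id]]
  # Does this hit's matched read interval also look like backbone? Checked
  # only when backbone seed tags actually land inside the interval.
  is_backbone_like <- function(h) {
    bbs <- bb_starts[[h$strand]]
    if (h$iend - h$istart + 1L < backbone_overlap ||
        !any(bbs >= h$istart - idx$tag_width & bbs <= h$iend)) return(FALSE)
    s <- strands[h$strand]
    subj_chr <- if (circular) paste0(s, s) else s
    bsc <- .score_alignment(bb_body, substr(subj_chr, h$istart, h$iend), idx$submat)
    alen <- bsc$subject_end - bsc$subject_start + 1L
    alen >= backbone_overlap && bsc$identity >= min_identity
  }
  for (cat in ASSEMBLY_ORDER[1:3]) {
    pids <- names(hits)[idx$category[names(hits)] == cat]
    if (!length(pids)) next
    pass <- sort(pids[vapply(pids, function(p) {
      hits[[p]]$identity >= min_identity && hits[[p]]$coverage >= min_coverage
    }, logical(1))])
    if (length(pass) == 0) next
    amb <- vapply(pass, function(p) is_backbone_like(hits[[p]]), logical(1))
    clean <- pass[!amb]
    if (length(clean) > 1) next  # conflicting within-read hits: vote for neither
    if (length(clean) == 1) {
      out[[cat]] <- list(part_id = clean[1],
                         identity = unname(hits[[clean[1]]]$identity),
                         ambiguous = FALSE)
    } else {
      # Only backbone-confounded hits: report the best, flagged ambiguous
      # (the category stays unmapped downstream).
      best <- pass[which.max(vapply(pass, function(p) hits[[p]]$identity, numeric(1)))]
      out[[cat]] <- list(part_id = best, identity = unname(hits[[best]]$identity),
                         ambiguous = TRUE)
    }
  }
  out
}

#' Deconvolute a set of long reads into barcode observations
#'
#' Runs [extract_barcode()] and [identify_parts()] over every read.
#'
#' @param reads Named character vector or `DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet(..., format = "fastq")`).
#' @param design An [library_design()] object.
#' @inheritParams identify_parts
#' @inheritParams extract_barcode
#' @return A list of observations, one per read, each with `read_id`,
#'   `barcode`, `barcode_status`, `part_hits` and `complete` (one unambiguous
#'   hit in each variable category).
#' @export
map_reads <- function(reads, design, max_flank_mismatches = 2L,
                      min_identity = 0.90, min_coverage = 0.90,
                      length_tolerance = 0L, backbone_overlap = 100L,
                      circular = TRUE) {
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads) %||% as.character(seq_along(reads))
    reads <- stats::setNames(as.character(reads), nm)
  }
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    .stopf("reads must be uniquely named (read_id)")
  idx <- part_index(design)
  lapply(names(reads), function(id) {
    bc <- extract_barcode(reads[[id]], design,
                          max_flank_mismatches = max_flank_mismatches,
                          length_tolerance = length_tolerance,
                          circular = circular)
    ph <- identify_parts(reads[[id]], design, min_identity = min_identity,
                         min_coverage = min_coverage,
                         backbone_overlap = backbone_overlap,
                         index = idx, circular = circular)
    complete <- all(vapply(ph, function(h) !is.null(h) && !h$ambiguous, logical(1)))
    list(read_id = id, barcode = bc$barcode, barcode_status = bc$status,
         part_hits = ph, complete = complete)
  })
}

#' Build the barcode-to-parts association table
#'
#' For each barcode and category, tallies distinct supporting read ids per
#' candidate part. A part is assigned iff exactly one candidate reaches
#' `min_support` distinct reads. A barcode with two or more candidates at
#' `min_support` in any one category is `conflict_eliminated` and excluded
#' from all downstream analysis (barcodes linking to multiple parts are
#' dropped, not adjudicated). A barcode whose best origin candidate falls
#' short of `min_support` is `insufficient_support`. On a `mapped` row the
#' promoter and resistance columns may still be unmapped.
#'
#' Tallying is order-independent: permuting the observations yields an
#' identical table.
#'
#' Barcodes one edit away from a much better-supported barcode are, by
#' default, discarded as sequencing-error variants before tallying
#' (`drop_error_variants`): a read with a substitution inside the barcode
#' mints a phantom barcode one mismatch from the real one, and two such
#' reads can coincide on the same phantom and clear `min_support`. Random
#' 20-mers essentially never sit at edit distance 1 of each other, so the
#' rule removes error products, not genuine library members; set
#' `drop_error_variants = FALSE` to treat barcodes as exact keys.
#'
#' @param observations Output of [map_reads()].
#' @param min_support Minimum number of distinct supporting reads (default 2).
#' @param drop_error_variants Drop barcodes at edit distance <= 1 of a
#'   barcode with at least `error_variant_ratio` times as many reads
#'   (default `TRUE`).
#' @param error_variant_ratio Support ratio above which the rarer of two
#'   neighbouring barcodes is deemed an error variant (default 2).
#' @return A `data.frame` of class `assoc_table` with columns `barcode`,
#'   `part1`, `part2`, `part3`, `support1`, `support2`, `support3`, `status`.
#'   Unassigned origins are `"UNASSIGNED"`; unassigned promoter/resistance
#'   are `"UNMAPPED"`. Support columns report the assigned part's support,
#'   or the best candidate's support when nothing is assigned.
#' @export
build_association <- function(observations, min_support = 2L,
                              drop_error_variants = TRUE,
                              error_variant_ratio = 2) {
  if (length(observations) == 0) {
    .warnf("no observations: returning empty association table")
    return(.empty_assoc())
  }
  votes <- list()
  for (ob in observations) {
    if (is.na(ob$barcode) || ob$barcode_status != "ok") next
    for (cat in ASSEMBLY_ORDER[1:3]) {
      h <- ob$part_hits[[cat]]
      if (is.null(h) || isTRUE(h$ambiguous)) next
      votes[[length(votes) + 1L]] <- data.frame(
        read_id = ob$read_id, barcode = ob$barcode, category = cat,
        part_id = h$part_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(votes)) {
    .warnf("no usable votes: returning empty association table")
    return(.empty_assoc())
  }
  votes <- unique(do.call(rbind, votes))  # distinct read ids per association
  if (drop_error_variants) {
    nread <- tapply(votes$read_id, votes$barcode,
                    function(x) length(unique(x)))
    bcs <- names(nread)
    if (length(bcs) > 1) {
      dd <- utils::adist(bcs)
      bad <- vapply(seq_along(bcs), function(i) {
        nb <- which(dd[i, ] <= 1 & seq_along(bcs) != i)
        length(nb) > 0 && any(nread[nb] >= error_variant_ratio * nread[i] &
                                nread[nb] > nread[i])
      }, logical(1))
      votes <- votes[!(votes$barcode %in% bcs[bad]), , drop = FALSE]
      if (!nrow(votes)) {
        .warnf("all barcodes removed as error variants")
        return(.empty_assoc())
      }
    }
  }
  support <- stats::aggregate(list(support = votes$read_id),
                              votes[c("barcode", "category", "part_id")],
                              function(x) length(unique(x)))

  rows <- lapply(sort(unique(support$barcode)), function(bc) {
    sb <- support[support$barcode == bc, , drop = FALSE]
    assigned <- list(); supp <- list(); conflict <- FALSE
    for (cat in ASSEMBLY_ORDER[1:3]) {
      sc <- sb[sb$category == cat, , drop = FALSE]
      sc <- sc[order(sc$part_id), , drop = FALSE]
      reaching <- sc[sc$support >= min_support, , drop = FALSE]
      if (nrow(reaching) >= 2) conflict <- TRUE
      if (nrow(reaching) == 1) {
        assigned[[cat]] <- reaching$part_id
        supp[[cat]] <- reaching$support
      } else {
        assigned[[cat]] <- NA_character_
        supp[[cat]] <- if (nrow(sc)) max(sc$support) else 0L
      }
    }
    status <- if (conflict) "conflict_eliminated"
    else if (!is.na(assigned$origin)) "mapped"
    else "insufficient_support"
    data.frame(
      barcode = bc,
      part1 = if (status == "mapped") assigned$origin else UNASSIGNED,
      part2 = if (status == "mapped" && !is.na(assigned$promoter)) assigned$promoter else UNMAPPED,
      part3 = if (status == "mapped" && !is.na(assigned$resistance)) assigned$resistance else UNMAPPED,
      support1 = supp$origin, support2 = supp$promoter, support3 = supp$resistance,
      status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  out
}

.empty_assoc <- function() {
  out <- data.frame(barcode = character(0), part1 = character(0),
                    part2 = character(0), part3 = character(0),
                    support1 = integer(0), support2 = integer(0),
                    support3 = integer(0), status = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Summarize an association table
#'
#' @param table An [build_association()] table.
#' @return A list of class `assoc_summary` with `per_origin` (a `data.frame`
#'   of mapped-barcode counts per origin, the pool-abundance measure used by
#'   [classify_origins()]) and `status_counts`.
#' @export
summarize_map <- function(table) {
  stopifnot(inherits(table, "assoc_table"))
  mapped <- table[table$status == "mapped", , drop = FALSE]
  per_origin <- if (nrow(mapped)) {
    ag <- stats::aggregate(list(n_barcodes = mapped$barcode),
                           list(origin = mapped$part1), length)
    ag[order(ag$origin), , drop = FALSE]
  } else data.frame(origin = character(0), n_barcodes = integer(0))
  rownames(per_origin) <- NULL
  status_counts <- table(factor(table$status,
                                levels = c("mapped", "insufficient_support",
                                           "conflict_eliminated")))
  structure(list(per_origin = per_origin,
                 status_counts = c(status_counts)),
            class = "assoc_summary")
}

#' @export
print.assoc_summary <- function(x, ...) {
  cat("Barcode-to-origin map summary\n")
  cat(sprintf("  mapped: %d  insufficient_support: %d  conflict_eliminated: %d\n",
              x$status_counts[["mapped"]], x$status_counts[["insufficient_support"]],
              x$status_counts[["conflict_eliminated"]]))
  cat(sprintf("  origins with >=1 mapped barcode: %d\n", nrow(x$per_origin)))
  invisible(x)
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("Barcode association table: %d barcodes (%d mapped, %d insufficient, %d conflict)\n",
              nrow(x), sum(x$status == "mapped"),
              sum(x$status == "insufficient_support"),
              sum(x$status == "conflict_eliminated")))
  NextMethod()
}

#' Read / write an association table TSV
#'
#' @param table An `assoc_table`.
#' @param path File path.
#' @export
write_assoc_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("barcode", "part1", "part2", "part3", "status")
  if (!all(req %in% names(df)))
    .stopf("association TSV '%s' must have columns %s", path,
           paste(req, collapse = ", "))
  class(df) <- c("assoc_table", "data.frame")
  df
}

#' Score an association table against a simulated ground truth
#'
#' Precision is the fraction of mapped barcode-to-origin assignments that
#' match the truth; recall is the fraction of true barcodes recovered with
#' the correct origin.
#'
#' @param table An `assoc_table`.
#' @param truth A [simulate_library()] ground truth.
#' @return A list with `precision`, `recall`, `n_mapped`, `n_true`.
#' @export
score_association <- function(table, truth) {
  stopifnot(inherits(table, "assoc_table"), inherits(truth, "ground_truth"))
  mapped <- table[table$status == "mapped", , drop = FALSE]
  true_origin <- stats::setNames(truth$library$origin, truth$library$barcode)
  hit <- !is.na(true_origin[mapped$barcode]) &
    mapped$part1 == true_origin[mapped$barcode]
  list(precision = if (nrow(mapped)) mean(hit) else NA_real_,
       recall = sum(hit) / nrow(truth$library),
       n_mapped = nrow(mapped), n_true = nrow(truth$library))
}
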