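# BarSeq analysis: count filtering, per-origin enrichment fractions and
# barcode-diversity tallies per sample, and classification of each origin per
# host as functional, donor carryover, single-barcode artifact, or not
# detected.

SELECTION_MODES <- c("plate", "plate_outgrowth", "liquid")

.check_counts <- function(counts) {
  req <- c("sample_id", "barcode", "count")
  if (!is.data.frame(counts) || !all(req %in% names(counts)))
    .stopf("counts must be a data.frame with columns %s", paste(req, collapse = ", "))
  if (any(counts$count < 0) || any(counts$count != floor(counts$count)))
    .stopf("counts must be non-negative integers")
  if (anyDuplicated(counts[c("sample_id", "barcode")]))
    .stopf("(sample_id, barcode) pairs must be unique")
  counts
}

.check_samples <- function(samples) {
  req <- c("sample_id", "host", "selection")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    .stopf("samples must be a data.frame with columns %s", paste(req, collapse = ", "))
  if (!all(samples$selection %in% SELECTION_MODES))
    .stopf("selection must be one of %s", paste(SELECTION_MODES, collapse = ", "))
  if (!("timepoint" %in% names(samples))) samples$timepoint <- NA_integer_
  liq <- samples$selection == "liquid"
  if (any(liq & (is.na(samples$timepoint) | !samples$timepoint %in% 1:4)))
    .stopf("liquid samples must have timepoint in 1..4 (24/48/72/96 h)")
  if (any(!liq & !is.na(samples$timepoint)))
    .stopf("plate-derived samples must have no timepoint")
  samples
}

#' Filter a barcode count table by minimum count
#'
#' Removes every row with `count < min_count` ("below 6" drops 5 and keeps
#' 6) and reports, per sample, the fraction of the original count mass
#' retained. Filtering is idempotent.
#'
#' @param counts `data.frame` with columns `sample_id`, `barcode`, `count`.
#' @param min_count Minimum retained count (default 6).
#' @return A list with `counts` (filtered table) and `retained`
#'   (`data.frame` of `sample_id`, `retained_fraction`). A sample emptied by
#'   the filter gets retained_fraction 0 with a warning.
#' @export
filter_counts <- function(counts, min_count = 6L) {
  counts <- .check_counts(counts)
  totals <- tapply(counts$count, counts$sample_id, sum)
  kept <- counts[counts$count >= min_count, , drop = FALSE]
  rownames(kept) <- NULL
  kept_tot <- tapply(kept$count, factor(kept$sample_id, levels = names(totals)), sum)
  kept_tot[is.na(kept_tot)] <- 0
  retained <- data.frame(sample_id = names(totals),
                         retained_fraction = ifelse(totals > 0, kept_tot / totals, 0),
                         stringsAsFactors = FALSE)
  rownames(retained) <- NULL
  empty <- retained$sample_id[retained$retained_fraction == 0]
  if (length(empty))
    .warnf("sample(s) emptied by the count filter: %s", paste(empty, collapse = ", "))
  list(counts = kept, retained = retained)
}

#' Per-origin enrichment fractions and barcode diversity
#'
#' For every sample, the fraction attributed to an origin is the summed
#' counts of that origin's mapped barcodes divided by all filtered counts in
#' the sample. By default the denominator includes barcodes absent from the
#' association table, which are reported as `unmapped_fraction` (so origin
#' fractions plus the unmapped fraction sum to 1 per sample); set
#' `denominator = "mapped"` to normalize over mapped counts only. Barcode
#' diversity `n_barcodes` is the number of distinct mapped barcodes of the
#' origin passing the filter in the sample.
#'
#' @param counts Filtered count table (`$counts` from [filter_counts()]).
#' @param assoc An `assoc_table`; only `mapped` rows contribute.
#' @param samples Optional sample metadata (`sample_id`, `host`, `selection`,
#'   `timepoint`), carried along for [classify_origins()].
#' @param denominator `"all"` (default) or `"mapped"`.
#' @return An object of class `enrichment_matrix`: list with `fractions`
#'   (long `data.frame`: `origin`, `sample_id`, `fraction`, `n_barcodes`,
#'   zero-filled over the full origin x sample grid), `per_sample`
#'   (`sample_id`, `total_count`, `unmapped_fraction`) and `samples`.
#' @export
origin_enrichment <- function(counts, assoc, samples = NULL,
                              denominator = c("all", "mapped")) {
  counts <- .check_counts(counts)
  denominator <- match.arg(denominator)
  stopifnot(inherits(assoc, "assoc_table"))
  if (!is.null(samples)) samples <- .check_samples(samples)

  mapped <- assoc[assoc$status == "mapped", c("barcode", "part1")]
  origin_of <- stats::setNames(mapped$part1, mapped$barcode)
  origins <- sort(unique(mapped$part1))
  sample_ids <- if (!is.null(samples)) samples$sample_id else sort(unique(counts$sample_id))

  counts$origin <- origin_of[counts$barcode]
  per_sample <- do.call(rbind, lapply(sample_ids, function(sid) {
    cs <- counts[counts$sample_id == sid, , drop = FALSE]
    tot_all <- sum(cs$count)
    tot_mapped <- sum(cs$count[!is.na(cs$origin)])
    denom <- if (denominator == "all") tot_all else tot_mapped
    data.frame(sample_id = sid, total_count = tot_all,
               unmapped_fraction = if (denom > 0) (tot_all - tot_mapped) / denom else 0,
               stringsAsFactors = FALSE)
  }))
  if (denominator == "mapped") per_sample$unmapped_fraction <- 0

  grid <- expand.grid(origin = origins, sample_id = sample_ids,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$fraction <- 0; grid$n_barcodes <- 0L
  for (k in seq_len(nrow(per_sample))) {
    sid <- per_sample$sample_id[k]
    cs <- counts[counts$sample_id == sid & !is.na(counts$origin), , drop = FALSE]
    denom <- if (denominator == "all") per_sample$total_count[k] else sum(cs$count)
    if (nrow(cs) == 0 || denom == 0) next
    fr <- tapply(cs$count, factor(cs$origin, levels = origins), sum) / denom
    nb <- tapply(cs$barcode, factor(cs$origin, levels = origins),
                 function(x) length(unique(x)))
    sel <- grid$sample_id == sid
    grid$fraction[sel] <- ifelse(is.na(fr), 0, fr)[grid$origin[sel]]
    grid$n_barcodes[sel] <- ifelse(is.na(nb), 0L, nb)[grid$origin[sel]]
  }
  structure(list(fractions = grid, per_sample = per_sample, samples = samples),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("Enrichment matrix: %d origins x %d samples\n",
              length(unique(x$fractions$origin)), nrow(x$per_sample)))
  cat(sprintf("  mean unmapped fraction: %.3f\n", mean(x$per_sample$unmapped_fraction)))
  invisible(x)
}

#' Strict monotone decline test
#'
#' `TRUE` iff each successive value is strictly smaller than its
#' predecessor.
#'
#' @param x Numeric vector (in time order).
#' @return Logical scalar; `NA` when fewer than 2 values.
#' @export
strictly_declining <- function(x) {
  if (length(x) < 2) return(NA)
  all(diff(x) < 0)
}

#' Classify origins per host from enrichment evidence
#'
#' Implements the origin-call heuristics: an origin is `functional` in a
#' host when at least one plate-mode sample (plate or plate outgrowth) shows
#' at least `min_diversity` distinct barcodes at a count fraction of at
#' least `min_fraction`, and the liquid time series is not strictly
#' monotonically declining. An origin whose enrichment rests on a single
#' barcode (maximum diversity 1 despite a fraction above `min_fraction`) is
#' an `artifact_single_barcode`. An origin whose fractions stay below
#' `min_fraction` everywhere, decline strictly across the liquid timepoints,
#' and which sits in the top quartile of pool abundance is `carryover`
#' (signal attributable to the conjugation donor rather than replication in
#' the recipient: such origins are abundant in the pool and are diluted out
#' under selection). Everything else is `not_detected`.
#'
#' With fewer than 3 liquid timepoints the trend test abstains and calls are
#' made on plate evidence alone, flagged `partial_evidence` (carryover is
#' then never called). Hosts are classified independently.
#'
#' @param enr An [origin_enrichment()] result (must carry sample metadata).
#' @param pool_abundance Mapped-barcode counts per origin: the `per_origin`
#'   data.frame from [summarize_map()] (or any data.frame with columns
#'   `origin` and `n_barcodes`), measuring each origin's representation in
#'   the pool itself.
#' @param min_diversity Minimum distinct barcodes for a functional call
#'   (default 2: a single barcode is never sufficient).
#' @param min_fraction Minimum count fraction (default 0.05).
#' @return A `data.frame` of class `origin_calls`: one row per
#'   (origin, host) with `call`, the evidence fields
#'   (`max_fraction_plate`, `max_diversity`, `liquid_declining`,
#'   `top_quartile_pool`) and `partial_evidence`.
#' @export
classify_origins <- function(enr, pool_abundance, min_diversity = 2L,
                             min_fraction = 0.05) {
  stopifnot(inherits(enr, "enrichment_matrix"))
  if (is.null(enr$samples))
    .stopf("classify_origins needs sample metadata (pass `samples` to origin_enrichment)")
  if (inherits(pool_abundance, "assoc_summary")) pool_abundance <- pool_abundance$per_origin
  if (!all(c("origin", "n_barcodes") %in% names(pool_abundance)))
    .stopf("pool_abundance must have columns origin, n_barcodes")
  samples <- enr$samples
  fr <- merge(enr$fractions, samples, by = "sample_id")
  q75 <- stats::quantile(pool_abundance$n_barcodes, 0.75, names = FALSE)
  topq <- stats::setNames(pool_abundance$n_barcodes >= q75, pool_abundance$origin)

  rows <- list()
  for (host in unique(samples$host)) {
    fh <- fr[fr$host == host, , drop = FALSE]
    plate <- fh[fh$selection %in% c("plate", "plate_outgrowth"), , drop = FALSE]
    liquid <- fh[fh$selection == "liquid", , drop = FALSE]
    liquid <- liquid[order(liquid$timepoint), , drop = FALSE]
    n_liq <- length(unique(liquid$timepoint))
    partial <- nrow(plate) == 0 || n_liq < 3
    for (og in sort(unique(fh$origin))) {
      p <- plate[plate$origin == og, , drop = FALSE]
      l <- liquid[liquid$origin == og, , drop = FALSE]
      all_f <- fh$fraction[fh$origin == og]
      max_div <- max(fh$n_barcodes[fh$origin == og], 0L)
      declining <- if (n_liq >= 3) strictly_declining(l$fraction) else NA
      plate_ev <- nrow(p) > 0 &&
        any(p$n_barcodes >= min_diversity & p$fraction >= min_fraction)
      call <- if (max_div == 1L && max(all_f) >= min_fraction) {
        "artifact_single_barcode"
      } else if (plate_ev && !isTRUE(declining)) {
        "functional"
      } else if (all(all_f < min_fraction) && isTRUE(declining) &&
                 isTRUE(topq[og])) {
        "carryover"
      } else "not_detected"
      rows[[length(rows) + 1L]] <- data.frame(
        origin = og, host = host, call = call,
        max_fraction_plate = if (nrow(p)) max(p$fraction) else NA_real_,
        max_fraction = max(all_f), max_diversity = max_div,
        liquid_declining = declining,
        top_quartile_pool = isTRUE(topq[og]),
        partial_evidence = partial, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("origin_calls", "data.frame")
  out
}

#' @export
print.origin_calls <- function(x, ...) {
  if (!all(c("host", "call") %in% names(x))) return(NextMethod())
  cat("Origin calls per host:\n")
  print(table(x$host, x$call))
  invisible(x)
}

#' Write the enrichment matrix (and calls) to TSV
#'
#' One data row per origin x sample with the fraction and barcode
#' diversity, origins ordered by name; per-origin calls are appended as a
#' `call` column when provided. [read_matrix_tsv()] re-reads the fractions;
#' the round trip preserves values to full precision.
#'
#' @param enr An `enrichment_matrix`.
#' @param path Output TSV path.
#' @param calls Optional `origin_calls`.
#' @return `path`, invisibly.
#' @export
render_matrix <- function(enr, path, calls = NULL) {
  stopifnot(inherits(enr, "enrichment_matrix"))
  df <- enr$fractions[order(enr$fractions$origin, enr$fractions$sample_id), ]
  if (!is.null(calls)) {
    if (!is.null(enr$samples)) {
      key <- merge(df, enr$samples[c("sample_id", "host")], by = "sample_id")
      df <- merge(key, calls[c("origin", "host", "call")],
                  by = c("origin", "host"), all.x = TRUE)
      df <- df[order(df$origin, df$sample_id),
               c("origin", "sample_id", "fraction", "n_barcodes", "call")]
    }
  }
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname render_matrix
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("origin", "sample_id", "fraction", "n_barcodes")
  if (!all(req %in% names(df)))
    .stopf("matrix TSV '%s' must have columns %s", path, paste(req, collapse = ", "))
  df
}

#' Heatmap of enrichment fractions
#'
#' Base-graphics heatmap of the per-origin fractions (rows: origins, ordered
#' by name; columns: samples), with barcode-diversity counts printed in each
#' cell, mirroring the usual presentation of pooled-library screens.
#'
#' @param x An `enrichment_matrix`.
#' @param ... Ignored.
#' @export
plot.enrichment_matrix <- function(x, ...) {
  fr <- x$fractions
  origins <- sort(unique(fr$origin)); sids <- unique(fr$sample_id)
  m <- matrix(0, length(origins), length(sids), dimnames = list(origins, sids))
  nb <- m
  for (i in seq_len(nrow(fr))) {
    m[fr$origin[i], fr$sample_id[i]] <- fr$fraction[i]
    nb[fr$origin[i], fr$sample_id[i]] <- fr$n_barcodes[i]
  }
  op <- graphics::par(mar = c(7, 6, 2, 1)); on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_along(sids), seq_along(origins), t(m), col = pal,
                  axes = FALSE, xlab = "", ylab = "", zlim = c(0, max(m, 1e-9)))
  graphics::axis(1, seq_along(sids), sids, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(origins), origins, las = 2, cex.axis = 0.6)
  for (i in seq_along(origins)) for (j in seq_along(sids))
    if (nb[i, j] > 0) graphics::text(j, i, nb[i, j], cex = 0.5)
  invisible(x)
}
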