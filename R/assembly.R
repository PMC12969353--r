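# In-silico assembly of a four-part barcoded plasmid. The circular product is
# linearized at a canonical rotation: position 0 is the first base of
# flank_left (the barcode cassette anchor), which keeps barcode coordinates
# stable across all members of a pool.

ASSEMBLY_ORDER <- c("origin", "promoter", "resistance", "backbone")

#' Assemble one barcoded plasmid in silico
#'
#' Joins one part per category in the fixed order origin -> promoter ->
#' resistance -> backbone -> (origin), checking that the downstream overhang
#' of each part equals the upstream overhang of the next. Each shared
#' junction overhang appears exactly once in the product, so the total length
#' is the sum of the part bodies plus the four 4-nt junctions. The barcode is
#' inserted between the backbone's priming sites.
#'
#' @param design An [library_design()] object.
#' @param selection Named character vector mapping each category
#'   (`origin`, `promoter`, `resistance`, and optionally `backbone`) to a
#'   `part_id`. The backbone may be omitted since a design carries exactly
#'   one.
#' @param barcode Barcode sequence of length `design$barcode_length`.
#' @param plasmid_id Identifier for the record (default derived from the
#'   selection).
#' @return An object of class `oripool_plasmid` with fields `plasmid_id`,
#'   `barcode`, `part_ids`, `sequence` (canonical linearization of the
#'   circular molecule), `topology` and `features` (0-based half-open
#'   coordinates; strand `"+"` carries flank_left -> barcode -> flank_right).
#' @export
#' @examples
#' d <- example_design(n_origins = 2, n_promoters = 2, n_resistance = 1)
#' p <- assemble_plasmid(d, c(origin = "o1", promoter = "p2", resistance = "r1"),
#'                       strrep("A", 20))
#' nchar(p$sequence)
assemble_plasmid <- function(design, selection, barcode, plasmid_id = NULL) {
  stopifnot(inherits(design, "oripool_design"))
  selection <- unlist(selection)
  if (!("backbone" %in% names(selection)))
    selection[["backbone"]] <- design$parts$part_id[design$parts$category == "backbone"]
  missing <- setdiff(ASSEMBLY_ORDER, names(selection))
  if (length(missing))
    .stopf("selection must name one part per category; missing: %s",
           paste(missing, collapse = ", "))
  if (!.is_dna(barcode))
    .stopf("barcode must be a non-empty uppercase ACGT string")
  if (nchar(barcode) != design$barcode_length)
    .stopf("barcode length %d does not match design barcode_length %d",
           nchar(barcode), design$barcode_length)

  parts <- lapply(ASSEMBLY_ORDER, function(cat) {
    p <- .get_part(design, selection[[cat]])
    if (p$category != cat)
      .stopf("part '%s' has category '%s', selected for '%s'",
             p$part_id, p$category, cat)
    p
  })
  names(parts) <- ASSEMBLY_ORDER

  # Overhang chaining, including the wrap-around junction backbone -> origin.
  nxt <- c(2L, 3L, 4L, 1L)
  for (i in seq_along(parts)) {
    a <- parts[[i]]; b <- parts[[nxt[i]]]
    if (a$downstream_overhang != b$upstream_overhang)
      .stopf("assembly incompatibility at junction (%s, %s): overhang %s != %s",
             a$category, b$category, a$downstream_overhang, b$upstream_overhang)
  }

  # Insert the barcode into the backbone's cassette slot.
  bb <- parts$backbone$body_seq
  slot <- paste0(design$flank_left, design$flank_right)
  cassette <- paste0(design$flank_left, barcode, design$flank_right)
  bb_barcoded <- sub(slot, cassette, bb, fixed = TRUE)

  # Canonical linearization starting at flank_left. The backbone body splits
  # into the cassette-to-end segment (sequence start) and the pre-cassette
  # segment (sequence end).
  fl_at <- regexpr(paste0(design$flank_left, barcode, design$flank_right),
                   bb_barcoded, fixed = TRUE)[1]
  bb_head <- substr(bb_barcoded, fl_at, nchar(bb_barcoded))
  bb_tail <- substr(bb_barcoded, 1, fl_at - 1)

  segs <- list(
    list(label = "backbone_cassette", seq = bb_head, part = parts$backbone$part_id),
    list(label = "junction", seq = parts$backbone$downstream_overhang, part = NA),
    list(label = "part_body", seq = parts$origin$body_seq, part = parts$origin$part_id),
    list(label = "junction", seq = parts$origin$downstream_overhang, part = NA),
    list(label = "part_body", seq = parts$promoter$body_seq, part = parts$promoter$part_id),
    list(label = "junction", seq = parts$promoter$downstream_overhang, part = NA),
    list(label = "part_body", seq = parts$resistance$body_seq, part = parts$resistance$part_id),
    list(label = "junction", seq = parts$resistance$downstream_overhang, part = NA),
    list(label = "backbone_tail", seq = bb_tail, part = parts$backbone$part_id)
  )
  seqs <- vapply(segs, `[[`, character(1), "seq")
  widths <- nchar(seqs)
  starts <- cumsum(c(0L, widths[-length(widths)]))
  sequence <- paste(seqs, collapse = "")

  lfl <- nchar(design$flank_left); lfr <- nchar(design$flank_right)
  bl <- design$barcode_length
  feat <- data.frame(
    label = c("flank_left", "barcode", "flank_right",
              parts$backbone$part_id, parts$origin$part_id,
              parts$promoter$part_id, parts$resistance$part_id,
              parts$backbone$part_id),
    start = c(0L, lfl, lfl + bl,
              starts[1], starts[3], starts[5], starts[7], starts[9]),
    end = c(lfl, lfl + bl, lfl + bl + lfr,
            starts[1] + widths[1], starts[3] + widths[3],
            starts[5] + widths[5], starts[7] + widths[7],
            starts[9] + widths[9]),
    strand = "+", stringsAsFactors = FALSE)
  feat <- feat[feat$end > feat$start, , drop = FALSE]
  rownames(feat) <- NULL

  part_ids <- vapply(parts, `[[`, character(1), "part_id")
  structure(list(
    plasmid_id = plasmid_id %||% paste(part_ids[ASSEMBLY_ORDER[1:3]], collapse = "_"),
    barcode = barcode, part_ids = part_ids, sequence = sequence,
    topology = "circular", features = feat), class = "oripool_plasmid")
}

#' @export
print.oripool_plasmid <- function(x, ...) {
  cat(sprintf("<oripool_plasmid> %s: %s bp circular, barcode %s\n",
              x$plasmid_id, format(nchar(x$sequence), big.mark = ","), x$barcode))
  cat(sprintf("  parts: %s\n", paste(sprintf("%s=%s", names(x$part_ids), x$part_ids),
                                     collapse = ", ")))
  invisible(x)
}

#' Canonicalize a rotation/strand representation of a plasmid sequence
#'
#' All rotations (and the reverse complement) of a circular sequence denote
#' the same molecule. This returns the canonical linearization: the strand
#' and rotation on which `flank_left` is found, starting at its first base.
#'
#' @param seq Linearized circular sequence (any rotation, either strand).
#' @param flank_left The barcode cassette anchor sequence.
#' @return The canonical sequence, or `NA_character_` if the anchor is not
#'   found on either strand.
#' @export
canonicalize_rotation <- function(seq, flank_left) {
  for (s in c(seq, revcomp(seq))) {
    at <- .find_circular(s, flank_left)
    if (!is.na(at)) return(.rotate_seq(s, at))
  }
  NA_character_
}

#' Enumerate the combinatorial design space
#'
#' Counts and lists every combination of one part per variable category
#' (origin x promoter x resistance); the backbone is fixed. With the
#' study-scale registry of 38 x 10 x 2 variants this is 760 combinations.
#'
#' @param design An [library_design()] object.
#' @return A list with `n` (the count) and `selections`, a `data.frame` with
#'   one row per combination (columns `origin`, `promoter`, `resistance`) in
#'   deterministic order: origin varies slowest, resistance fastest, each
#'   category in registry order.
#' @export
enumerate_design_space <- function(design) {
  stopifnot(inherits(design, "oripool_design"))
  ids <- lapply(ASSEMBLY_ORDER[1:3], function(cat) .parts_of(design, cat)$part_id)
  names(ids) <- ASSEMBLY_ORDER[1:3]
  counts <- lengths(ids)
  if (any(counts == 0)) {
    .warnf("empty variable category (%s): design space is empty",
           paste(names(counts)[counts == 0], collapse = ", "))
    return(list(n = 0L, selections = data.frame(origin = character(0),
                                                promoter = character(0),
                                                resistance = character(0))))
  }
  grid <- expand.grid(resistance = ids$resistance, promoter = ids$promoter,
                      origin = ids$origin, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("origin", "promoter", "resistance")]
  rownames(grid) <- NULL
  list(n = prod(counts), selections = grid)
}
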