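# Library design: the registry of golden-gate parts plus the barcode cassette
# geometry. Junctions between parts are modeled as abstract 4-nt overhang
# labels rather than simulated type IIS digestion: what the downstream
# pipeline needs is junction validity, not restriction chemistry.

POOL_CATEGORIES <- c("origin", "promoter", "resistance", "backbone")

#' Construct a single library part
#'
#' A part occupies one of the four golden-gate positions: `origin` (part 1),
#' `promoter` (part 2, drug-resistance promoter plus RBS), `resistance`
#' (part 3, resistance CDS) or `backbone` (part 4, the barcoded backbone).
#'
#' @param part_id Unique identifier within a design.
#' @param category One of `"origin"`, `"promoter"`, `"resistance"`,
#'   `"backbone"`.
#' @param body_seq Uppercase A/C/G/T body sequence (without overhangs).
#' @param upstream_overhang,downstream_overhang 4-nt overhang labels; the
#'   downstream overhang of a part must equal the upstream overhang of its
#'   successor for assembly to succeed.
#' @return A one-row `data.frame` with the part's fields.
#' @export
pool_part <- function(part_id, category, body_seq,
                      upstream_overhang, downstream_overhang) {
  category <- match.arg(category, POOL_CATEGORIES)
  if (!.is_dna(body_seq)) .stopf("part '%s': body_seq must be non-empty uppercase ACGT", part_id)
  for (ov in c(upstream_overhang, downstream_overhang)) {
    if (!.is_dna(ov) || nchar(ov) != 4L)
      .stopf("part '%s': overhangs must be 4-nt DNA strings", part_id)
  }
  data.frame(part_id = as.character(part_id), category = category,
             upstream_overhang = upstream_overhang,
             downstream_overhang = downstream_overhang,
             body_seq = body_seq, stringsAsFactors = FALSE)
}

#' Construct a library design
#'
#' Bundles the parts registry with the barcode cassette: a random N-mer
#' barcode sits between two fixed PCR priming sites (`flank_left`,
#' `flank_right`) inside the backbone. The backbone body must contain
#' `flank_left` immediately followed by `flank_right` exactly once; assembly
#' inserts the barcode between them.
#'
#' @param parts A `data.frame` with columns `part_id`, `category`,
#'   `upstream_overhang`, `downstream_overhang`, `body_seq` (e.g. rbind of
#'   [pool_part()] rows, or [read_parts_tsv()] output).
#' @param flank_left,flank_right Priming-site sequences flanking the barcode.
#'   The study's priming sites are not printed in the source material, so
#'   user-supplied flanks are required; the bundled example design ships
#'   invented synthetic flanks.
#' @param barcode_length Barcode length in nt (default 20, minimum 8).
#' @return An object of class `oripool_design`.
#' @export
library_design <- function(parts, flank_left, flank_right, barcode_length = 20L) {
  req <- c("part_id", "category", "upstream_overhang", "downstream_overhang", "body_seq")
  if (!is.data.frame(parts) || !all(req %in% names(parts)))
    .stopf("parts must be a data.frame with columns %s", paste(req, collapse = ", "))
  parts <- as.data.frame(parts)[req]
  parts[] <- lapply(parts, as.character)
  if (anyDuplicated(parts$part_id))
    .stopf("duplicated part_id: %s",
           paste(unique(parts$part_id[duplicated(parts$part_id)]), collapse = ", "))
  if (!all(parts$category %in% POOL_CATEGORIES))
    .stopf("unknown category: %s",
           paste(setdiff(parts$category, POOL_CATEGORIES), collapse = ", "))
  if (!all(.is_dna(parts$body_seq)))
    .stopf("all part bodies must be non-empty uppercase ACGT")
  if (!all(nchar(parts$upstream_overhang) == 4L & .is_dna(parts$upstream_overhang)) ||
      !all(nchar(parts$downstream_overhang) == 4L & .is_dna(parts$downstream_overhang)))
    .stopf("all overhang labels must be 4-nt DNA strings")
  if (sum(parts$category == "backbone") != 1L)
    .stopf("design must contain exactly one backbone part")
  if (!.is_dna(flank_left) || !.is_dna(flank_right))
    .stopf("flank sequences must be non-empty uppercase ACGT")
  barcode_length <- as.integer(barcode_length)
  if (is.na(barcode_length) || barcode_length < 8L)
    .stopf("barcode_length must be an integer >= 8")

  bb <- parts$body_seq[parts$category == "backbone"]
  slot <- paste0(flank_left, flank_right)
  n_slot <- length(gregexpr(slot, bb, fixed = TRUE)[[1]])
  if (regexpr(slot, bb, fixed = TRUE)[1] < 1 || n_slot != 1L)
    .stopf("backbone body must contain flank_left immediately followed by flank_right exactly once (the barcode slot)")

  structure(list(parts = parts, flank_left = flank_left,
                 flank_right = flank_right,
                 barcode_length = barcode_length),
            class = "oripool_design")
}

#' @export
print.oripool_design <- function(x, ...) {
  tab <- table(factor(x$parts$category, levels = POOL_CATEGORIES))
  cat("Magic pool library design\n")
  cat(sprintf("  parts: %d origin, %d promoter, %d resistance, %d backbone\n",
              tab[["origin"]], tab[["promoter"]], tab[["resistance"]], tab[["backbone"]]))
  cat(sprintf("  barcode: N%d between %d-nt / %d-nt priming sites\n",
              x$barcode_length, nchar(x$flank_left), nchar(x$flank_right)))
  invisible(x)
}

.get_part <- function(design, part_id) {
  i <- match(part_id, design$parts$part_id)
  if (is.na(i)) .stopf("unknown part_id '%s'", part_id)
  design$parts[i, , drop = FALSE]
}

.parts_of <- function(design, category) {
  design$parts[design$parts$category == category, , drop = FALSE]
}

#' Read / write a parts registry TSV
#'
#' The registry format has columns `part_id`, `category`,
#' `upstream_overhang`, `downstream_overhang`, `body_seq`.
#'
#' @param path File path.
#' @return `read_parts_tsv()` returns the parts `data.frame`.
#' @export
read_parts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("part_id", "category", "upstream_overhang", "downstream_overhang", "body_seq")
  if (!all(req %in% names(df)))
    .stopf("parts TSV '%s' must have columns %s", path, paste(req, collapse = ", "))
  df[req]
}

#' @rdname read_parts_tsv
#' @param parts Parts `data.frame` (or an `oripool_design`, whose registry is
#'   written).
#' @export
write_parts_tsv <- function(parts, path) {
  if (inherits(parts, "oripool_design")) parts <- parts$parts
  utils::write.table(parts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled synthetic example design
#'
#' Generates a design with the study-scale composition (38 origin variants,
#' 10 promoter variants, 2 resistance variants, one barcoded backbone) from
#' random sequences. All sequences, including the 20-nt barcode priming
#' sites, are synthetic inventions: the real part sequences live in the
#' study's supplementary material and are not redistributed here.
#'
#' @param n_origins,n_promoters,n_resistance Number of variants per variable
#'   category.
#' @param origin_length,promoter_length,resistance_length Body lengths (nt).
#' @param backbone_stuffer Length of backbone sequence outside the barcode
#'   cassette (nt); stands in for the conditional R6K origin, oriT and
#'   carbenicillin marker.
#' @param confound_promoter If `TRUE`, the last promoter variant carries a
#'   160-bp block copied verbatim from the backbone, reproducing the
#'   promoter/backbone ambiguity observed for part 2.4 in the source library.
#' @param seed RNG seed used to draw the synthetic sequences.
#' @return An `oripool_design`.
#' @export
example_design <- function(n_origins = 38, n_promoters = 10, n_resistance = 2,
                           origin_length = 200, promoter_length = 120,
                           resistance_length = 400, backbone_stuffer = 900,
                           confound_promoter = FALSE, seed = 20260101) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # Four junction labels, one per inter-part junction (backbone->origin,
  # origin->promoter, promoter->resistance, resistance->backbone).
  ov <- c(A = "AATG", B = "GCTT", C = "CGAA", D = "TGGC")
  fl <- random_dna(1, 20)
  fr <- random_dna(1, 20)

  mk <- function(n, prefix, len, up, down) {
    if (n == 0) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(i) {
      pool_part(sprintf("%s%d", prefix, i),
                switch(prefix, o = "origin", p = "promoter", r = "resistance"),
                random_dna(1, len), up, down)
    }))
  }
  origins <- mk(n_origins, "o", origin_length, ov[["A"]], ov[["B"]])
  promoters <- mk(n_promoters, "p", promoter_length, ov[["B"]], ov[["C"]])
  resistances <- mk(n_resistance, "r", resistance_length, ov[["C"]], ov[["D"]])

  half <- floor(backbone_stuffer / 2)
  bb_pre <- random_dna(1, half)
  bb_post <- random_dna(1, backbone_stuffer - half)
  backbone <- pool_part("bb1", "backbone",
                        paste0(bb_pre, fl, fr, bb_post),
                        ov[["D"]], ov[["A"]])

  if (confound_promoter && n_promoters >= 1 && backbone_stuffer - half >= 160) {
    shared <- substr(bb_post, 1, 160)
    i <- nrow(promoters)
    promoters$body_seq[i] <- paste0(substr(promoters$body_seq[i], 1,
                                           max(0, promoter_length - 160)), shared)
  }

  library_design(rbind(origins, promoters, resistances, backbone),
                 flank_left = fl, flank_right = fr, barcode_length = 20L)
}

# Save/restore the global RNG state so fixture constructors with their own
# seed do not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
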