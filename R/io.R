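# Library serialization. GenBank records carry the full plasmid record
# (sequence, circular topology, features); FASTA carries the canonical
# linearized sequence only. No installed R package both writes and reads
# GenBank flat files with features, so a minimal writer/parser for the subset
# this package emits is implemented here.

#' Write a plasmid library to GenBank or FASTA
#'
#' @param plasmids A list of [assemble_plasmid()] records.
#' @param path Output file path.
#' @param format `"genbank"` (full record: sequence, circular topology flag,
#'   features) or `"fasta"` (canonical linearized sequence only).
#' @return `path`, invisibly.
#' @seealso [read_library()] for the inverse; `read(write(x))` reproduces
#'   sequences, topology and annotations exactly for GenBank.
#' @export
write_library <- function(plasmids, path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  if (inherits(plasmids, "oripool_plasmid")) plasmids <- list(plasmids)
  stopifnot(all(vapply(plasmids, inherits, logical(1), "oripool_plasmid")))
  if (format == "fasta") {
    seqs <- Biostrings::DNAStringSet(vapply(plasmids, `[[`, character(1), "sequence"))
    names(seqs) <- vapply(plasmids, `[[`, character(1), "plasmid_id")
    Biostrings::writeXStringSet(seqs, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (p in plasmids) .write_genbank_record(p, con)
  invisible(path)
}

.write_genbank_record <- function(p, con) {
  n <- nchar(p$sequence)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-2026",
                     p$plasmid_id, n, p$topology), con)
  writeLines(sprintf("DEFINITION  barcoded combinatorial plasmid; barcode=%s", p$barcode), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  if (nrow(p$features)) {
    for (i in seq_len(nrow(p$features))) {
      f <- p$features[i, ]
      loc <- sprintf("%d..%d", f$start + 1L, f$end)  # to 1-based inclusive
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     misc_feature    %s", loc), con)
      writeLines(sprintf("                     /label=\"%s\"", f$label), con)
    }
  }
  writeLines("ORIGIN", con)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(p$sequence, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tolower(blocks), collapse = " ")), con)
  }
  writeLines("//", con)
}

#' Read a plasmid library written by [write_library()]
#'
#' @param path Input file path.
#' @param format `"genbank"` or `"fasta"`. FASTA records come back with
#'   `plasmid_id` and `sequence` only (barcode, parts and features are not
#'   stored in FASTA).
#' @return A list of `oripool_plasmid` records.
#' @export
read_library <- function(path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    return(lapply(seq_along(seqs), function(i) {
      structure(list(plasmid_id = names(seqs)[i], barcode = NA_character_,
                     part_ids = NULL, sequence = as.character(seqs[[i]]),
                     topology = "circular",
                     features = data.frame(label = character(0), start = integer(0),
                                           end = integer(0), strand = character(0))),
                class = "oripool_plasmid")
    }))
  }
  lines <- readLines(path)
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LOCUS", lines[i])) { i <- i + 1L; next }
    rec <- .parse_genbank_record(lines, i, path)
    recs[[length(recs) + 1L]] <- rec$record
    i <- rec$next_line
  }
  if (!length(recs)) .stopf("no GenBank records found in '%s'", path)
  recs
}

.parse_genbank_record <- function(lines, i, path) {
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[i])), "[[:space:]]+")[[1]]
  plasmid_id <- locus[1]
  declared_len <- suppressWarnings(as.integer(locus[2]))
  topology <- if (any(locus == "circular")) "circular" else "linear"
  barcode <- NA_character_
  feats <- list()
  seq_chunks <- character(0)
  i <- i + 1L
  state <- "header"
  terminated <- FALSE
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^//\\s*$", ln)) { terminated <- TRUE; i <- i + 1L; break }
    if (grepl("^DEFINITION", ln)) {
      m <- regmatches(ln, regexpr("barcode=[ACGTN]+", ln))
      if (length(m)) barcode <- sub("barcode=", "", m)
    } else if (grepl("^FEATURES", ln)) {
      state <- "features"
    } else if (grepl("^ORIGIN", ln)) {
      state <- "origin"
    } else if (state == "features" && grepl("^     \\S", ln)) {
      loc <- trimws(sub("^     \\S+\\s+", "", ln))
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      loc <- gsub("complement\\(|\\)", "", loc)
      se <- suppressWarnings(as.integer(strsplit(loc, "\\.\\.")[[1]]))
      if (length(se) != 2 || anyNA(se))
        .stopf("parse error in '%s' line %d: malformed feature location '%s'", path, i, loc)
      feats[[length(feats) + 1L]] <- list(start = se[1] - 1L, end = se[2],
                                          strand = strand, label = NA_character_)
    } else if (state == "features" && grepl("/label=", ln)) {
      if (length(feats))
        feats[[length(feats)]]$label <- gsub('.*?/label="([^"]*)".*', "\\1", ln)
    } else if (state == "origin") {
      seq_chunks <- c(seq_chunks, gsub("[0-9[:space:]]", "", ln))
    }
    i <- i + 1L
  }
  if (!terminated)
    .stopf("parse error in '%s': record '%s' truncated before '//' terminator",
           path, plasmid_id)
  sequence <- toupper(paste(seq_chunks, collapse = ""))
  if (!is.na(declared_len) && nchar(sequence) != declared_len)
    .stopf("parse error in '%s': record '%s' declares %d bp but carries %d",
           path, plasmid_id, declared_len, nchar(sequence))
  features <- if (length(feats)) {
    data.frame(label = vapply(feats, `[[`, character(1), "label"),
               start = vapply(feats, `[[`, integer(1), "start"),
               end = vapply(feats, `[[`, integer(1), "end"),
               strand = vapply(feats, `[[`, character(1), "strand"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  }
  list(record = structure(list(plasmid_id = plasmid_id, barcode = barcode,
                               part_ids = NULL, sequence = sequence,
                               topology = topology, features = features),
                          class = "oripool_plasmid"),
       next_line = i)
}
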