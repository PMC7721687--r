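## Canonical / extra-zone partitioning and the signed coordinate convention --

#' Partition a genome into 5'-extra, canonical and 3'-extra zones
#'
#' The canonical zone of an LA genome is numbered from the conserved 5'
#' motif (`GAAAAA` in most LA viruses; a homologous motif such as `AATTAA`
#' may be supplied for other viruses) to the 3' terminus of the canonical
#' end motif (e.g. `CCATATGC`). Nucleotides upstream of the motif form the
#' 5'-extra zone, numbered (-)1, (-)2, ... toward the 5' terminus;
#' nucleotides downstream of the canonical end form the 3'-extra zone,
#' numbered (+)1, (+)2, ...
#'
#' When `reference` (an annotated `la_partition`) is given, zone boundaries
#' are projected from the reference through a global nucleotide alignment
#' instead of motif matching, and this takes precedence over the motif
#' anchors.
#'
#' Anchor ambiguity is resolved by choosing the anchor occurrence that
#' maximizes the canonical length while keeping the extra zone at most
#' `max_extra` nucleotides; occurrences that would imply longer extras are
#' considered implausible and raise an `"ambiguous anchor"` error.
#'
#' @param seq An [viral_sequence()].
#' @param anchor_5 5' motif string fixing canonical position 1.
#' @param anchor_3 Canonical 3'-end motif; `NULL` means the canonical zone
#'   runs to the 3' terminus (no 3'-extra).
#' @param reference Optional annotated `la_partition` used for
#'   alignment-based boundary projection.
#' @param max_extra Maximum plausible extra-zone length (default 400 nt).
#' @return An object of class `la_partition` with fields `sequence`,
#'   `five_extra_len`, `canonical_len`, `three_extra_len`, `anchor_5`,
#'   `anchor_3`, `anchor_method`.
#' @export
partition_genome <- function(seq, anchor_5 = "GAAAAA", anchor_3 = NULL,
                             reference = NULL, max_extra = 400L) {
  stopifnot(inherits(seq, "la_sequence"))
  n <- seq$length
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "la_partition"))
    b <- project_boundaries(seq, reference)
    return(new_partition(seq, b$five, b$canonical, b$three,
                         anchor_5, anchor_3, "reference_alignment"))
  }
  anchor_5 <- normalize_dna(anchor_5)
  if (grepl("N", anchor_5)) stop("anchors must not contain N")
  occ5 <- literal_matches(seq$residues, anchor_5)
  if (length(occ5) == 0L) stop("unanchorable: 5' anchor '", anchor_5,
                               "' not found in ", seq$id)
  ok5 <- occ5[occ5 - 1L <= max_extra]
  if (length(ok5) == 0L) {
    stop("ambiguous anchor: all ", length(occ5), " occurrence(s) of '",
         anchor_5, "' imply a 5'-extra longer than ", max_extra, " nt")
  }
  start5 <- min(ok5)  # maximizes canonical length
  if (is.null(anchor_3)) {
    end3 <- n
  } else {
    anchor_3 <- normalize_dna(anchor_3)
    if (grepl("N", anchor_3)) stop("anchors must not contain N")
    occ3 <- literal_matches(seq$residues, anchor_3)
    ends <- occ3 + nchar(anchor_3) - 1L
    ends <- ends[ends > start5 & (n - ends) <= max_extra]
    if (length(ends) == 0L) stop("unanchorable: 3' anchor '", anchor_3,
                                 "' not found within ", max_extra,
                                 " nt of the 3' terminus of ", seq$id)
    end3 <- max(ends)   # maximizes canonical length
  }
  new_partition(seq, start5 - 1L, end3 - start5 + 1L, n - end3,
                anchor_5, anchor_3, "motif")
}

new_partition <- function(seq, five, canonical, three,
                          anchor_5, anchor_3, method) {
  stopifnot(five >= 0L, canonical >= 1L, three >= 0L,
            five + canonical + three == seq$length)
  structure(list(sequence = seq,
                 five_extra_len = as.integer(five),
                 canonical_len = as.integer(canonical),
                 three_extra_len = as.integer(three),
                 anchor_5 = anchor_5, anchor_3 = anchor_3,
                 anchor_method = method),
            class = "la_partition")
}

literal_matches <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## Project reference canonical boundaries onto seq through a global alignment.
project_boundaries <- function(seq, reference) {
  ref <- reference$sequence
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq$residues),
    subject = Biostrings::DNAString(ref$residues),
    type = "global",
    substitutionMatrix = nt_submat(),
    gapOpening = 10, gapExtension = 0.5)
  pat <- chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- chars(as.character(Biostrings::alignedSubject(aln)))
  # column-wise cumulative positions
  pat_pos <- cumsum(pat != "-")
  sub_pos <- cumsum(sub != "-")
  map_ref_to_seq <- function(ref_pos) {
    col <- which(sub_pos == ref_pos & sub != "-")[1]
    if (is.na(col)) stop("region lost in alignment at reference position ",
                         ref_pos)
    # nearest non-gap query position at or before this column
    p <- pat_pos[col]
    max(p, 1L)
  }
  rs <- reference$five_extra_len + 1L
  re <- reference$five_extra_len + reference$canonical_len
  qs <- map_ref_to_seq(rs)
  qe <- map_ref_to_seq(re)
  list(five = qs - 1L, canonical = qe - qs + 1L,
       three = seq$length - qe)
}

#' @export
print.la_partition <- function(x, ...) {
  cat(sprintf("<la_partition> %s: 5'-extra %d / canonical %d / 3'-extra %d (%s)\n",
              x$sequence$id, x$five_extra_len, x$canonical_len,
              x$three_extra_len, x$anchor_method))
  invisible(x)
}

#' Extract zone sequences from a partition
#'
#' @param p An `la_partition`.
#' @return A nucleotide string (possibly empty for extras).
#' @export
canonical_seq <- function(p) {
  substr(p$sequence$residues, p$five_extra_len + 1L,
         p$five_extra_len + p$canonical_len)
}

#' @rdname canonical_seq
#' @export
extra5_seq <- function(p) {
  if (p$five_extra_len == 0L) return("")
  substr(p$sequence$residues, 1L, p$five_extra_len)
}

#' @rdname canonical_seq
#' @export
extra3_seq <- function(p) {
  if (p$three_extra_len == 0L) return("")
  substr(p$sequence$residues, p$five_extra_len + p$canonical_len + 1L,
         p$sequence$length)
}

## Signed coordinates ---------------------------------------------------------

#' Signed zone coordinates
#'
#' `signed_coord()` constructs a coordinate in the signed convention:
#' `FIVE_EXTRA` positions count (-)1, (-)2, ... upstream from the canonical
#' start; `CANONICAL` positions run 1..canonical_len; `THREE_EXTRA`
#' positions count (+)1, (+)2, ... downstream of the canonical end.
#' `to_signed_coord()` and `from_signed_coord()` convert between absolute
#' 1-based positions on the full sequence and zone coordinates; they are
#' mutually inverse over the whole sequence.
#'
#' @param zone One of `"FIVE_EXTRA"`, `"CANONICAL"`, `"THREE_EXTRA"`.
#' @param index Positive integer index within the zone.
#' @return `signed_coord()`: an `la_coord`; `to_signed_coord()`: an
#'   `la_coord`; `from_signed_coord()`: an absolute 1-based position.
#' @export
signed_coord <- function(zone, index) {
  zone <- match.arg(zone, c("FIVE_EXTRA", "CANONICAL", "THREE_EXTRA"))
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stop("coordinate out of bounds")
  structure(list(zone = zone, index = index), class = "la_coord")
}

#' @export
print.la_coord <- function(x, ...) {
  cat(format_coord(x), "\n")
  invisible(x)
}

format_coord <- function(c) {
  switch(c$zone,
         FIVE_EXTRA = sprintf("(-)%d", c$index),
         CANONICAL = sprintf("%d", c$index),
         THREE_EXTRA = sprintf("(+)%d", c$index))
}

#' @rdname signed_coord
#' @param p An `la_partition`.
#' @param absolute_index Absolute 1-based position on the full sequence.
#' @export
to_signed_coord <- function(p, absolute_index) {
  i <- as.integer(absolute_index)
  if (is.na(i) || i < 1L || i > p$sequence$length) {
    stop("coordinate out of bounds: ", absolute_index)
  }
  f <- p$five_extra_len
  cend <- f + p$canonical_len
  if (i <= f) {
    signed_coord("FIVE_EXTRA", f - i + 1L)
  } else if (i <= cend) {
    signed_coord("CANONICAL", i - f)
  } else {
    signed_coord("THREE_EXTRA", i - cend)
  }
}

#' @rdname signed_coord
#' @param coord An `la_coord`.
#' @export
from_signed_coord <- function(p, coord) {
  stopifnot(inherits(coord, "la_coord"))
  f <- p$five_extra_len
  abs <- switch(coord$zone,
    FIVE_EXTRA = {
      if (coord$index > f) stop("coordinate out of bounds: ",
                                format_coord(coord))
      f - coord$index + 1L
    },
    CANONICAL = {
      if (coord$index > p$canonical_len) stop("coordinate out of bounds: ",
                                              format_coord(coord))
      f + coord$index
    },
    THREE_EXTRA = {
      if (coord$index > p$three_extra_len) stop("coordinate out of bounds: ",
                                                format_coord(coord))
      f + p$canonical_len + coord$index
    })
  abs
}

#' Length of a closed coordinate span
#'
#' Counts nucleotides in the closed interval from `start` to `end`,
#' crossing zone boundaries transparently (e.g. from (-)14 in the 5'-extra
#' zone to canonical 37 is 51 nt).
#'
#' @param p An `la_partition`.
#' @param start,end `la_coord` endpoints; `start` must not lie 3' of `end`.
#' @return Integer nucleotide count.
#' @export
span_length <- function(p, start, end) {
  a <- from_signed_coord(p, start)
  b <- from_signed_coord(p, end)
  if (a > b) stop("negative span: ", format_coord(start), " is 3' of ",
                  format_coord(end))
  b - a + 1L
}

## Base-labelled coordinate strings like "C(-)14" used in reports.
coord_label <- function(p, absolute_index) {
  base <- substr(p$sequence$residues, absolute_index, absolute_index)
  paste0(base, format_coord(to_signed_coord(p, absolute_index)))
}

span_label <- function(p, abs_start, abs_end) {
  paste0(coord_label(p, abs_start), "-", coord_label(p, abs_end))
}

## Partition reports ----------------------------------------------------------

#' Export a partition as GFF3 region features or a JSON report
#'
#' @param p An `la_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
partition_gff3 <- function(p, path) {
  f <- p$five_extra_len
  cend <- f + p$canonical_len
  rows <- list()
  if (f > 0L) rows <- c(rows, list(gff3_row(p$sequence$id, "region", 1L, f,
                                            "ID=five_extra;Name=5'-extra")))
  rows <- c(rows, list(gff3_row(p$sequence$id, "region", f + 1L, cend,
                                "ID=canonical;Name=canonical")))
  if (p$three_extra_len > 0L) {
    rows <- c(rows, list(gff3_row(p$sequence$id, "region", cend + 1L,
                                  p$sequence$length,
                                  "ID=three_extra;Name=3'-extra")))
  }
  write_gff3(do.call(rbind, rows), path)
}

#' @rdname partition_gff3
#' @export
partition_report <- function(p, path = NULL) {
  rep <- list(id = p$sequence$id,
              length = p$sequence$length,
              five_extra_len = p$five_extra_len,
              canonical_len = p$canonical_len,
              three_extra_len = p$three_extra_len,
              anchor_5 = p$anchor_5,
              anchor_3 = if (is.null(p$anchor_3)) NA else p$anchor_3,
              anchor_method = p$anchor_method)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  rep
}
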