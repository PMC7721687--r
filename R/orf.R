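## Gag / Pol ORF annotation and the -1 ribosomal frameshift -------------------

GENETIC_CODE1 <- local({
  gc <- Biostrings::GENETIC_CODE
  # index by codon string; stops are "*"
  gc
})

#' Translate a reading frame
#'
#' Standard genetic-code translation of one forward frame. Stop codons are
#' rendered as `"*"`, codons containing `N` as `"X"`, and a trailing
#' partial codon is dropped.
#'
#' @param seq Nucleotide string (`U` read as `T`).
#' @param frame Frame offset 0, 1 or 2 relative to position 1.
#' @return Amino-acid string.
#' @examples
#' translate("ATGGCT", 0)  # "MA"
#' @export
translate <- function(seq, frame = 0L) {
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  start <- frame + 1L
  if (start > n) return("")
  ncod <- (n - frame) %/% 3L
  if (ncod == 0L) return("")
  pos <- start + 3L * (seq_len(ncod) - 1L)
  codons <- substring(seq, pos, pos + 2L)
  aa <- GENETIC_CODE1[codons]
  aa[is.na(aa)] <- "X"
  collapse0(aa)
}

#' Find ATG-initiated, stop-terminated open reading frames
#'
#' Scans the three forward frames. For each stop codon, the ORF reported
#' runs from the first `ATG` after the previous in-frame stop (the longest
#' ORF per stop); nested starts sharing the same stop are not listed
#' separately. Only ORFs terminated by a stop codon within the sequence are
#' returned. The `end` coordinate excludes the stop codon, so
#' `end - start + 1 == 3 * nchar(protein)`.
#'
#' @param seq Nucleotide string (canonical zone).
#' @param min_protein_len Minimum protein length in residues.
#' @return A list of `la_orf` records (`start`, `end`, `frame`, `protein`),
#'   sorted by `start`. May be empty.
#' @export
find_orfs <- function(seq, min_protein_len = 100L) {
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    aa <- chars(translate(seq, frame))
    if (length(aa) == 0L) next
    stops <- which(aa == "*")
    prev <- 0L
    for (s in stops) {
      if (s - prev > 1L) {
        cand <- which(aa[(prev + 1L):(s - 1L)] == "M")
        if (length(cand) > 0L) {
          first_m <- prev + cand[1]
          plen <- s - first_m
          if (plen >= min_protein_len) {
            start <- frame + 3L * (first_m - 1L) + 1L
            out[[length(out) + 1L]] <- structure(
              list(start = start,
                   end = start + 3L * plen - 1L,
                   frame = frame,
                   protein = collapse0(aa[first_m:(s - 1L)])),
              class = "la_orf")
          }
        }
      }
      prev <- s
    }
  }
  out[order(vapply(out, `[[`, 1L, "start"))]
}

#' @export
print.la_orf <- function(x, ...) {
  cat(sprintf("<la_orf> %d..%d frame %d, %d aa\n", x$start, x$end, x$frame,
              nchar(x$protein)))
  invisible(x)
}

#' Detect -1 frameshift slippery heptamers
#'
#' A slippery site matches the XXXYYYZ heptamer pattern: three identical
#' bases, three identical bases, one further base. Under the default strict
#' rule Y must be `A` or `T` and Z must not be `G`, matching heptamers
#' known to drive -1 programmed ribosomal frameshifting (e.g. `GGGTTTA`).
#' With `strict = FALSE` any XXXYYYZ heptamer is reported.
#'
#' @param seq Nucleotide string.
#' @param window Integer vector `c(start, end)` restricting the scan
#'   (positions of heptamer starts; the heptamer may extend past `end`).
#' @param strict Apply the Y/Z composition rule (default `TRUE`).
#' @return A list of `la_slippery` records (`position`, `heptamer`,
#'   `X`, `Y`, `Z`) in 5' to 3' order.
#' @export
detect_slippery_sites <- function(seq, window = NULL, strict = TRUE) {
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  if (is.null(window)) window <- c(1L, n)
  lo <- max(1L, as.integer(window[1]))
  hi <- min(n - 6L, as.integer(window[2]))
  if (hi < lo) return(list())
  pos <- lo:hi
  b <- function(k) substring(seq, pos + k - 1L, pos + k - 1L)
  x1 <- b(1); y1 <- b(4); z <- b(7)
  ok <- x1 == b(2) & x1 == b(3) & y1 == b(5) & y1 == b(6) & x1 != "N" &
    y1 != "N" & z != "N"
  if (strict) ok <- ok & y1 %in% c("A", "T") & z != "G"
  lapply(which(ok), function(i) {
    structure(list(position = pos[i],
                   heptamer = substring(seq, pos[i], pos[i] + 6L),
                   X = x1[i], Y = y1[i], Z = z[i]),
              class = "la_slippery")
  })
}

#' Annotate the Gag / slippery-site / Pol / fusion-protein model
#'
#' On the canonical zone of a partition: Gag is the longest 5'-proximal ORF
#' of Gag-like size; the slippery site is the XXXYYYZ heptamer nearest to
#' (and upstream of) the Gag stop codon; Pol is the longest ORF in frame
#' `(gag.frame - 1) mod 3` whose span overlaps or follows the slippery
#' site. The Gag-Pol fusion protein consists of the Gag residues whose
#' codons end at or before the heptamer's last base, concatenated with the
#' -1-frame translation resuming one nucleotide 5' of the next frame-0
#' codon boundary and continuing to the Pol stop. Re-initiation codons are
#' all in-frame `ATG`s strictly between the Gag end and the Pol start.
#'
#' @param p An `la_partition`.
#' @param min_gag_len Minimum Gag protein length in residues (default 400).
#' @param min_pol_len Minimum Pol protein length in residues (default 200).
#' @param strict_slippery Passed to [detect_slippery_sites()].
#' @return An `la_gagpol` with fields `gag`, `pol`, `slippery`,
#'   `fusion_protein`, `reinit_codons` (canonical coordinates throughout).
#' @export
build_gagpol_model <- function(p, min_gag_len = 400L, min_pol_len = 200L,
                               strict_slippery = TRUE) {
  canon <- canonical_seq(p)
  orfs <- find_orfs(canon, min_protein_len = min_gag_len)
  if (length(orfs) == 0L) stop("no gag: no ORF of >= ", min_gag_len,
                               " residues in the canonical zone")
  gag <- orfs[[1]]  # sorted by start: 5'-proximal; ties cannot occur
  gag_stop_start <- gag$end + 1L
  sites <- detect_slippery_sites(canon, window = c(1L, gag_stop_start - 1L),
                                 strict = strict_slippery)
  if (length(sites) == 0L) {
    stop("no frameshift site: no slippery heptamer upstream of the Gag stop")
  }
  slippery <- sites[[length(sites)]]  # nearest upstream
  pol_frame <- (gag$frame - 1L) %% 3L
  pol_cands <- Filter(function(o) {
    o$frame == pol_frame && (o$end + 3L) >= slippery$position
  }, find_orfs(canon, min_protein_len = min_pol_len))
  if (length(pol_cands) == 0L) {
    stop("no pol: no ORF of >= ", min_pol_len, " residues in frame ",
         pol_frame, " overlapping or following the slippery site")
  }
  pol <- pol_cands[[which.max(vapply(pol_cands,
                                     function(o) nchar(o$protein), 1L))]]
  h7 <- slippery$position + 6L
  m <- (h7 - gag$start + 1L) %/% 3L         # gag codons retained
  gag_prefix <- substr(gag$protein, 1L, m)
  q <- gag$start + 3L * m - 1L              # -1 frame resume point
  tail_aa <- translate(substr(canon, q, pol$end + 3L), 0L)
  stop_at <- regexpr("*", tail_aa, fixed = TRUE)
  if (stop_at > 0L) tail_aa <- substr(tail_aa, 1L, stop_at - 1L)
  fusion <- paste0(gag_prefix, tail_aa)
  # in-frame ATGs strictly between the Gag end and the Pol start
  atg <- literal_matches(canon, "ATG")
  reinit <- atg[atg > gag$end & atg < pol$start &
                  (atg - 1L) %% 3L == pol_frame]
  structure(list(gag = gag, pol = pol, slippery = slippery,
                 fusion_protein = fusion,
                 reinit_codons = as.integer(reinit)),
            class = "la_gagpol")
}

#' @export
print.la_gagpol <- function(x, ...) {
  cat(sprintf(paste0("<la_gagpol> gag %d..%d (%d aa) | slippery %s at %d | ",
                     "pol %d..%d (%d aa) | fusion %d aa | %d reinit codon(s)\n"),
              x$gag$start, x$gag$end, nchar(x$gag$protein),
              x$slippery$heptamer, x$slippery$position,
              x$pol$start, x$pol$end, nchar(x$pol$protein),
              nchar(x$fusion_protein), length(x$reinit_codons)))
  invisible(x)
}

#' Export Gag-Pol annotations as GFF3
#'
#' CDS features for Gag and Pol, a `sequence_feature` for the slippery
#' site, with frame and re-initiation codons in the attribute column.
#' Coordinates are absolute 1-based positions on the full sequence.
#'
#' @param p An `la_partition`.
#' @param gp An `la_gagpol`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
gagpol_gff3 <- function(p, gp, path) {
  off <- p$five_extra_len
  id <- p$sequence$id
  reinit <- if (length(gp$reinit_codons)) {
    paste0(";reinit_codons=", paste(gp$reinit_codons + off, collapse = ","))
  } else ""
  rows <- rbind(
    gff3_row(id, "CDS", gp$gag$start + off, gp$gag$end + off,
             paste0("ID=gag;frame=", gp$gag$frame)),
    gff3_row(id, "CDS", gp$pol$start + off, gp$pol$end + off,
             paste0("ID=pol;frame=", gp$pol$frame, reinit)),
    gff3_row(id, "sequence_feature", gp$slippery$position + off,
             gp$slippery$position + 6L + off,
             paste0("ID=slippery_site;heptamer=", gp$slippery$heptamer)))
  write_gff3(rows, path)
}
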