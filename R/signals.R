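## Cis-signal discovery: 5' motif, AU-rich stretch, the three stem loops -----

new_signal <- function(kind, abs_span, p, hairpin = NULL, note = "",
                       extra = list()) {
  structure(c(list(kind = kind,
                   abs_span = as.integer(abs_span),
                   location = span_label(p, abs_span[1], abs_span[2]),
                   hairpin = hairpin,
                   note = note), extra),
            class = "la_signal")
}

#' @export
print.la_signal <- function(x, ...) {
  cat(sprintf("<la_signal> %s at %s%s%s\n", x$kind, x$location,
              if (!is.null(x$hairpin))
                sprintf(" (dG %.1f kJ/mol)", x$hairpin$dG_kJ) else "",
              if (nzchar(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}

## Best hairpin in a canonical-coordinate window, optionally requiring the
## hairpin to start within the first `start_within` window positions.
best_window_hairpin <- function(canon, lo, hi, model, start_within = NULL) {
  win <- substr(canon, lo, hi)
  if (nchar(win) < 5L) return(NULL)
  sr <- if (is.null(start_within)) NULL else c(1L, start_within)
  hp <- fold_hairpin(win, model, start_range = sr)
  if (is.null(hp)) return(NULL)
  hp$abs_span_canonical <- c(lo + hp$span[1] - 1L, lo + hp$span[2] - 1L)
  hp
}

#' Locate the conserved cis-signals of an LA genome
#'
#' Finds, on the canonical zone of `p`:
#' * `FIVE_PRIME_MOTIF` - the conserved 5' motif (the partition's 5'
#'   anchor, e.g. `GAAAAA`) within canonical positions 1-10;
#' * `AU_RICH` - the 15-nt window of the 5' UTR with the highest AU
#'   fraction (5'-most on ties), reported with its `au_fraction`;
#' * `FRAMESHIFT_SL` - the best hairpin whose span begins within 12 nt 3'
#'   of the slippery heptamer;
#' * `PACKAGING_SL` - the best 20-30 nt hairpin in the 3' half of the
#'   canonical zone, ranked by loop-sequence identity to the reference
#'   packaging loop when `ref_packaging_loop` is given, else by free
#'   energy (loop conservation matters more than stem sequence for this
#'   signal);
#' * `REPLICATION_SL` - the best hairpin lying wholly within the last 40
#'   canonical nucleotides.
#'
#' @param p An `la_partition`.
#' @param gp An `la_gagpol` for the same partition.
#' @param ref_packaging_loop Optional reference packaging-loop string used
#'   to rank packaging-hairpin candidates.
#' @param model An `la_energy_model`.
#' @return A named list of `la_signal` records. `FRAMESHIFT_SL` is skipped
#'   with a warning if `gp` lacks a slippery site.
#' @export
find_signal_stemloops <- function(p, gp, ref_packaging_loop = NULL,
                                  model = NULL) {
  if (is.null(model)) model <- default_energy_model()
  canon <- canonical_seq(p)
  n <- nchar(canon)
  off <- p$five_extra_len
  out <- list()

  # 5' conserved motif within canonical 1..10
  motif <- p$anchor_5
  m <- literal_matches(substr(canon, 1L, 10L + nchar(motif)), motif)
  m <- m[m <= 10L]
  if (length(m) > 0L) {
    out$FIVE_PRIME_MOTIF <- new_signal(
      "FIVE_PRIME_MOTIF", off + c(m[1], m[1] + nchar(motif) - 1L), p,
      note = motif)
  }

  # AU-rich 15-mer in the 5' UTR
  utr_end <- gp$gag$start - 1L
  if (utr_end >= 15L) {
    v <- chars(substr(canon, 1L, utr_end))
    au <- as.integer(v %in% c("A", "T"))
    win <- stats::filter(au, rep(1, 15), sides = 1)[15:length(au)]
    best <- which.max(win)  # 5'-most maximum
    frac <- win[best] / 15
    out$AU_RICH <- new_signal("AU_RICH", off + c(best, best + 14L), p,
                              note = sprintf("AU fraction %.3f", frac),
                              extra = list(au_fraction = frac))
  }

  # frameshift stem loop: starts within 12 nt 3' of the heptamer
  if (!is.null(gp$slippery)) {
    h7 <- gp$slippery$position + 6L
    lo <- h7 + 1L
    hi <- min(n, h7 + 12L + 64L)
    hp <- best_window_hairpin(canon, lo, hi, model, start_within = 12L)
    if (!is.null(hp)) {
      out$FRAMESHIFT_SL <- new_signal(
        "FRAMESHIFT_SL", off + hp$abs_span_canonical, p, hairpin = hp,
        note = sprintf("adjacent to slippery %s at canonical %d",
                       gp$slippery$heptamer, gp$slippery$position))
    }
  } else {
    warning("no slippery site: skipping FRAMESHIFT_SL")
  }

  # packaging stem loop: 20-30 nt hairpin in the 3' half
  half <- (n %/% 2L) + 1L
  cands <- list()
  starts <- seq(half, n - 33L, by = 3L)
  for (s in starts) {
    hp <- best_window_hairpin(canon, s, s + 33L, model)
    if (!is.null(hp)) {
      sp <- hp$abs_span_canonical[2] - hp$abs_span_canonical[1] + 1L
      if (sp >= 20L && sp <= 30L) cands[[length(cands) + 1L]] <- hp
    }
  }
  if (length(cands) > 0L) {
    key <- vapply(cands, function(h)
      paste(h$abs_span_canonical, collapse = "-"), "")
    cands <- cands[!duplicated(key)]
    if (!is.null(ref_packaging_loop)) {
      score <- vapply(cands, function(h)
        loop_identity(h$loop_seq, ref_packaging_loop), 0)
      ord <- order(-score, vapply(cands, function(h) h$dG_kcal, 0))
    } else {
      ord <- order(vapply(cands, function(h) h$dG_kcal, 0))
    }
    hp <- cands[[ord[1]]]
    out$PACKAGING_SL <- new_signal("PACKAGING_SL",
                                   off + hp$abs_span_canonical, p,
                                   hairpin = hp)
  }

  # replication stem loop: wholly within the last 40 canonical nt
  hp <- best_window_hairpin(canon, max(1L, n - 39L), n, model)
  if (!is.null(hp)) {
    out$REPLICATION_SL <- new_signal("REPLICATION_SL",
                                     off + hp$abs_span_canonical, p,
                                     hairpin = hp)
  }
  out
}

## Ungapped loop-sequence identity (loops are short; compare best sliding
## register of the shorter within the longer).
loop_identity <- function(a, b) {
  a <- chartr("T", "U", normalize_dna(a))
  b <- chartr("T", "U", normalize_dna(b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ca <- chars(a); la <- length(ca)
  cb <- chars(b)
  best <- 0
  for (s in 0:(length(cb) - la)) {
    best <- max(best, sum(ca == cb[s + seq_len(la)]))
  }
  best / la
}

#' Export signal annotations as GFF3
#'
#' @param p An `la_partition`.
#' @param signals Result of [find_signal_stemloops()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
signals_gff3 <- function(p, signals, path) {
  rows <- lapply(signals, function(s) {
    attrs <- paste0("ID=", s$kind, ";kind=", s$kind)
    if (!is.null(s$hairpin)) {
      attrs <- paste0(attrs, sprintf(";dG_kJ=%.1f;structure=%s",
                                     s$hairpin$dG_kJ,
                                     s$hairpin$dot_bracket))
    }
    gff3_row(p$sequence$id, "sequence_feature", s$abs_span[1], s$abs_span[2],
             attrs)
  })
  write_gff3(do.call(rbind, rows), path)
}
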