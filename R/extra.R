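## Extra-sequence characterization -------------------------------------------

## Maximal exact matches (>= min_len) between a query string and a subject
## string, via k-mer seeding + maximal extension. Positions are 1-based in
## each string. `skip_diagonal` drops matches where the two strings are the
## same sequence region (same absolute position, used for self-identity).
maximal_exact_matches <- function(query, subject, min_len,
                                  q_offset = 0L, s_offset = 0L,
                                  require_disjoint = TRUE) {
  k <- as.integer(min_len)
  nq <- nchar(query)
  ns <- nchar(subject)
  if (nq < k || ns < k) return(NULL)
  sub_kmers <- substring(subject, 1:(ns - k + 1L), k:ns)
  idx <- split(seq_len(ns - k + 1L), sub_kmers)
  q_starts <- 1:(nq - k + 1L)
  q_kmers <- substring(query, q_starts, q_starts + k - 1L)
  qc <- chars(query)
  sc <- chars(subject)
  hits <- list()
  seen <- character(0)
  for (qi in q_starts) {
    sps <- idx[[q_kmers[qi]]]
    if (is.null(sps)) next
    for (si in sps) {
      # extend left
      a <- qi; b <- si
      while (a > 1L && b > 1L && qc[a - 1L] == sc[b - 1L] &&
               qc[a - 1L] != "N") {
        a <- a - 1L; b <- b - 1L
      }
      key <- paste(a, b, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      # extend right
      e <- qi + k - 1L; f <- si + k - 1L
      while (e < nq && f < ns && qc[e + 1L] == sc[f + 1L] &&
               qc[e + 1L] != "N") {
        e <- e + 1L; f <- f + 1L
      }
      len <- e - a + 1L
      if (len < k) next
      qa <- a + q_offset; qe <- e + q_offset
      sa <- b + s_offset; se <- f + s_offset
      if (require_disjoint && qa <= se && sa <= qe) next  # overlapping spans
      hits[[length(hits) + 1L]] <-
        data.frame(q_start = qa, q_end = qe, s_start = sa, s_end = se,
                   length = len)
    }
  }
  if (length(hits) == 0L) return(NULL)
  out <- unique(do.call(rbind, hits))
  # drop matches contained in a longer one on both axes
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i != j && keep[i] &&
            out$q_start[j] <= out$q_start[i] && out$q_end[j] >= out$q_end[i] &&
            out$s_start[j] <= out$s_start[i] && out$s_end[j] >= out$s_end[i] &&
            out$length[j] > out$length[i]) {
        keep[i] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(-out$length, out$q_start), , drop = FALSE]
}

#' Find viral self-identity between extra and canonical sequence
#'
#' Reports all maximal exact matches of at least `min_len` nucleotides
#' between windows overlapping either extra zone (extended by up to
#' `flank` nt of adjacent canonical sequence, because such repeats often
#' span the zone boundary) and the canonical zone, requiring the two
#' absolute intervals to be disjoint. Matches are sorted by length,
#' longest first.
#'
#' @param p An `la_partition` with at least one non-empty extra zone.
#' @param min_len Minimum match length (default 13 nt).
#' @param flank Canonical flank included in the query windows (default 60).
#' @return A data frame with absolute query/subject intervals, the match
#'   length, percent identity (100, exact mode) and coordinate labels in
#'   the signed convention, or an empty data frame.
#' @export
find_self_identity <- function(p, min_len = 13L, flank = 60L) {
  if (p$five_extra_len == 0L && p$three_extra_len == 0L) {
    stop("partition has no extra zones")
  }
  res <- p$sequence$residues
  n <- p$sequence$length
  f <- p$five_extra_len
  cend <- f + p$canonical_len
  canon <- canonical_seq(p)
  out <- list()
  if (f > 0L) {
    q_end <- min(n, f + flank)
    out$five <- maximal_exact_matches(substr(res, 1L, q_end), canon,
                                      min_len, q_offset = 0L, s_offset = f)
  }
  if (p$three_extra_len > 0L) {
    q_start <- max(1L, cend - flank + 1L)
    out$three <- maximal_exact_matches(substr(res, q_start, n), canon,
                                       min_len, q_offset = q_start - 1L,
                                       s_offset = f)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty_self_identity())
  out <- unique(out)
  out$identity <- 100
  out$query_label <- vapply(seq_len(nrow(out)), function(i)
    span_label(p, out$q_start[i], out$q_end[i]), "")
  out$subject_label <- vapply(seq_len(nrow(out)), function(i)
    span_label(p, out$s_start[i], out$s_end[i]), "")
  rownames(out) <- NULL
  out[order(-out$length, out$q_start), , drop = FALSE]
}

empty_self_identity <- function() {
  data.frame(q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             length = integer(0), identity = numeric(0),
             query_label = character(0), subject_label = character(0))
}

#' Find stretches shared between the extra zones of two viruses
#'
#' Maximal common substrings of at least `min_len` nucleotides between the
#' selected zone of two partitions, longest first.
#'
#' @param p_a,p_b `la_partition`s with non-empty selected zones.
#' @param zone `"FIVE_EXTRA"` (default) or `"THREE_EXTRA"`.
#' @param min_len Minimum stretch length (default 13 nt).
#' @return A data frame with the shared stretch, its span in each virus
#'   (absolute and labelled) and its length; empty if none.
#' @export
find_shared_stretches <- function(p_a, p_b, zone = "FIVE_EXTRA",
                                  min_len = 13L) {
  zone <- match.arg(zone, c("FIVE_EXTRA", "THREE_EXTRA"))
  zs <- function(p) if (zone == "FIVE_EXTRA") extra5_seq(p) else extra3_seq(p)
  zoff <- function(p) if (zone == "FIVE_EXTRA") 0L else
    p$five_extra_len + p$canonical_len
  sa <- zs(p_a); sb <- zs(p_b)
  if (!nzchar(sa) || !nzchar(sb)) stop("selected zone is empty")
  m <- maximal_exact_matches(sa, sb, min_len, require_disjoint = FALSE)
  if (is.null(m) || nrow(m) == 0L) {
    return(data.frame(virus_a = character(0), virus_b = character(0),
                      stretch = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), length = integer(0),
                      span_a = character(0), span_b = character(0)))
  }
  a0 <- zoff(p_a); b0 <- zoff(p_b)
  out <- data.frame(
    virus_a = p_a$sequence$id, virus_b = p_b$sequence$id,
    stretch = substring(sa, m$q_start, m$q_end),
    a_start = m$q_start + a0, a_end = m$q_end + a0,
    b_start = m$s_start + b0, b_end = m$s_end + b0,
    length = m$length)
  out$span_a <- vapply(seq_len(nrow(out)), function(i)
    span_label(p_a, out$a_start[i], out$a_end[i]), "")
  out$span_b <- vapply(seq_len(nrow(out)), function(i)
    span_label(p_b, out$b_start[i], out$b_end[i]), "")
  out[order(-out$length, out$a_start), , drop = FALSE]
}

#' Scan for near-palindromic stretches
#'
#' Finds arm pairs where the left arm equals the reverse complement of the
#' right arm up to `max_mismatch` mismatches, separated by a loop of at
#' most `max_loop` nucleotides. Arms are maximal (not extendable without
#' exceeding the mismatch budget), end on a matching pair, and hits whose
#' span is contained in a longer hit's span are dropped.
#'
#' @param seq Nucleotide string.
#' @param min_arm Minimum arm length (default 8).
#' @param max_loop Maximum loop length (default 8).
#' @param max_mismatch Maximum arm mismatches (default 2).
#' @return A data frame with `start`, `end` (1-based span), `arm_len`,
#'   `loop_len`, `mismatches`.
#' @export
palindrome_scan <- function(seq, min_arm = 8L, max_loop = 8L,
                            max_mismatch = 2L) {
  s <- chars(normalize_dna(seq))
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  hits <- list()
  for (g in 0:max_loop) {
    for (c0 in seq_len(n - g)) {       # loop occupies c0 .. c0+g-1
      l <- c0 - 1L
      r <- c0 + g
      arm <- 0L
      mism <- 0L
      best <- NULL
      while (l >= 1L && r <= n) {
        match_here <- comp[[s[l]]] == s[r]
        if (!match_here) {
          mism <- mism + 1L
          if (mism > max_mismatch) break
        }
        arm <- arm + 1L
        if (match_here && arm >= min_arm) {
          best <- c(l, r, arm, mism)   # arms end on a matching pair
        }
        l <- l - 1L
        r <- r + 1L
      }
      if (!is.null(best)) {
        hits[[length(hits) + 1L]] <-
          data.frame(start = best[1], end = best[2], arm_len = best[3],
                     loop_len = g, mismatches = best[4])
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      arm_len = integer(0), loop_len = integer(0),
                      mismatches = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  # non-redundant: drop hits whose span is contained in another hit's span
  # (same-span hits collapse to the largest arm)
  ord <- order(-(out$end - out$start), -out$arm_len, out$start)
  out <- out[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    inside <- out$start >= out$start[i] & out$end <= out$end[i] &
      (out$end - out$start < out$end[i] - out$start[i] |
         out$arm_len < out$arm_len[i])
    inside[i] <- FALSE
    keep[inside] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$start, out$end), , drop = FALSE]
}

#' Match extra sequences against candidate host sequences
#'
#' Local alignment (Smith-Waterman through Biostrings, affine gaps, both
#' strands) of an extra zone (plus `flank` nt of adjacent canonical
#' sequence) against each record of a host database, reporting alignments
#' that reach `min_len` aligned columns and `min_identity` percent
#' identity. Identity is identical columns divided by aligned columns.
#' One best local alignment is reported per host record and strand.
#'
#' @param p An `la_partition`.
#' @param zone `"FIVE_EXTRA"` or `"THREE_EXTRA"`.
#' @param host_db List of [viral_sequence()] records (e.g. rRNA or
#'   chromosome fragments) or a FASTA path.
#' @param min_len Minimum aligned length (default 50).
#' @param min_identity Minimum percent identity (default 85).
#' @param flank Canonical flank added to the query (default 60).
#' @return A data frame with `host_id`, `identity`, `length`, query and
#'   subject intervals and `strand`.
#' @export
match_host_sequences <- function(p, zone = "FIVE_EXTRA", host_db,
                                 min_len = 50L, min_identity = 85,
                                 flank = 60L) {
  zone <- match.arg(zone, c("FIVE_EXTRA", "THREE_EXTRA"))
  if (is.character(host_db) && length(host_db) == 1L) {
    host_db <- read_fasta(host_db)
  }
  if (length(host_db) == 0L) stop("no host records")
  n <- p$sequence$length
  f <- p$five_extra_len
  cend <- f + p$canonical_len
  if (zone == "FIVE_EXTRA") {
    q_start <- 1L; q_end <- min(n, f + flank)
  } else {
    q_start <- max(1L, cend - flank + 1L); q_end <- n
  }
  query <- substr(p$sequence$residues, q_start, q_end)
  rows <- list()
  for (h in host_db) {
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") h$residues else revcomp(h$residues)
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(query),
        subject = Biostrings::DNAString(subj),
        type = "local", substitutionMatrix = nt_submat(),
        gapOpening = 10, gapExtension = 0.5)
      st <- alignment_stats(aln)
      if (st$cols >= min_len && st$identity >= min_identity) {
        qr <- c(Biostrings::start(Biostrings::pattern(aln)),
                Biostrings::end(Biostrings::pattern(aln)))
        sr <- c(Biostrings::start(Biostrings::subject(aln)),
                Biostrings::end(Biostrings::subject(aln)))
        if (strand == "-") sr <- c(h$length - sr[2] + 1L,
                                   h$length - sr[1] + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          host_id = h$id, identity = round(st$identity, 1),
          length = st$cols,
          q_start = qr[1] + q_start - 1L, q_end = qr[2] + q_start - 1L,
          s_start = sr[1], s_end = sr[2], strand = strand)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(host_id = character(0), identity = numeric(0),
                      length = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$identity * out$length), , drop = FALSE]
}
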