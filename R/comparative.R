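## Region-resolved identity matrices, conserved residues, NJ phylograms ------

nt_submat <- function() {
  # ClustalW-like DNA scoring: match +5, mismatch -4
  Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                           baseOnly = TRUE)
}

aa_submat <- function() {
  getdata <- function(nm) {
    e <- new.env()
    utils::data(list = nm, package = "Biostrings", envir = e)
    get(nm, envir = e)
  }
  getdata("BLOSUM62")
}

## identical columns / columns where both are non-gap, from an alignment
alignment_stats <- function(aln) {
  a <- chars(as.character(Biostrings::alignedPattern(aln)))
  b <- chars(as.character(Biostrings::alignedSubject(aln)))
  both <- a != "-" & b != "-"
  cols <- sum(both)
  list(cols = cols,
       identity = if (cols == 0) 0 else 100 * sum(a[both] == b[both]) / cols)
}

global_align <- function(a, b, kind) {
  if (kind == "NT") {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(normalize_dna(a)),
      subject = Biostrings::DNAString(normalize_dna(b)),
      type = "global", substitutionMatrix = nt_submat(),
      gapOpening = 10, gapExtension = 0.5)
  } else {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
      type = "global", substitutionMatrix = aa_submat(),
      gapOpening = 10, gapExtension = 0.5)
  }
}

#' Percent identity between two sequences
#'
#' Global alignment with affine gaps (nucleotides: match +5 / mismatch -4,
#' gap open 10 / extend 0.5; amino acids: BLOSUM62, gap open 10 /
#' extend 0.5). Identity is identical columns divided by columns where
#' both sequences are non-gap, times 100, rounded to one decimal.
#'
#' @param a,b Sequences (strings).
#' @param kind `"NT"` or `"AA"`.
#' @return Percent identity (one decimal).
#' @examples
#' pairwise_identity("ACGT", "ACGA", "NT")  # 75
#' @export
pairwise_identity <- function(a, b, kind = c("NT", "AA")) {
  kind <- match.arg(kind)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  round(alignment_stats(global_align(a, b, kind))$identity, 1)
}

#' Region specification on an annotated reference
#'
#' Named interval on a reference sequence (protein or nucleotide space)
#' used to slice comparable regions out of target sequences through a
#' pairwise alignment: e.g. the Gag domain, the central third of the RdRp,
#' or the 19-aa / 44-aa variable stretches.
#'
#' @param name Region label, e.g. `"VAR44_AA"`.
#' @param start,end Reference interval (1-based, inclusive).
#' @param kind `"AA"` or `"NT"`.
#' @return An `la_region`.
#' @export
region_spec <- function(name, start, end, kind = c("AA", "NT")) {
  kind <- match.arg(kind)
  stopifnot(start >= 1L, end >= start)
  structure(list(name = name, start = as.integer(start),
                 end = as.integer(end), kind = kind), class = "la_region")
}

#' Extract the region of a target aligned to a reference interval
#'
#' Globally aligns `target` with `reference` and returns the target
#' subsequence spanned by the alignment columns of the reference interval
#' in `region`. On the reference itself this returns exactly the
#' reference interval.
#'
#' @param target,reference Sequences (strings, both in `region$kind`
#'   space).
#' @param region An [region_spec()].
#' @return Target subsequence (string).
#' @export
extract_region <- function(target, reference, region) {
  stopifnot(inherits(region, "la_region"))
  if (region$end > nchar(reference)) {
    stop("region beyond reference length")
  }
  aln <- global_align(target, reference, region$kind)
  pat <- chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- chars(as.character(Biostrings::alignedSubject(aln)))
  sub_pos <- cumsum(sub != "-")
  cols <- which(sub_pos >= region$start & sub_pos <= region$end & sub != "-")
  if (length(cols) == 0L) stop("region lost in alignment")
  piece <- pat[min(cols):max(cols)]
  piece <- piece[piece != "-"]
  if (length(piece) == 0L) stop("region lost in alignment")
  collapse0(piece)
}

#' Pairwise percent-identity matrix over a region
#'
#' All pairwise identities between labelled sequences, optionally computed
#' on the region extracted against a reference (pairwise alignments, not a
#' multiple alignment, so the result is independent of input order).
#'
#' @param seqs Named character vector of sequences (>= 2).
#' @param kind `"NT"` or `"AA"`.
#' @param region Optional [region_spec()]; requires `reference`.
#' @param reference Reference sequence (string) the region is defined on.
#' @return An `la_identity_matrix`: fields `labels`, `values` (symmetric
#'   percent matrix with 100 diagonal), `region`, `aligner_settings`.
#' @export
identity_matrix <- function(seqs, kind = c("NT", "AA"), region = NULL,
                            reference = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (!is.null(region)) {
    if (is.null(reference)) stop("region extraction requires a reference")
    kind <- region$kind
    seqs <- vapply(seqs, function(s)
      tryCatch(extract_region(s, reference, region),
               error = function(e) {
                 warning("region extraction failed: ", conditionMessage(e))
                 NA_character_
               }), "")
  }
  labels <- names(seqs)
  k <- length(seqs)
  m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(m) <- 100
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!is.na(seqs[i]) && !is.na(seqs[j])) {
        v <- pairwise_identity(seqs[[i]], seqs[[j]], kind)
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  structure(list(labels = labels, values = m,
                 region = if (is.null(region)) kind else region$name,
                 aligner_settings = list(
                   kind = kind, gap_opening = 10, gap_extension = 0.5,
                   nt_match = 5, nt_mismatch = -4, aa_matrix = "BLOSUM62")),
            class = "la_identity_matrix")
}

#' @export
print.la_identity_matrix <- function(x, ...) {
  cat(sprintf("<la_identity_matrix> %d taxa, region %s\n",
              length(x$labels), x$region))
  print(round(x$values, 1))
  invisible(x)
}

#' Write an identity matrix as TSV
#'
#' @param m An `la_identity_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
identity_matrix_tsv <- function(m, path) {
  df <- data.frame(label = m$labels, m$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check conserved Gag / Pol residues against a reference
#'
#' Aligns a Gag-Pol protein with an annotated reference and reports
#' whether the cap-snatching histidine (reference position 154 by
#' default; position 153 in some viruses is the same aligned site) and
#' the four cap-recognition residues are conserved, and the percent
#' identity of the RdRp A-D motifs.
#'
#' @param gagpol Target Gag-Pol protein (string).
#' @param reference Reference Gag-Pol protein (string).
#' @param h_pos Reference position of the cap-snatching His (default 154).
#' @param cap_pos Named reference positions of the cap-recognition
#'   residues (defaults Tyr-150, Asp-152, Tyr-452, Tyr-538).
#' @param motifs Named list of reference intervals `c(start, end)` for the
#'   RdRp A-D motifs (optional).
#' @return An `la_residue_panel` with fields `h154`, `cap_residues`,
#'   `rdrp_motifs`.
#' @export
check_conserved_residues <- function(gagpol, reference, h_pos = 154L,
                                     cap_pos = c(Y150 = 150L, D152 = 152L,
                                                 Y452 = 452L, Y538 = 538L),
                                     motifs = NULL) {
  aln <- tryCatch(global_align(gagpol, reference, "AA"),
                  error = function(e) stop("unalignable: ",
                                           conditionMessage(e)))
  pat <- chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- chars(as.character(Biostrings::alignedSubject(aln)))
  sub_pos <- cumsum(sub != "-")
  at_ref <- function(pos) {
    col <- which(sub_pos == pos & sub != "-")[1]
    if (is.na(col)) return(c(NA, NA))
    c(pat[col], sub[col])
  }
  h <- at_ref(h_pos)
  h154 <- !any(is.na(h)) && h[1] == h[2]
  cap <- vapply(cap_pos, function(pos) {
    v <- at_ref(pos)
    !any(is.na(v)) && v[1] == v[2]
  }, TRUE)
  motif_id <- NULL
  if (!is.null(motifs)) {
    motif_id <- vapply(motifs, function(iv) {
      cols <- which(sub_pos >= iv[1] & sub_pos <= iv[2] & sub != "-")
      if (length(cols) == 0L) return(NA_real_)
      both <- pat[cols] != "-" & sub[cols] != "-"
      if (!any(both)) return(0)
      100 * sum(pat[cols][both] == sub[cols][both]) / length(cols)
    }, 0)
  }
  structure(list(h154 = h154, cap_residues = cap, rdrp_motifs = motif_id),
            class = "la_residue_panel")
}

#' @export
print.la_residue_panel <- function(x, ...) {
  cat(sprintf("<la_residue_panel> His154 %s; cap residues %s\n",
              x$h154, paste(names(x$cap_residues), x$cap_residues,
                            sep = "=", collapse = " ")))
  if (!is.null(x$rdrp_motifs)) {
    cat("  RdRp motifs:", paste(names(x$rdrp_motifs),
                                round(x$rdrp_motifs, 1),
                                sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Neighbor-joining phylogram from an identity matrix
#'
#' Distances are `1 - identity/100`; the tree is built with
#' neighbor-joining (labels are sorted first so the result is independent
#' of input order) and negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param m An `la_identity_matrix` with at least 3 labels.
#' @return An `la_phylogram`: fields `tree` (an `ape::phylo`), `newick`,
#'   `distance_basis`, `method`.
#' @export
nj_phylogram <- function(m) {
  stopifnot(inherits(m, "la_identity_matrix"))
  if (length(m$labels) < 3L) stop("too few taxa for neighbor-joining")
  ord <- order(m$labels)
  d <- stats::as.dist(1 - m$values[ord, ord] / 100)
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative neighbor-joining branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  structure(list(tree = tree,
                 newick = ape::write.tree(tree),
                 distance_basis = "1 - identity/100",
                 method = "neighbor-joining"),
            class = "la_phylogram")
}

#' @export
print.la_phylogram <- function(x, ...) {
  cat("<la_phylogram>", x$newick, "\n")
  invisible(x)
}
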