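## Hairpin folding interface --------------------------------------------------

model_for_cpp <- function(model) {
  # flatten to plain numerics for the C++ engine
  list(stack = unname(model$stack),
       mismatch_hairpin = as.numeric(model$mismatch_hairpin),
       mismatch_internal = as.numeric(model$mismatch_internal),
       mismatch_internal_1n = as.numeric(model$mismatch_internal_1n),
       mismatch_internal_23 = as.numeric(model$mismatch_internal_23),
       hairpin_init = model$hairpin_init,
       bulge_init = model$bulge_init,
       internal_init = model$internal_init,
       terminal_au = model$terminal_au,
       ninio = model$ninio,
       ninio_max = model$ninio_max,
       terminal_mismatch = model$terminal_mismatch,
       max_loop = model$max_loop)
}

## Energy of a closed hairpin (i,j): V(i,j) + terminal AU/GU penalty at the
## outermost pair (the exterior-loop contribution of the helix end).
closed_energies <- function(code, V, model) {
  n <- length(code)
  E <- V
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (is.finite(V[i, j]) && V[i, j] < 1e8) {
        t <- pair_type(code[i], code[j])
        E[i, j] <- V[i, j] + if (t >= 3) model$terminal_au else 0
      } else E[i, j] <- Inf
    }
  }
  E
}

build_hairpin <- function(seq_rna, code, V, model, i, j) {
  pairs <- cpp_traceback(code, model_for_cpp(model), V, i, j)
  inner <- pairs[nrow(pairs), ]
  loop <- c(inner[1] + 1L, inner[2] - 1L)
  t <- pair_type(code[i], code[j])
  dg <- V[i, j] + if (t >= 3) model$terminal_au else 0
  db <- rep(".", nchar(seq_rna))
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  structure(list(
    pairs = pairs,
    loop = loop,
    loop_seq = substr(seq_rna, loop[1], loop[2]),
    dG_kcal = dg,
    dG_kJ = dg * 4.184,
    span = c(i, j),
    dot_bracket = collapse0(db),
    sequence = seq_rna), class = "la_hairpin")
}

#' @export
print.la_hairpin <- function(x, ...) {
  cat(sprintf("<la_hairpin> span %d..%d, loop '%s', dG = %.2f kcal/mol (%.1f kJ/mol)\n",
              x$span[1], x$span[2], x$loop_seq, x$dG_kcal, x$dG_kJ))
  cat(" ", x$sequence, "\n ", x$dot_bracket, "\n")
  invisible(x)
}

#' Fold a short sequence into its minimum-free-energy hairpin
#'
#' Dynamic programming over nested single-hairpin structures (stacks,
#' bulges up to 30 nt, interior loops up to 30 nt, hairpin loops of 3-30
#' nt; no multiloops, no pseudoknots) with the nearest-neighbor model of
#' [load_energy_model()]. `T` is read as `U`. The reported free energy is
#' the closed-hairpin energy including the terminal AU/GU penalty of the
#' outermost pair; unpaired flanking nucleotides contribute nothing.
#' Ties are broken toward the smallest span, then the 5'-most hairpin.
#'
#' @param seq Nucleotide string, 5-200 nt.
#' @param model An `la_energy_model` (defaults to the embedded tables).
#' @param start_range Optional integer `c(lo, hi)`: only hairpins whose
#'   first paired base lies in this range are considered.
#' @return An `la_hairpin` (fields `pairs`, `loop`, `loop_seq`, `dG_kcal`,
#'   `dG_kJ`, `span`, `dot_bracket`), or `NULL` if no structure with
#'   negative free energy exists.
#' @examples
#' fold_hairpin("GGGGAAAACCCC")
#' @export
fold_hairpin <- function(seq, model = NULL, start_range = NULL) {
  if (is.null(model)) model <- default_energy_model()
  n <- nchar(seq)
  if (n < 5L) stop("sequence too short to fold (< 5 nt)")
  if (n > 200L) stop("sequence too long (> 200 nt): use enumerate on windows")
  seq_rna <- chartr("T", "U", normalize_dna(seq))
  code <- encode_rna(seq_rna)
  V <- cpp_fold_matrix(code, model_for_cpp(model))
  E <- closed_energies(code, V, model)
  if (!is.null(start_range)) {
    keep <- seq_len(nrow(E)) >= start_range[1] &
      seq_len(nrow(E)) <= start_range[2]
    E[!keep, ] <- Inf
  }
  if (!any(is.finite(E)) || min(E) >= 0) return(NULL)
  idx <- which(E == min(E), arr.ind = TRUE)
  # tie-break: smallest span, then 5'-most
  spans <- idx[, 2] - idx[, 1]
  idx <- idx[order(spans, idx[, 1]), , drop = FALSE]
  build_hairpin(seq_rna, code, V, model, idx[1, 1], idx[1, 2])
}

#' Enumerate near-optimal hairpins
#'
#' Lists the optimal hairpin for every distinct outermost pair whose
#' closed free energy lies within `suboptimality_percent` of the minimum,
#' best first, capped at `max_count`. With `suboptimality_percent = 0`
#' only ties with the minimum-free-energy structure are returned.
#'
#' @inheritParams fold_hairpin
#' @param suboptimality_percent Energy window as a percentage of the
#'   minimum free energy (default 5).
#' @param max_count Upper bound on the number of hairpins (default 50).
#' @return A list of `la_hairpin`, possibly empty.
#' @export
enumerate_hairpins <- function(seq, model = NULL, suboptimality_percent = 5,
                               max_count = 50L) {
  if (is.null(model)) model <- default_energy_model()
  n <- nchar(seq)
  if (n < 5L) stop("sequence too short to fold (< 5 nt)")
  if (n > 200L) stop("sequence too long (> 200 nt): use enumerate on windows")
  seq_rna <- chartr("T", "U", normalize_dna(seq))
  code <- encode_rna(seq_rna)
  V <- cpp_fold_matrix(code, model_for_cpp(model))
  E <- closed_energies(code, V, model)
  if (!any(is.finite(E))) return(list())
  mfe <- min(E)
  if (mfe >= 0) return(list())
  thr <- mfe + abs(mfe) * suboptimality_percent / 100 + 1e-9
  idx <- which(is.finite(E) & E <= thr & E < 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  e <- E[idx]
  ord <- order(e, idx[, 2] - idx[, 1], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  idx <- idx[seq_len(min(nrow(idx), max_count)), , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) {
    build_hairpin(seq_rna, code, V, model, idx[r, 1], idx[r, 2])
  })
}

#' Score a kissing-loop complex between two hairpin loops
#'
#' Finds the longest contiguous antiparallel Watson-Crick duplex (GU
#' optional) between the unpaired nucleotides of two hairpin loops, e.g.
#' 5'-AAUU annealing with 3'-UUAA gives four base pairs.
#'
#' @param loop_a,loop_b Loop nucleotide strings (`T` read as `U`).
#' @param allow_gu Also count GU pairs (default `FALSE`).
#' @return An `la_kissing` with fields `loop_a`, `loop_b`, `n_pairs` and
#'   `paired_offsets` (positions within each loop, or `NULL` if none).
#' @examples
#' kissing_pairs("AAUU", "AAUU")$n_pairs  # 4
#' @export
kissing_pairs <- function(loop_a, loop_b, allow_gu = FALSE) {
  a <- chars(chartr("T", "U", normalize_dna(loop_a)))
  b <- chars(chartr("T", "U", normalize_dna(loop_b)))
  if (length(a) == 0L || length(b) == 0L) stop("loops must be non-empty")
  comp <- function(x, y) {
    wc <- (x == "A" & y == "U") | (x == "U" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G")
    if (allow_gu) wc <- wc | (x == "G" & y == "U") | (x == "U" & y == "G")
    wc
  }
  nb <- length(b)
  best <- 0L
  best_off <- NULL
  # antiparallel duplex: a[i] pairs b[j] along anti-diagonals i + j = s
  for (s in 2L:(length(a) + nb)) {
    i <- max(1L, s - nb):min(length(a), s - 1L)
    j <- s - i
    ok <- comp(a[i], b[j])
    r <- rle(ok)
    if (any(r$values)) {
      len <- max(r$lengths[r$values])
      if (len > best) {
        best <- len
        k <- which(r$values & r$lengths == len)[1]
        start <- if (k == 1L) 1L else sum(r$lengths[1:(k - 1L)]) + 1L
        best_off <- cbind(a_pos = i[start:(start + len - 1L)],
                          b_pos = j[start:(start + len - 1L)])
      }
    }
  }
  structure(list(loop_a = collapse0(a), loop_b = collapse0(b),
                 n_pairs = best, paired_offsets = best_off),
            class = "la_kissing")
}

#' @export
print.la_kissing <- function(x, ...) {
  cat(sprintf("<la_kissing> %s / %s: %d bp\n", x$loop_a, x$loop_b, x$n_pairs))
  invisible(x)
}
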