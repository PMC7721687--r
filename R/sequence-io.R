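## Sequence container and FASTA input ---------------------------------------

#' Construct a viral sequence record
#'
#' A light container for a positive-strand cDNA sequence of a viral dsRNA
#' genome. Residues are normalized to uppercase DNA (`U` is read as `T`);
#' the alphabet is restricted to `A`, `C`, `G`, `T`, `N` and the fraction of
#' `N` must stay below 10%.
#'
#' @param id Accession or label.
#' @param residues Nucleotide string (DNA or RNA letters, any case).
#' @param description Optional free-text description.
#' @return An object of class `la_sequence` with fields `id`, `description`,
#'   `residues` and `length`.
#' @examples
#' viral_sequence("toy", "gaaaaauuuACGT")
#' @export
viral_sequence <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  res <- normalize_dna(residues)
  n <- nchar(res)
  if (n < 1L) stop("sequence '", id, "' is empty")
  bad <- gsub("[ACGTN]", "", res)
  if (nzchar(bad)) {
    stop("sequence '", id, "' contains non-nucleotide characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  n_frac <- lengths(regmatches(res, gregexpr("N", res, fixed = TRUE))) / n
  if (n_frac >= 0.10) {
    stop("sequence '", id, "' has an N fraction of ",
         round(100 * n_frac, 1), "% (must be < 10%)")
  }
  structure(list(id = id, description = description,
                 residues = res, length = n),
            class = "la_sequence")
}

## Uppercase, RNA -> DNA. Used on every sequence entering the package.
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' @export
print.la_sequence <- function(x, ...) {
  cat(sprintf("<la_sequence> %s (%d nt)%s\n", x$id, x$length,
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Read viral sequences from a FASTA file
#'
#' Multi-record FASTA (wrapped or unwrapped) is read with Biostrings;
#' record ids and descriptions are preserved, `U` is normalized to `T` and
#' case is folded to uppercase.
#'
#' @param path Path to a FASTA file.
#' @return A list of [viral_sequence()] records, in file order. An empty
#'   file yields an empty list with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("parse error in '", path, "': ", conditionMessage(e))
                  })
  if (length(set) == 0L) {
    warning("no FASTA records in '", path, "'")
    return(list())
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- viral_sequence(ids[i], as.character(set[[i]]), desc[i])
  }
  out
}

#' Write viral sequences to a FASTA file
#'
#' @param seqs A single `la_sequence` or a list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "la_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    header <- if (nzchar(s$description)) {
      paste(s$id, s$description)
    } else s$id
    writeLines(paste0(">", header), con)
    starts <- seq(1L, s$length, by = width)
    writeLines(substring(s$residues, starts,
                         pmin(starts + width - 1L, s$length)), con)
  }
  invisible(path)
}

## Small shared string helpers ------------------------------------------------

## vector of single characters -> one string and back
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
collapse0 <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA/RNA string
#'
#' @param x Nucleotide string; `U` is treated as `T`.
#' @return The reverse complement as an uppercase DNA string.
#' @export
revcomp <- function(x) {
  x <- normalize_dna(x)
  collapse0(rev(chars(chartr("ACGTN", "TGCAN", x))))
}
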