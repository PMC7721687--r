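## Nearest-neighbor free-energy model (37 degrees C, 1 M NaCl) ---------------

## Pair type encoding shared with the C++ folding engine:
## 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA, 0 unpairable.
PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")
NT4 <- c("A", "C", "G", "U")

#' Load the nearest-neighbor RNA energy model
#'
#' Reads the Turner 2004 free-energy tables (37 degrees C, 1 M NaCl)
#' shipped with the package as plain TSV files: Watson-Crick and GU
#' stacking energies, loop-size-indexed initiation penalties for hairpin,
#' bulge and interior loops (sizes capped at 30), terminal-mismatch tables
#' for hairpin and interior loops, the interior-loop asymmetry (Ninio)
#' parameters, and the terminal AU/GU penalty. All values are in kcal/mol.
#'
#' The special tabulated 1x1, 2x1 and 2x2 interior loops of the full
#' Turner model are scored here by the generic
#' initiation + asymmetry + terminal-mismatch formula; see the package
#' vignette for the accuracy consequences.
#'
#' @param terminal_mismatch Include terminal-mismatch bonuses for hairpin
#'   and interior loops (default `TRUE`).
#' @param dir Directory holding the tables (defaults to the copy installed
#'   with the package).
#' @return An object of class `la_energy_model`.
#' @export
load_energy_model <- function(terminal_mismatch = TRUE, dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "energy", package = "lahelper")
  }
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  stk <- rd("stack.tsv")
  stack <- matrix(Inf, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(match(stk$pair1, PAIR_TYPES),
              match(stk$pair2, PAIR_TYPES))] <- stk$dg
  mm_table <- function(f) {
    d <- rd(f)
    a <- array(0, dim = c(6, 4, 4),
               dimnames = list(PAIR_TYPES, NT4, NT4))
    a[cbind(match(d$pair, PAIR_TYPES), match(d$x, NT4),
            match(d$y, NT4))] <- d$dg
    a
  }
  loop_init <- function(f) {
    d <- rd(f)
    v <- d$dg[match(0:30, d$size)]
    v[is.na(v)] <- Inf
    v
  }
  misc <- rd("misc.tsv")
  mval <- function(k) misc$value[misc$key == k]
  model <- list(
    stack = stack,
    mismatch_hairpin = mm_table("mismatch_hairpin.tsv"),
    mismatch_internal = mm_table("mismatch_internal.tsv"),
    mismatch_internal_1n = mm_table("mismatch_internal_1n.tsv"),
    mismatch_internal_23 = mm_table("mismatch_internal_23.tsv"),
    hairpin_init = loop_init("hairpin_init.tsv"),
    bulge_init = loop_init("bulge_init.tsv"),
    internal_init = loop_init("internal_init.tsv"),
    terminal_au = mval("terminal_au"),
    ninio = mval("ninio"),
    ninio_max = mval("ninio_max"),
    temperature = mval("temperature_C"),
    terminal_mismatch = isTRUE(terminal_mismatch),
    max_loop = 30L)
  stopifnot(all(model$hairpin_init[4:31] >= 0),
            all(diag(model$stack)[c(1, 2)] <= 0))
  structure(model, class = "la_energy_model")
}

## Cached default model (tables are read once per session).
the_model_cache <- new.env(parent = emptyenv())

default_energy_model <- function() {
  if (is.null(the_model_cache$model)) {
    the_model_cache$model <- load_energy_model()
  }
  the_model_cache$model
}

#' @export
print.la_energy_model <- function(x, ...) {
  cat(sprintf(paste0("<la_energy_model> Turner nearest-neighbor set, %g C, ",
                     "terminal mismatches %s\n"), x$temperature,
              if (x$terminal_mismatch) "on" else "off"))
  invisible(x)
}

## Encode an RNA/DNA string as integers 1..4 (A,C,G,U); stops on others.
encode_rna <- function(seq) {
  v <- chars(chartr("T", "U", normalize_dna(seq)))
  code <- match(v, NT4)
  if (anyNA(code)) stop("bad alphabet: sequence contains characters other ",
                        "than A/C/G/T/U")
  as.integer(code)
}

pair_type <- function(a, b) {
  # a, b integer codes 1..4
  key <- a * 10L + b
  match(key, c(23L, 32L, 34L, 43L, 14L, 41L), nomatch = 0L)
}
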