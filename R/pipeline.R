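## Workflow orchestration, report writing, GFF3, accessions ------------------

gff3_row <- function(seqid, type, start, end, attributes,
                     source = "lahelper", score = ".", strand = "+") {
  data.frame(seqid = seqid, source = source, type = type,
             start = as.integer(start), end = as.integer(end),
             score = score, strand = strand, phase = ".",
             attributes = attributes, stringsAsFactors = FALSE)
}

write_gff3 <- function(rows, path) {
  stopifnot(ncol(rows) == 9L, all(rows$start >= 1L), all(rows$end >= rows$start))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param inputs Named character vector of FASTA paths, or a named list of
#'   [viral_sequence()] records.
#' @param anchors Named list per virus of `list(anchor_5=, anchor_3=)`;
#'   a `default` entry applies to viruses without their own entry.
#' @param host_db Optional host FASTA path or record list for
#'   [match_host_sequences()].
#' @param thresholds Named list overriding `min_self_identity`,
#'   `min_shared`, `palindrome_min_arm`, `palindrome_max_loop`,
#'   `palindrome_max_mismatch`, `min_gag_len`.
#' @param outdir Output directory for artifacts.
#' @param seed Integer seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return An `la_config`.
#' @export
la_config <- function(inputs, anchors = list(default = list(
                        anchor_5 = "GAAAAA", anchor_3 = NULL)),
                      host_db = NULL, thresholds = list(),
                      outdir = NULL, seed = 1L) {
  th <- list(min_self_identity = 13L, min_shared = 13L,
             palindrome_min_arm = 8L, palindrome_max_loop = 8L,
             palindrome_max_mismatch = 2L, min_gag_len = 400L)
  th[names(thresholds)] <- thresholds
  structure(list(inputs = inputs, anchors = anchors, host_db = host_db,
                 thresholds = th, outdir = outdir, seed = as.integer(seed)),
            class = "la_config")
}

anchor_for <- function(cfg, id) {
  if (!is.null(cfg$anchors[[id]])) cfg$anchors[[id]] else cfg$anchors$default
}

#' Run the full characterization workflow
#'
#' For every input genome: partition, Gag-Pol annotation, cis-signal
#' discovery, extra-sequence analysis (self-identity, palindromes, host
#' matches when a host database is configured); across the set: shared
#' 5'-extra stretches for all pairs with non-empty extras, a nucleotide
#' identity matrix, and (for three or more genomes) a neighbor-joining
#' phylogram. Per-stage errors are collected and reported together.
#' When `outdir` is set, artifacts are written: per-virus GFF3, match
#' tables as TSV, the matrix as TSV, the tree as Newick and the report as
#' JSON. Re-running with identical inputs yields identical artifacts.
#'
#' @param cfg An [la_config()].
#' @return An `la_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "la_config"))
  seqs <- if (is.character(cfg$inputs)) {
    out <- list()
    for (path in cfg$inputs) out <- c(out, read_fasta(path))
    stats::setNames(out, vapply(out, `[[`, "", "id"))
  } else cfg$inputs
  if (length(seqs) == 0L) stop("parse error: no input sequences")
  th <- cfg$thresholds
  errors <- character(0)
  per_virus <- list()
  for (vs in seqs) {
    rec <- list(id = vs$id)
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        errors <<- c(errors, paste0(vs$id, "/", name, ": ",
                                    conditionMessage(e)))
        NULL
      })
    }
    anc <- anchor_for(cfg, vs$id)
    rec$partition <- stage("partition", partition_genome(
      vs, anchor_5 = anc$anchor_5, anchor_3 = anc$anchor_3))
    if (!is.null(rec$partition)) {
      rec$gagpol <- stage("gagpol", build_gagpol_model(
        rec$partition, min_gag_len = th$min_gag_len))
      if (!is.null(rec$gagpol)) {
        rec$signals <- stage("signals", find_signal_stemloops(
          rec$partition, rec$gagpol))
      }
      has_extra <- rec$partition$five_extra_len > 0L ||
        rec$partition$three_extra_len > 0L
      if (has_extra) {
        rec$self_identity <- stage("self_identity", find_self_identity(
          rec$partition, min_len = th$min_self_identity))
        if (!is.null(cfg$host_db)) {
          rec$host_hits <- stage("host", match_host_sequences(
            rec$partition, "FIVE_EXTRA", cfg$host_db))
        }
      }
      rec$palindromes <- stage("palindromes", {
        n_keep <- min(vs$length, rec$partition$five_extra_len + 80L)
        palindrome_scan(substr(vs$residues, 1, n_keep),
                        min_arm = th$palindrome_min_arm,
                        max_loop = th$palindrome_max_loop,
                        max_mismatch = th$palindrome_max_mismatch)
      })
    }
    per_virus[[vs$id]] <- rec
  }
  shared <- list()
  ids <- names(per_virus)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        pa <- per_virus[[i]]$partition
        pb <- per_virus[[j]]$partition
        if (!is.null(pa) && !is.null(pb) &&
              pa$five_extra_len > 0L && pb$five_extra_len > 0L) {
          sh <- tryCatch(find_shared_stretches(pa, pb,
                                               min_len = th$min_shared),
                         error = function(e) NULL)
          if (!is.null(sh) && nrow(sh) > 0L) {
            shared[[paste(ids[i], ids[j], sep = "|")]] <- sh
          }
        }
      }
    }
  }
  matrix_nt <- NULL
  phylo <- NULL
  if (length(seqs) >= 2L) {
    matrix_nt <- tryCatch(identity_matrix(
      vapply(seqs, `[[`, "", "residues"), kind = "NT"),
      error = function(e) {
        errors <<- c(errors, paste0("identity_matrix: ",
                                    conditionMessage(e)))
        NULL
      })
    if (!is.null(matrix_nt) && length(seqs) >= 3L) {
      phylo <- nj_phylogram(matrix_nt)
    }
  }
  report <- structure(list(
    per_virus = per_virus, shared_stretches = shared,
    identity_matrix = matrix_nt, phylogram = phylo,
    errors = errors,
    provenance = list(package_version =
                        as.character(utils::packageVersion("lahelper")),
                      thresholds = th, seed = cfg$seed)),
    class = "la_report")
  if (!is.null(cfg$outdir)) write_report_artifacts(report, cfg$outdir)
  if (length(errors) > 0L) {
    stop("pipeline stage errors:\n  ", paste(errors, collapse = "\n  "))
  }
  report
}

#' @export
print.la_report <- function(x, ...) {
  cat(sprintf("<la_report> %d genome(s), %d shared-stretch pair(s), %d error(s)\n",
              length(x$per_virus), length(x$shared_stretches),
              length(x$errors)))
  invisible(x)
}

write_report_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(report$per_virus)) {
    rec <- report$per_virus[[id]]
    if (is.null(rec$partition)) next
    safe <- gsub("[^A-Za-z0-9._-]", "_", id)
    partition_gff3(rec$partition, file.path(outdir, paste0(safe, ".regions.gff3")))
    if (!is.null(rec$gagpol)) {
      gagpol_gff3(rec$partition, rec$gagpol,
                  file.path(outdir, paste0(safe, ".gagpol.gff3")))
    }
    if (!is.null(rec$signals) && length(rec$signals) > 0L) {
      signals_gff3(rec$partition, rec$signals,
                   file.path(outdir, paste0(safe, ".signals.gff3")))
    }
    if (!is.null(rec$self_identity) && nrow(rec$self_identity) > 0L) {
      write.table(rec$self_identity,
                  file.path(outdir, paste0(safe, ".self_identity.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(report$identity_matrix)) {
    identity_matrix_tsv(report$identity_matrix,
                        file.path(outdir, "identity_matrix.tsv"))
  }
  if (!is.null(report$phylogram)) {
    writeLines(report$phylogram$newick, file.path(outdir, "phylogram.nwk"))
  }
  jsonlite::write_json(report_summary(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

report_summary <- function(report) {
  pv <- lapply(report$per_virus, function(rec) {
    out <- list(id = rec$id)
    if (!is.null(rec$partition)) {
      out$partition <- partition_report(rec$partition)
    }
    if (!is.null(rec$gagpol)) {
      gp <- rec$gagpol
      out$gagpol <- list(gag = c(gp$gag$start, gp$gag$end),
                         pol = c(gp$pol$start, gp$pol$end),
                         slippery = gp$slippery$position,
                         heptamer = gp$slippery$heptamer,
                         fusion_len = nchar(gp$fusion_protein),
                         reinit = gp$reinit_codons)
    }
    if (!is.null(rec$signals)) {
      out$signals <- lapply(rec$signals, function(s) {
        list(kind = s$kind, location = s$location,
             dG_kJ = if (!is.null(s$hairpin)) round(s$hairpin$dG_kJ, 1)
                     else NULL)
      })
    }
    if (!is.null(rec$self_identity)) {
      out$self_identity <- rec$self_identity
    }
    out
  })
  list(per_virus = pv, errors = report$errors,
       provenance = report$provenance)
}

## GenBank accession support --------------------------------------------------

#' Directory holding user-fetched GenBank accession FASTA files
#'
#' Comparisons against published LA genomes need their GenBank records,
#' which this package never downloads implicitly. Fetch them once with
#' [fetch_accessions()] (requires network access) into this directory;
#' analyses and tests that depend on them pick the files up from here.
#' Defaults to `tools::R_user_dir("lahelper", "data")` and can be
#' overridden with `options(lahelper.accession_dir = ...)`.
#'
#' @return A directory path (not necessarily existing).
#' @export
accession_dir <- function() {
  getOption("lahelper.accession_dir",
            tools::R_user_dir("lahelper", which = "data"))
}

#' Fetch GenBank nucleotide records as FASTA (requires network access)
#'
#' @param accessions Character vector of accession numbers.
#' @param dir Destination directory (default [accession_dir()]).
#' @return Paths of the downloaded files, invisibly.
#' @export
fetch_accessions <- function(accessions, dir = accession_dir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                 "efetch.fcgi?db=nuccore&rettype=fasta&retmode=text&id=")
  paths <- character(0)
  for (acc in accessions) {
    dest <- file.path(dir, paste0(acc, ".fasta"))
    if (!file.exists(dest)) {
      utils::download.file(paste0(base, acc), dest, quiet = TRUE)
    }
    paths <- c(paths, dest)
  }
  invisible(paths)
}

#' Load a fetched accession, if available
#'
#' @param accession Accession number.
#' @param dir Directory searched (default [accession_dir()]).
#' @return A [viral_sequence()], or `NULL` when the record has not been
#'   fetched.
#' @export
load_accession <- function(accession, dir = accession_dir()) {
  path <- file.path(dir, paste0(accession, ".fasta"))
  if (!file.exists(path)) return(NULL)
  recs <- read_fasta(path)
  if (length(recs) == 0L) return(NULL)
  recs[[1]]
}
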