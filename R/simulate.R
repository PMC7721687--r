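## LA-like genome simulator with planted ground truth ------------------------
##
## The generator emits a genome whose annotation at zero divergence equals
## the planted truth exactly. Designed blocks (motif, AU-rich window,
## slippery heptamer, the three stem loops, self-identity copies, the
## near-palindrome, anchors) are written over a random background, and a
## deterministic repair pass removes any stop codon or start codon that the
## random background would otherwise introduce in the two translated frames
## (Gag frame 0; the -1 Pol frame from the frameshift point to the Pol
## stop). Stem loops are built from GC-only arms so their recovery under
## the default energy model is unambiguous, and -- stop codons requiring a
## T -- they can never truncate a reading frame.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Parameters for the synthetic LA genome generator
#'
#' Presets mirror the genome geometries reported for sequenced LA viruses:
#' `"LAbarr1"` (5'-extra 14 / canonical 4591 / 3'-extra 17, homologous 5'
#' motif `AATTAA`, full feature planting including the boundary-spanning
#' 51-nt self-identity copy, the near-palindrome and the 3' self-identity
#' copy) and `"LAlus4-EX229"` (187 / 4580 / 9, `GAAAAA` motif, a planted
#' 178-nt host rRNA-like fragment in the 5'-extra instead of
#' self-identity).
#'
#' @param preset `"LAbarr1"` (default) or `"LAlus4-EX229"`.
#' @param ... Named overrides of individual fields.
#' @return A list of generator parameters (class `la_genome_params`).
#' @export
la_genome_params <- function(preset = c("LAbarr1", "LAlus4-EX229"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    "LAbarr1" = list(
      five_extra_len = 14L, canonical_len = 4591L, three_extra_len = 17L,
      motif5 = "AATTAA", tail3 = "CCATAAGC",
      gag_start = 61L, gag_aa = 677L, pol_start = 2376L,
      plant_self5 = TRUE, plant_self3 = TRUE, plant_palindrome = TRUE,
      host_len = 0L),
    "LAlus4-EX229" = list(
      five_extra_len = 187L, canonical_len = 4580L, three_extra_len = 9L,
      motif5 = "GAAAAA", tail3 = "CCATATGC",
      gag_start = 61L, gag_aa = 677L, pol_start = 2376L,
      plant_self5 = FALSE, plant_self3 = FALSE, plant_palindrome = FALSE,
      host_len = 178L))
  p$preset <- preset
  ov <- list(...)
  p[names(ov)] <- ov
  structure(p, class = "la_genome_params")
}

## Designed blocks shared by all genomes (GC-only stems fold unambiguously
## and cannot harbour stop codons).
PAL_ARM <- "GCGGCGCC"                      # 5' palindrome / kissing stem arm
FS_SL <- "GCCGCGGACAACCGCGGC"              # frameshift stem loop (18 nt)
PACK_ARM <- "GGCGGCCG"                     # packaging stem arm (8 bp)
PACK_LOOP <- "ACAACACA"                    # packaging loop (conserved)
REP_SL <- "GGCGCAAACAGCGCC"                # replication stem loop (15 nt)
T3_BLOCK <- "AGGCGGCACAAGCCGCC"            # 3'-extra: A + 16-nt hairpin

#' Generate a synthetic LA-like genome with planted ground truth
#'
#' Deterministic per seed. The emitted genome carries: the 5' conserved
#' motif at canonical position 1; an all-AU 15-nt window at canonical
#' 21-35; a Gag ORF from canonical 61; a codon-aligned `GGGTTTA` slippery
#' heptamer near the Gag stop with a GC-stem hairpin 2 nt downstream; a
#' stop-free -1 frame from the frameshift point to the Pol stop (so the
#' Gag-Pol fusion protein is well defined); a Pol ORF whose ATG is the
#' first in-frame start after a planted upstream in-frame stop; a 24-nt
#' packaging stem loop inside Pol; a 15-nt replication stem loop in the
#' last 40 canonical nucleotides; and, depending on the preset, a 5'
#' boundary-spanning self-identity copy, a 3' self-identity copy, a
#' near-palindrome around the motif, and a host rRNA-like fragment in the
#' 5'-extra zone.
#'
#' @param params An [la_genome_params()].
#' @param seed Integer seed.
#' @return A list with `sequence` (an [viral_sequence()]), `truth` (class
#'   `la_truth`, all planted coordinates) and `host_db` (the synthetic
#'   host records used for host planting, if any).
#' @export
simulate_genome <- function(params = la_genome_params(), seed = 1L) {
  stopifnot(inherits(params, "la_genome_params"))
  with_seed(seed, {
    for (attempt in 1:50) {
      g <- try(build_genome_attempt(params, seed), silent = TRUE)
      if (!inherits(g, "try-error") && validate_genome(g)) return(g)
    }
    stop("layout infeasible: could not satisfy genome constraints for the ",
         "given parameters")
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

build_genome_attempt <- function(pr, seed) {
  can_len <- pr$canonical_len
  gag_start <- pr$gag_start
  gag_end <- gag_start + 3L * pr$gag_aa - 1L
  slip_pos <- gag_start + 3L * (pr$gag_aa - 36L)       # codon-aligned
  h7 <- slip_pos + 6L
  q <- slip_pos + 5L                                    # -1 resume point
  fs2 <- slip_pos - 10L                                 # planted -1 stop
  fs_sl_start <- h7 + 3L
  pol_start <- pr$pol_start
  pol_aa <- (can_len - 35L - pol_start + 1L) %/% 3L
  pol_end <- pol_start + 3L * pol_aa - 1L
  pack_start <- can_len - 386L
  rep_start <- can_len - 24L
  tail_start <- can_len - nchar(pr$tail3) + 1L
  if (gag_end + 3L >= pol_start || pol_start - q < 60L ||
        pack_start <= pol_start + 30L || pack_start + 23L >= pol_end - 30L ||
        rep_start <= pol_end + 3L || can_len < 3000L) {
    stop("layout infeasible: canonical zone too short for the ORF footprint")
  }

  s <- character(can_len)
  protect <- NULL
  mark <- function(a, b) protect <<- rbind(protect, c(a, b))

  ## 5' UTR
  s[1:6] <- chars(substr(paste0(pr$motif5, "AAAAA"), 1, 6))
  mark(1L, 6L)
  if (pr$plant_palindrome) {
    s[7:14] <- chars(revcomp(PAL_ARM))
    mark(7L, 14L)
  } else s[7:14] <- rand_bases(8)
  s[15:20] <- chars("CACCAG")
  # all-AU window free of TAA at the codon offsets of its planted copy
  repeat {
    win <- sample(c("A", "T"), 15, replace = TRUE)
    tri <- sapply(c(1, 4, 7, 10, 13), function(i)
      collapse0(win[i:(i + 2)]))
    if (!any(tri %in% STOP_CODONS) && sum(win == "T") >= 4) break
  }
  s[21:35] <- win
  mark(21L, 35L)
  s[36:38] <- c("C", "A", "A")
  s[39:60] <- rand_bases(22)

  ## Gag codons, then planted blocks
  gag_cod <- sample(NONSTOP_CODONS, pr$gag_aa - 1L, replace = TRUE)
  s[gag_start:(gag_start + 2L)] <- c("A", "T", "G")
  s[(gag_start + 3L):gag_end] <- unlist(strsplit(gag_cod, ""))
  s[(gag_end + 1L):(gag_end + 3L)] <- c("T", "A", "A")
  mark(gag_start, gag_start + 2L)
  mark(gag_end + 1L, gag_end + 3L)
  s[fs2:(fs2 + 2L)] <- c("T", "A", "A")        # -1 frame stop before slip
  mark(fs2, fs2 + 2L)
  s[slip_pos:(slip_pos + 6L)] <- chars("GGGTTTA")
  s[(slip_pos + 7L):(slip_pos + 8L)] <- c("C", "A")
  mark(slip_pos, slip_pos + 8L)
  s[fs_sl_start:(fs_sl_start + 17L)] <- chars(FS_SL)
  mark(fs_sl_start, fs_sl_start + 17L)
  # pairing-inert guard (A/C cannot pair with A/C) so the planted hairpin
  # is recovered at exactly its designed span
  s[(fs_sl_start + 18L):(fs_sl_start + 47L)] <- rep(c("A", "C", "C"), 10L)
  mark(fs_sl_start + 18L, fs_sl_start + 47L)

  ## spacer between Gag stop and Pol start (-1 frame codons, stop/ATG free)
  spacer_cod <- sample(setdiff(NONSTOP_CODONS, "ATG"),
                       (pol_start - gag_end - 6L) %/% 3L, replace = TRUE)
  s[(gag_end + 4L):(gag_end + 5L)] <- c("C", "A")
  s[(gag_end + 6L):(pol_start - 1L)] <- unlist(strsplit(spacer_cod, ""))

  ## Pol codons (the -1 frame is codon-aligned with pol_start)
  pol_cod <- sample(NONSTOP_CODONS, pol_aa - 1L, replace = TRUE)
  s[pol_start:(pol_start + 2L)] <- c("A", "T", "G")
  s[(pol_start + 3L):pol_end] <- unlist(strsplit(pol_cod, ""))
  s[(pol_end + 1L):(pol_end + 3L)] <- c("T", "A", "A")
  mark(pol_start, pol_start + 2L)
  mark(pol_end + 1L, pol_end + 3L)

  ## packaging stem loop inside Pol
  pack <- paste0(PACK_ARM, PACK_LOOP, revcomp(PACK_ARM))
  s[pack_start:(pack_start + 23L)] <- chars(pack)
  mark(pack_start, pack_start + 23L)

  ## 3' region: filler, replication stem loop, canonical tail anchor
  s[(pol_end + 4L):(can_len)] <- rand_bases(can_len - pol_end - 3L)
  # all-A guard ahead of the replication stem loop (see above); the Pol
  # stop codon inside it is re-planted
  s[(rep_start - 15L):(rep_start - 1L)] <- "A"
  s[(pol_end + 1L):(pol_end + 3L)] <- c("T", "A", "A")
  mark(rep_start - 15L, rep_start - 1L)
  s[rep_start:(rep_start + 14L)] <- chars(REP_SL)
  mark(rep_start, rep_start + 14L)
  if (tail_start > rep_start + 15L) {
    s[(rep_start + 15L):(tail_start - 1L)] <- "A"
    mark(rep_start + 15L, tail_start - 1L)
  }
  s[tail_start:can_len] <- chars(pr$tail3)
  mark(tail_start, can_len)

  ## extra zones
  host_db <- synthetic_host_db(seed = 1000L + seed)
  host <- NULL
  if (pr$five_extra_len == 14L && pr$plant_self5) {
    extra5 <- chars(paste0("CCACAC", PAL_ARM))
  } else {
    extra5 <- rand_bases(pr$five_extra_len)
    if (pr$host_len > 0L) {
      if (pr$five_extra_len < pr$host_len) {
        stop("layout infeasible: 5'-extra too short for the host fragment")
      }
      # fragment taken from the host 3' terminus and planted at the extra
      # zone 5' terminus: neither flank can extend a local alignment, so
      # the planted hit is recovered at exactly its designed span
      hlen <- host_db[[1]]$length
      frag <- substr(host_db[[1]]$residues, hlen - pr$host_len + 1L, hlen)
      extra5[1:pr$host_len] <- chars(frag)
      host <- list(host_id = host_db[[1]]$id,
                   extra_span = c(1L, pr$host_len),
                   host_span = c(hlen - pr$host_len + 1L, hlen),
                   length = pr$host_len)
    }
  }
  extra3 <- if (pr$plant_self3) chars(T3_BLOCK) else
    c("A", rand_bases(pr$three_extra_len - 1L))
  if (length(extra3) != pr$three_extra_len) {
    stop("layout infeasible: 3'-extra length incompatible with planting")
  }

  ## self-identity copies
  self5 <- self3 <- NULL
  dup_s <- 402L
  if (pr$plant_self5) {
    dup <- c(extra5, s[1:37])                 # spans the zone boundary
    s[dup_s:(dup_s + length(dup) - 1L)] <- dup
    mark(dup_s, dup_s + length(dup) - 1L)
    s[dup_s + length(dup)] <- "G"             # right-flank mismatch (vs s[38])
    self5 <- list(q_span_abs = c(1L, pr$five_extra_len + 37L),
                  s_span_can = c(dup_s, dup_s + length(dup) - 1L),
                  length = length(dup))
  }
  if (pr$plant_self3) {
    t3s <- can_len - 134L
    src <- extra3[2:17]
    s[t3s:(t3s + 15L)] <- src
    mark(t3s, t3s + 15L)
    s[t3s - 1L] <- "C"                        # left-flank mismatch (vs 'A')
    mark(t3s - 1L, t3s - 1L)
    self3 <- list(
      q_span_abs = pr$five_extra_len + can_len + c(2L, 17L),
      s_span_can = c(t3s, t3s + 15L),
      length = 16L)
  }

  protected <- protect
  repair_frames(s, protected, gag_start, gag_end, q, pol_end, fs2,
                pol_start) -> s

  full <- c(extra5, s, extra3)
  vs <- viral_sequence(sprintf("synthetic_%s_seed%d", pr$preset, seed),
                       collapse0(full),
                       description = "synthetic LA-like genome")
  off <- pr$five_extra_len
  truth <- structure(list(
    seed = seed, params = pr,
    five_extra_len = pr$five_extra_len, canonical_len = can_len,
    three_extra_len = pr$three_extra_len,
    motif5 = substr(pr$motif5, 1, 6), tail3 = pr$tail3,
    gag = c(start = gag_start, end = gag_end),
    gag_protein = translate(substr(collapse0(s), gag_start, gag_end), 0L),
    slippery_pos = slip_pos, heptamer = "GGGTTTA",
    pol = c(start = pol_start, end = pol_end),
    pol_protein = translate(substr(collapse0(s), pol_start, pol_end), 0L),
    fusion_protein = paste0(
      translate(substr(collapse0(s), gag_start, q), 0L),
      translate(substr(collapse0(s), q, pol_end), 0L)),
    reinit = integer(0),
    signals = list(
      five_prime_motif = c(1L, 6L),
      au_rich = c(21L, 35L), au_fraction = 1.0,
      frameshift_sl = c(fs_sl_start, fs_sl_start + 17L),
      packaging_sl = c(pack_start, pack_start + 23L),
      packaging_loop = PACK_LOOP,
      replication_sl = c(rep_start, rep_start + 14L)),
    self_identity5 = self5, self_identity3 = self3,
    palindrome = if (pr$plant_palindrome)
      list(start_abs = 7L, end_abs = 28L, arm_len = 8L, loop_len = 6L)
      else NULL,
    host = host,
    protected_abs = cbind(protected[, 1] + off, protected[, 2] + off)),
    class = "la_truth")
  if (pr$five_extra_len > 0L) {
    truth$protected_abs <- rbind(truth$protected_abs, c(1L, off))
  }
  if (pr$three_extra_len > 0L) {
    truth$protected_abs <- rbind(truth$protected_abs,
                                 c(off + can_len + 1L, off + can_len +
                                     pr$three_extra_len))
  }
  list(sequence = vs, truth = truth, host_db = host_db)
}

## Remove stop codons (and unwanted in-frame ATGs) introduced by the random
## background: mutate one unprotected base of each offending codon to C
## (no stop or ATG contains a C, so the pass terminates).
repair_frames <- function(s, protected, gag_start, gag_end, q, pol_end,
                          fs2, pol_start) {
  is_prot <- rep(FALSE, length(s))
  for (r in seq_len(nrow(protected))) {
    is_prot[protected[r, 1]:protected[r, 2]] <- TRUE
  }
  fix_codon <- function(p) {
    free <- p + which(!is_prot[p:(p + 2L)]) - 1L
    if (length(free) == 0L) stop("layout infeasible: constrained codon is ",
                                 "fully protected at ", p)
    s[free[length(free)]] <<- "C"
  }
  for (pass in 1:25) {
    changed <- FALSE
    # frame 0 stops inside Gag
    for (p in seq(gag_start, gag_end - 2L, by = 3L)) {
      if (collapse0(s[p:(p + 2L)]) %in% STOP_CODONS) {
        fix_codon(p); changed <- TRUE
      }
    }
    # -1 frame: no stops from the resume point to the Pol stop
    for (p in seq(q, pol_end - 2L, by = 3L)) {
      if (collapse0(s[p:(p + 2L)]) %in% STOP_CODONS) {
        fix_codon(p); changed <- TRUE
      }
    }
    # -1 frame: no ATG between the planted upstream stop and the Pol start
    for (p in seq(fs2 + 3L, pol_start - 3L, by = 3L)) {
      if (collapse0(s[p:(p + 2L)]) == "ATG") {
        fix_codon(p); changed <- TRUE
      }
    }
    # no frame-0 ATG in the 5' UTR (would move the Gag start)
    for (p in seq(1L, gag_start - 3L, by = 3L)) {
      if (collapse0(s[p:(p + 2L)]) == "ATG") {
        fix_codon(p); changed <- TRUE
      }
    }
    if (!changed) break
  }
  s
}

## Annotation round trip: the attempt is accepted only if the pipeline
## reproduces every planted feature exactly.
validate_genome <- function(g) {
  tr <- g$truth
  ok <- try({
    p <- partition_genome(g$sequence, anchor_5 = tr$motif5,
                          anchor_3 = tr$tail3)
    stopifnot(p$five_extra_len == tr$five_extra_len,
              p$canonical_len == tr$canonical_len,
              p$three_extra_len == tr$three_extra_len)
    gp <- build_gagpol_model(p)
    stopifnot(gp$gag$start == tr$gag["start"], gp$gag$end == tr$gag["end"],
              gp$slippery$position == tr$slippery_pos,
              gp$pol$start == tr$pol["start"], gp$pol$end == tr$pol["end"],
              identical(gp$fusion_protein, tr$fusion_protein),
              identical(gp$reinit_codons, tr$reinit))
    sg <- find_signal_stemloops(p, gp,
                                ref_packaging_loop = tr$signals$packaging_loop)
    off <- tr$five_extra_len
    stopifnot(
      identical(sg$FIVE_PRIME_MOTIF$abs_span,
                off + tr$signals$five_prime_motif),
      identical(sg$AU_RICH$abs_span, off + tr$signals$au_rich),
      abs(sg$AU_RICH$au_fraction - tr$signals$au_fraction) < 1e-9,
      identical(sg$FRAMESHIFT_SL$abs_span, off + tr$signals$frameshift_sl),
      identical(sg$PACKAGING_SL$abs_span, off + tr$signals$packaging_sl),
      identical(sg$REPLICATION_SL$abs_span, off + tr$signals$replication_sl))
    if (!is.null(tr$self_identity5)) {
      si <- find_self_identity(p)
      stopifnot(nrow(si) >= 1L,
                si$q_start[1] == tr$self_identity5$q_span_abs[1],
                si$q_end[1] == tr$self_identity5$q_span_abs[2],
                si$s_start[1] == tr$self_identity5$s_span_can[1] + off,
                si$s_end[1] == tr$self_identity5$s_span_can[2] + off)
    }
    TRUE
  }, silent = TRUE)
  isTRUE(ok)
}

#' Synthetic host sequence database
#'
#' Random labelled records emulating the kinds of host sequences found in
#' LA extra zones (small-subunit rRNA-like, large-subunit rRNA-like, and a
#' chromosome fragment). Purely synthetic stand-ins generated per seed;
#' they carry no real rRNA sequence.
#'
#' @param seed Integer seed.
#' @return A list of [viral_sequence()] records.
#' @export
synthetic_host_db <- function(seed = 42L) {
  with_seed(seed, {
    mk <- function(id, n, desc) viral_sequence(id, collapse0(rand_bases(n)),
                                               desc)
    list(mk("18S_rRNA_synthetic", 1800L, "synthetic SSU rRNA-like record"),
         mk("26S_rRNA_synthetic", 3392L, "synthetic LSU rRNA-like record"),
         mk("chrII_synthetic", 2000L, "synthetic chromosome fragment"))
  })
}

## Family evolution -----------------------------------------------------------

#' Specification of a simulated virus family
#'
#' @param tree A Newick string or `ape::phylo`; branch lengths are
#'   expected substitutions per (unprotected) site.
#' @param indel_rate Expected indels per site per branch (default 0).
#'   Indels are restricted to non-coding, unprotected canonical positions
#'   so that reading frames and planted features stay annotatable.
#' @param protect Avoid substitutions inside planted feature intervals
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @return An `la_family_spec`.
#' @export
la_family_spec <- function(tree, indel_rate = 0, protect = TRUE, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3L,
            all(tree$edge.length >= 0), indel_rate >= 0)
  structure(list(tree = tree, indel_rate = indel_rate,
                 protect = isTRUE(protect), seed = as.integer(seed)),
            class = "la_family_spec")
}

#' Evolve a simulated genome along a guide tree
#'
#' Jukes-Cantor substitutions: on each branch the substitution count is
#' Poisson with mean branch length times the number of mutable sites, each
#' substitution replacing a uniformly chosen mutable site with a uniform
#' different base. With `protect = TRUE` planted feature intervals are
#' never touched. Optional indels (geometric lengths, at most 10 nt) are
#' confined to unprotected non-coding canonical sequence; leaf truths
#' carry coordinates shifted accordingly.
#'
#' @param genome Result of [simulate_genome()] (or its `sequence`).
#' @param truth The matching `la_truth` (taken from `genome` if omitted).
#' @param spec An [la_family_spec()].
#' @return A list with `genomes` (named list of [viral_sequence()]),
#'   `truths` (per-leaf), `tree` (the guide tree), and
#'   `realized_substitutions` (per-edge counts, for calibration checks).
#' @export
evolve_family <- function(genome, truth = NULL, spec) {
  if (is.list(genome) && !inherits(genome, "la_sequence")) {
    if (is.null(truth)) truth <- genome$truth
    genome <- genome$sequence
  }
  stopifnot(inherits(genome, "la_sequence"), inherits(truth, "la_truth"),
            inherits(spec, "la_family_spec"))
  tree <- ape::reorder.phylo(spec$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  with_seed(spec$seed, {
    seqs <- list()
    truths <- list()
    node_seq <- list()
    node_truth <- list()
    node_seq[[root]] <- chars(genome$residues)
    node_truth[[root]] <- truth
    realized <- numeric(nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      res <- mutate_branch(node_seq[[par]], node_truth[[par]],
                           tree$edge.length[e], spec)
      node_seq[[child]] <- res$seq
      node_truth[[child]] <- res$truth
      realized[e] <- res$n_sub
      if (child <= n_tip) {
        lab <- tree$tip.label[child]
        vs <- viral_sequence(lab, collapse0(res$seq),
                             description = paste("descendant of",
                                                 genome$id))
        seqs[[lab]] <- vs
        truths[[lab]] <- res$truth
      }
    }
    list(genomes = seqs, truths = truths, tree = tree,
         realized_substitutions = realized)
  })
}

mutate_branch <- function(s, truth, bl, spec) {
  n <- length(s)
  prot <- rep(FALSE, n)
  if (spec$protect) {
    pm <- truth$protected_abs
    for (r in seq_len(nrow(pm))) {
      lo <- max(1L, pm[r, 1]); hi <- min(n, pm[r, 2])
      if (lo <= hi) prot[lo:hi] <- TRUE
    }
  }
  mutable <- which(!prot)
  n_sub <- 0L
  if (bl > 0 && length(mutable) > 0L) {
    target <- min(rpois(1L, bl * length(mutable)), length(mutable))
    sites <- sample(mutable, length(mutable))
    i <- 1L
    while (n_sub < target && i <= length(sites)) {
      p <- sites[i]
      i <- i + 1L
      for (base in sample(setdiff(c("A", "C", "G", "T"), s[p]))) {
        if (substitution_ok(s, p, base, truth)) {
          s[p] <- base
          n_sub <- n_sub + 1L
          break
        }
      }
    }
  }
  if (spec$indel_rate > 0) {
    k <- rpois(1L, spec$indel_rate * n)
    for (i in seq_len(k)) {
      res <- apply_indel(s, truth, prot)
      s <- res$seq; truth <- res$truth; prot <- res$prot
    }
  }
  list(seq = s, truth = truth, n_sub = n_sub)
}

## Purifying-selection-like constraint on simulated substitutions: a
## substitution is rejected if it would make the genome un-annotatable --
## a premature stop in the Gag frame or in the -1 frame of the fusion
## protein, a spurious in-frame start codon that would move the Gag or Pol
## start, or a new slippery heptamer between the planted one and the Gag
## stop (which would change the annotated frameshift site).
substitution_ok <- function(s, p, base, truth) {
  off <- truth$five_extra_len
  old <- s[p]
  s[p] <- base
  gag_s <- off + truth$gag["start"]
  gag_e <- off + truth$gag["end"]
  pol_s <- off + truth$pol["start"]
  pol_e <- off + truth$pol["end"]
  slip <- off + truth$slippery_pos
  q_abs <- slip + 5L
  fs2 <- slip - 10L
  codon_at <- function(origin, pos) {
    cs <- origin + 3L * ((pos - origin) %/% 3L)
    collapse0(s[cs:(cs + 2L)])
  }
  ok <- TRUE
  if (p >= gag_s && p <= gag_e) {
    if (codon_at(gag_s, p) %in% STOP_CODONS) ok <- FALSE
  }
  if (ok && p >= q_abs && p <= pol_e + 3L) {
    cs <- q_abs + 3L * ((p - q_abs) %/% 3L)
    cod <- collapse0(s[cs:(cs + 2L)])
    if (cs <= pol_e - 2L && cod %in% STOP_CODONS) ok <- FALSE
    if (ok && cod == "ATG" && cs > fs2 && cs < pol_s) ok <- FALSE
  }
  if (ok && p > fs2 && p < pol_s && p < q_abs) {
    cs <- fs2 + 3L * ((p - fs2) %/% 3L)
    if (collapse0(s[cs:(cs + 2L)]) == "ATG") ok <- FALSE
  }
  if (ok && p < gag_s) {
    utr0 <- off + 1L
    cs <- utr0 + 3L * ((p - utr0) %/% 3L)
    if (cs + 2L < gag_s && collapse0(s[cs:(cs + 2L)]) == "ATG") ok <- FALSE
  }
  if (ok && p > slip && p <= gag_e + 3L) {
    h_lo <- max(slip + 1L, p - 6L)
    h_hi <- min(p, gag_e + 3L - 6L)
    for (h in if (h_lo <= h_hi) h_lo:h_hi else integer(0)) {
      v <- s[h:(h + 6L)]
      if (v[1] == v[2] && v[2] == v[3] && v[4] == v[5] && v[5] == v[6] &&
            v[4] %in% c("A", "T") && v[7] != "G") {
        ok <- FALSE
        break
      }
    }
  }
  s[p] <- old
  ok
}

## Indels are confined to unprotected, non-coding canonical positions: the
## 5' UTR filler and the stretch between the Pol stop and the replication
## stem loop. Coordinates at or after the indel shift by the indel length.
apply_indel <- function(s, truth, prot) {
  off <- truth$five_extra_len
  utr <- (off + 39L):(off + truth$gag["start"] - 3L)
  tail_reg <- (off + truth$pol["end"] + 4L):
    (off + truth$signals$replication_sl[1] - 2L)
  cand <- c(utr, tail_reg)
  cand <- cand[cand >= 1 & cand <= length(s) & !prot[cand]]
  if (length(cand) == 0L) return(list(seq = s, truth = truth, prot = prot))
  pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
  len <- min(1L + rgeom(1L, 0.5), 10L)
  ins <- runif(1) < 0.5
  if (!ins) {
    end <- pos + len - 1L
    if (end > length(s) || any(prot[pos:end])) {
      return(list(seq = s, truth = truth, prot = prot))
    }
    s <- s[-(pos:end)]
    prot <- prot[-(pos:end)]
    delta <- -len
  } else {
    s <- append(s, rand_bases(len), after = pos)
    prot <- append(prot, rep(FALSE, len), after = pos)
    delta <- len
  }
  list(seq = s, truth = shift_truth(truth, pos, delta), prot = prot)
}

## Shift all truth coordinates strictly after an indel at absolute `pos`.
shift_truth <- function(truth, pos, delta) {
  off <- truth$five_extra_len
  sh_abs <- function(v) ifelse(v > pos, v + delta, v)
  sh_can <- function(v) ifelse(v + off > pos, v + delta, v)
  truth$canonical_len <- truth$canonical_len + delta
  truth$gag <- sh_can(truth$gag)
  truth$pol <- sh_can(truth$pol)
  truth$slippery_pos <- sh_can(truth$slippery_pos)
  for (nm in c("five_prime_motif", "au_rich", "frameshift_sl",
               "packaging_sl", "replication_sl")) {
    truth$signals[[nm]] <- sh_can(truth$signals[[nm]])
  }
  if (!is.null(truth$self_identity5)) {
    truth$self_identity5$q_span_abs <- sh_abs(truth$self_identity5$q_span_abs)
    truth$self_identity5$s_span_can <- sh_can(truth$self_identity5$s_span_can)
  }
  if (!is.null(truth$self_identity3)) {
    truth$self_identity3$q_span_abs <- sh_abs(truth$self_identity3$q_span_abs)
    truth$self_identity3$s_span_can <- sh_can(truth$self_identity3$s_span_can)
  }
  truth$protected_abs <- cbind(sh_abs(truth$protected_abs[, 1]),
                               sh_abs(truth$protected_abs[, 2]))
  truth
}

#' Default two-cluster guide tree
#'
#' An 8-leaf tree with two clades, emulating the identity strata seen in
#' LA virus families: tight within-cluster identity and a deeper split
#' between clusters.
#'
#' @param within Within-cluster branch length (default 0.002).
#' @param between Stem branch length per cluster (default 0.06).
#' @return A Newick string.
#' @export
two_cluster_tree <- function(within = 0.002, between = 0.06) {
  w <- format(within, scientific = FALSE)
  b <- format(between, scientific = FALSE)
  sprintf(paste0("(((A1:%s,A2:%s):%s,(A3:%s,A4:%s):%s):%s,",
                 "((B1:%s,B2:%s):%s,(B3:%s,B4:%s):%s):%s);"),
          w, w, w, w, w, w, b, w, w, w, w, w, w, b)
}
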