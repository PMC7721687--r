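test_that("translation follows the standard code, frame offsets and stops", {
  expect_equal(translate("ATGGCT", 0), "MA")
  expect_equal(translate("TTTAA", 1), "L")
  expect_equal(translate("TAATAA", 0), "**")
  expect_equal(translate("ATGNNN", 0), "MX")
  expect_equal(translate("AUGGCU", 0), "MA")  # RNA input
  expect_equal(translate("AT", 0), "")
})

test_that("ORF finding reports ATG-initiated, stop-terminated frames", {
  orfs <- find_orfs("ATGAAATAG", min_protein_len = 1)
  expect_length(orfs, 1)
  expect_equal(orfs[[1]]$protein, "MK")
  expect_equal(orfs[[1]]$start, 1L)
  expect_equal(orfs[[1]]$end, 6L)   # stop codon excluded
  expect_equal((orfs[[1]]$end - orfs[[1]]$start + 1) / 3,
               nchar(orfs[[1]]$protein))
  # no stop, no ORF; too short, no ORF
  expect_length(find_orfs("ATGAAAAAAAAA", min_protein_len = 1), 0)
  expect_length(find_orfs("ATGAAATAG", min_protein_len = 3), 0)
})

test_that("slippery heptamer detection enforces the XXXYYYZ rule", {
  s1 <- detect_slippery_sites("GGGTTTA")
  expect_length(s1, 1)
  expect_equal(s1[[1]][c("X", "Y", "Z")], list(X = "G", Y = "T", Z = "A"))
  expect_length(detect_slippery_sites("GAGTTTA"), 0)   # bases 1-3 differ
  s2 <- detect_slippery_sites("AAATTTC")
  expect_length(s2, 1)
  expect_equal(s2[[1]][c("X", "Y", "Z")], list(X = "A", Y = "T", Z = "C"))
  expect_length(detect_slippery_sites("GGGTTTG"), 0)   # Z = G excluded
  expect_length(detect_slippery_sites("GGGCCCA"), 0)   # Y not A/T
  expect_length(detect_slippery_sites("GGGCCCA", strict = FALSE), 1)
})

test_that("slippery detection equals a brute-force heptamer scan", {
  set.seed(42)
  for (rep in 1:20) {
    s <- random_dna(sample(100:400, 1))
    got <- vapply(detect_slippery_sites(s), `[[`, 1L, "position")
    expect_equal(got, oracle_slippery(s))
    got2 <- vapply(detect_slippery_sites(s, strict = FALSE), `[[`, 1L,
                   "position")
    expect_equal(got2, oracle_slippery(s, strict = FALSE))
  }
})

test_that("the Gag-Pol model on an unmutated genome reproduces the truth", {
  gp <- fix$gagpol
  tr <- fix$truth
  expect_equal(gp$gag$start, unname(tr$gag["start"]))
  expect_equal(gp$gag$end, unname(tr$gag["end"]))
  expect_equal(gp$gag$protein, tr$gag_protein)
  expect_equal(gp$slippery$position, tr$slippery_pos)
  expect_equal(gp$slippery$heptamer, tr$heptamer)
  expect_equal(gp$pol$start, unname(tr$pol["start"]))
  expect_equal(gp$pol$end, unname(tr$pol["end"]))
  expect_equal(gp$pol$frame, (gp$gag$frame - 1) %% 3)
  expect_identical(gp$fusion_protein, tr$fusion_protein)
  expect_identical(gp$reinit_codons, tr$reinit)
})

test_that("the fusion protein splices a Gag prefix onto the -1 frame", {
  gp <- fix$gagpol
  canon <- canonical_seq(fix$partition)
  h7 <- gp$slippery$position + 6L
  m <- (h7 - gp$gag$start + 1L) %/% 3L
  prefix <- substr(gp$gag$protein, 1, m)
  expect_identical(substr(gp$fusion_protein, 1, m), prefix)
  # the tail is the -1-frame translation from one nt before the next codon
  q <- gp$gag$start + 3L * m - 1L
  tail_aa <- translate(substr(canon, q, gp$pol$end), 0)
  expect_identical(substr(gp$fusion_protein, m + 1, nchar(gp$fusion_protein)),
                   tail_aa)
  expect_false(grepl("*", gp$fusion_protein, fixed = TRUE))
  # and the fusion ends exactly like Pol
  expect_identical(substr(gp$fusion_protein,
                          nchar(gp$fusion_protein) - 99,
                          nchar(gp$fusion_protein)),
                   substr(gp$pol$protein, nchar(gp$pol$protein) - 99,
                          nchar(gp$pol$protein)))
})

test_that("disrupting every slippery heptamer yields the no-frameshift-site error", {
  # random coding sequence contains chance XXXYYYZ heptamers, so disrupt
  # them all (set the fourth base to C, which breaks the A/T-only YYY run
  # and can never create a stop codon) before expecting the error
  res <- chars(fix$genome$sequence$residues)
  off <- fix$truth$five_extra_len
  canon_end <- off + fix$truth$canonical_len
  repeat {
    canon <- paste(res[(off + 1):canon_end], collapse = "")
    sites <- detect_slippery_sites(canon)
    if (length(sites) == 0) break
    for (s in sites) res[off + s$position + 3L] <- "C"
  }
  vs <- viral_sequence("mut", paste(res, collapse = ""))
  p <- partition_genome(vs, anchor_5 = fix$truth$motif5,
                        anchor_3 = fix$truth$tail3)
  expect_error(build_gagpol_model(p), "no frameshift site")
})

test_that("point mutations away from annotated features leave annotations unchanged", {
  tr <- fix$truth
  res <- chars(fix$genome$sequence$residues)
  # mutate a handful of unprotected positions to a fixed base
  prot <- rep(FALSE, length(res))
  pm <- tr$protected_abs
  for (r in seq_len(nrow(pm))) prot[pm[r, 1]:pm[r, 2]] <- TRUE
  set.seed(5)
  sites <- sample(which(!prot), 10)
  res[sites] <- "C"
  vs <- viral_sequence("pm", paste(res, collapse = ""))
  p <- partition_genome(vs, anchor_5 = tr$motif5, anchor_3 = tr$tail3)
  gp <- build_gagpol_model(p)
  expect_equal(gp$gag$start, unname(tr$gag["start"]))
  expect_equal(gp$slippery$position, tr$slippery_pos)
  expect_equal(gp$pol$start, unname(tr$pol["start"]))
})

test_that("Gag-Pol annotations export as valid GFF3", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  gagpol_gff3(fix$partition, fix$gagpol, tmp)
  lines <- readLines(tmp)
  body <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(body) == 9L))
  expect_true(any(grepl("ID=gag", lines)))
  expect_true(any(grepl("heptamer=GGGTTTA", lines)))
})
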