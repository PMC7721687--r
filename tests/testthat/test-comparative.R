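test_that("pairwise identity behaves on exact and simple cases", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT", "NT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA", "NT"), 75)
  expect_equal(pairwise_identity("MKVLH", "MKVLH", "AA"), 100)
  expect_error(pairwise_identity("", "ACGT", "NT"), "empty")
  set.seed(41)
  for (rep in 1:5) {
    a <- random_dna(80)
    b <- random_dna(90)
    expect_equal(pairwise_identity(a, b, "NT"), pairwise_identity(b, a, "NT"))
  }
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  set.seed(42)
  seqs <- c(x = random_dna(120), y = random_dna(120), z = random_dna(120))
  m <- identity_matrix(seqs, kind = "NT")
  expect_true(isSymmetric(m$values))
  expect_equal(unname(diag(m$values)), rep(100, 3))
  expect_true(all(m$values >= 0 & m$values <= 100))
  # single pair consistency with pairwise_identity
  m2 <- identity_matrix(seqs[1:2], kind = "NT")
  expect_equal(m2$values[1, 2], pairwise_identity(seqs[[1]], seqs[[2]], "NT"))
})

test_that("off-diagonal structure tracks planted divergence", {
  g <- fix$genome
  fam <- evolve_family(g, spec = la_family_spec(
    "((L1:0.0,L2:0.0):0.0,L3:0.15);", seed = 13))
  m <- identity_matrix(vapply(fam$genomes, function(x) x$residues, ""),
                       kind = "NT")
  expect_equal(m$values["L1", "L2"], 100)
  expect_lt(m$values["L1", "L3"], 95)
  expect_lt(m$values["L2", "L3"], 95)
})

test_that("region extraction projects reference intervals through alignments", {
  set.seed(43)
  ref <- paste(sample(c(chars("ACDEFGHIKLMNPQRSTVWY")), 200, replace = TRUE),
               collapse = "")
  reg <- region_spec("VAR44_AA", 101, 144, "AA")
  expect_equal(extract_region(ref, ref, reg), substr(ref, 101, 144))
  expect_equal(nchar(extract_region(ref, ref, reg)), 44)
  # a target with substitutions but no indels keeps the planted region copy
  tgt <- chars(ref)
  tgt[c(10, 50, 160)] <- "A"
  tgt <- paste(tgt, collapse = "")
  expect_equal(extract_region(tgt, ref, reg), substr(tgt, 101, 144))
  expect_error(extract_region(ref, ref, region_spec("x", 190, 300, "AA")),
               "beyond reference")
})

test_that("conserved-residue panels flag targeted mutations only", {
  ref <- fix$gagpol$fusion_protein
  motifs <- list(A = c(900, 910), B = c(950, 960),
                 C = c(1000, 1010), D = c(1050, 1060))
  panel <- check_conserved_residues(ref, ref, motifs = motifs)
  expect_true(panel$h154)
  expect_true(all(panel$cap_residues))
  expect_equal(unname(panel$rdrp_motifs), rep(100, 4))
  mut <- chars(ref)
  mut[154] <- if (mut[154] == "A") "V" else "A"
  panel2 <- check_conserved_residues(paste(mut, collapse = ""), ref,
                                     motifs = motifs)
  expect_false(panel2$h154)
  expect_true(all(panel2$cap_residues))
  expect_equal(unname(panel2$rdrp_motifs), rep(100, 4))
})

test_that("neighbor-joining reproduces three-taxon additive distances", {
  # additive distances: dAB = 0.2, dAC = 0.3, dBC = 0.4
  v <- matrix(c(100, 80, 70,
                80, 100, 60,
                70, 60, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- structure(list(labels = c("A", "B", "C"), values = v,
                      region = "NT", aligner_settings = list()),
                 class = "la_identity_matrix")
  ph <- nj_phylogram(m)
  tree <- ph$tree
  # closed form: edge to A = (dAB + dAC - dBC)/2 etc.
  want <- c(A = 0.05, B = 0.15, C = 0.25)
  got <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                         tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(got[names(want)], want, tolerance = 1e-9)
  expect_error(nj_phylogram(structure(list(labels = c("A", "B"),
                                           values = v[1:2, 1:2]),
                                      class = "la_identity_matrix")),
               "too few taxa")
})

test_that("all-equal distances give a star-like tree with equal branches", {
  labs <- paste0("t", 1:4)
  v <- matrix(90, 4, 4, dimnames = list(labs, labs))
  diag(v) <- 100
  m <- structure(list(labels = labs, values = v, region = "NT",
                      aligner_settings = list()),
                 class = "la_identity_matrix")
  ph <- nj_phylogram(m)
  tip_edges <- ph$tree$edge.length[ph$tree$edge[, 2] <= 4]
  expect_equal(tip_edges, rep(0.05, 4), tolerance = 1e-9)
  internal <- ph$tree$edge.length[ph$tree$edge[, 2] > 4]
  expect_equal(internal, rep(0, length(internal)), tolerance = 1e-9)
})

test_that("NJ on a low-divergence simulated family recovers the topology", {
  g <- fix$genome
  fam <- evolve_family(g, spec = la_family_spec(two_cluster_tree(
    within = 0.004, between = 0.04), seed = 17))
  m <- identity_matrix(vapply(fam$genomes, function(x) x$residues, ""),
                       kind = "NT")
  ph <- nj_phylogram(m)
  rf <- ape::dist.topo(ape::unroot(ph$tree), ape::unroot(fam$tree))
  expect_equal(as.numeric(rf), 0)
})

test_that("higher substitution rates never increase expected identity", {
  g <- fix$genome
  mean_offdiag <- function(rate, seed) {
    fam <- evolve_family(g, spec = la_family_spec(
      sprintf("(L1:%f,L2:%f,L3:%f);", rate, rate, rate), seed = seed))
    m <- identity_matrix(vapply(fam$genomes, function(x) x$residues, ""),
                         kind = "NT")
    mean(m$values[upper.tri(m$values)])
  }
  rates <- c(0.01, 0.05, 0.12)
  ids <- vapply(seq_along(rates), function(i)
    mean_offdiag(rates[i], seed = 100 + i), 0)
  expect_true(all(diff(ids) < 0))
})
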