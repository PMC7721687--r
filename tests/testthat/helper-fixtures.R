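# Shared fixtures: built once per test run. All synthetic, all seeded.

# report every failure rather than stopping after the default cap
options(testthat.progress.max_fails = Inf)

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

fix <- local({
  g <- simulate_genome(seed = 1)
  p <- partition_genome(g$sequence, anchor_5 = g$truth$motif5,
                        anchor_3 = g$truth$tail3)
  gp <- build_gagpol_model(p)
  list(genome = g, truth = g$truth, partition = p, gagpol = gp)
})

# a second, independent genome (different seed) for two-virus analyses
fix2 <- local({
  g <- simulate_genome(seed = 2)
  p <- partition_genome(g$sequence, anchor_5 = g$truth$motif5,
                        anchor_3 = g$truth$tail3)
  list(genome = g, truth = g$truth, partition = p)
})

# small hand-built partition: 10 nt 5'-extra, 60 nt canonical, 8 nt 3'-extra
fix_small <- local({
  set.seed(99)
  canon <- paste0("GAAAAA", random_dna(46), "CCATATGC")
  vs <- viral_sequence("toy", paste0("CCGCGCATAC", canon, "ACCGGTTA"))
  partition_genome(vs, anchor_5 = "GAAAAA", anchor_3 = "CCATATGC")
})
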