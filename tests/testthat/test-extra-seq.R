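test_that("the planted boundary-spanning repeat is the top self-identity match", {
  tr <- fix$truth
  si <- find_self_identity(fix$partition)
  expect_gte(nrow(si), 2)
  off <- tr$five_extra_len
  expect_equal(si$length[1], 51L)
  expect_equal(c(si$q_start[1], si$q_end[1]), tr$self_identity5$q_span_abs)
  expect_equal(c(si$s_start[1], si$s_end[1]),
               tr$self_identity5$s_span_can + off)
  # the 3' planted copy is found too
  row3 <- si[si$length == 16L, ][1, ]
  expect_equal(c(row3$q_start, row3$q_end), tr$self_identity3$q_span_abs)
  expect_equal(c(row3$s_start, row3$s_end),
               tr$self_identity3$s_span_can + off)
  # every reported match re-validates by direct substring comparison,
  # is maximal, and has disjoint intervals
  res <- fix$partition$sequence$residues
  for (r in seq_len(nrow(si))) {
    expect_identical(substr(res, si$q_start[r], si$q_end[r]),
                     substr(res, si$s_start[r], si$s_end[r]))
    expect_false(si$q_start[r] <= si$s_end[r] &&
                   si$s_start[r] <= si$q_end[r])
    if (si$q_start[r] > 1 && si$s_start[r] > 1) {
      expect_false(substr(res, si$q_start[r] - 1, si$q_start[r] - 1) ==
                     substr(res, si$s_start[r] - 1, si$s_start[r] - 1))
    }
    if (si$q_end[r] < nchar(res) && si$s_end[r] < nchar(res)) {
      expect_false(substr(res, si$q_end[r] + 1, si$q_end[r] + 1) ==
                     substr(res, si$s_end[r] + 1, si$s_end[r] + 1))
    }
  }
})

test_that("a genome without duplication yields no self-identity match", {
  expect_equal(nrow(find_self_identity(fix_small)), 0)
  vs <- viral_sequence("noextra", paste0("GAAAAA", random_dna(100)))
  p <- partition_genome(vs, anchor_5 = "GAAAAA")
  expect_error(find_self_identity(p), "no extra zones")
})

test_that("self-identity agrees with the quadratic oracle", {
  p <- fix$partition
  n <- p$sequence$length
  f <- p$five_extra_len
  res <- p$sequence$residues
  got <- find_self_identity(p, min_len = 13)
  canon <- canonical_seq(p)
  want5 <- oracle_mems(substr(res, 1, f + 60), canon, 13, s_off = f)
  want3 <- oracle_mems(substr(res, n - p$three_extra_len - 60 + 1, n), canon,
                       13, q_off = n - p$three_extra_len - 60L, s_off = f)
  want <- unique(rbind(want5, want3))
  want <- want[order(-want$length, want$q_start), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$q_start, want$q_start)
  expect_equal(got$s_start, want$s_start)
  expect_equal(got$length, want$length)
})

test_that("shared stretches between two extras are found and maximal", {
  # plant a 13-mer in both 5'-extras of two small genomes
  set.seed(21)
  shared13 <- "GACAAGTCCTCCG"
  mk <- function(id, pre, post) {
    vs <- viral_sequence(id, paste0(pre, shared13, post,
                                    "GAAAAA", random_dna(120)))
    partition_genome(vs, anchor_5 = "GAAAAA")
  }
  # distinct flanking bases so the planted stretch is exactly maximal
  pa <- mk("va", paste0(random_dna(9), "T"), paste0("C", random_dna(4)))
  pb <- mk("vb", paste0(random_dna(2), "G"), paste0("A", random_dna(11)))
  sh <- find_shared_stretches(pa, pb, min_len = 13)
  expect_gte(nrow(sh), 1)
  expect_equal(sh$stretch[1], shared13)
  expect_equal(sh$length[1], 13L)
  # agreement with the common-substring oracle
  want <- oracle_mems(extra5_seq(pa), extra5_seq(pb), 13,
                      require_disjoint = FALSE)
  expect_equal(nrow(sh), nrow(want))
  expect_equal(sh$a_start, want$q_start)
  expect_equal(sh$b_start, want$s_start)
  # unrelated random extras share nothing at this length
  set.seed(22)
  ve <- partition_genome(viral_sequence("ve", paste0(random_dna(60), "GAAAAA",
                                                     random_dna(120))),
                         anchor_5 = "GAAAAA")
  vf <- partition_genome(viral_sequence("vf", paste0(random_dna(60), "GAAAAA",
                                                     random_dna(120))),
                         anchor_5 = "GAAAAA")
  expect_equal(nrow(find_shared_stretches(ve, vf, min_len = 13)), 0)
  expect_error(find_shared_stretches(ve, fix_small, zone = "THREE_EXTRA",
                                     min_len = 13), "empty")
})

test_that("palindrome scanning finds designed and printed palindromes", {
  hit <- palindrome_scan("GGGAATTCCC", min_arm = 3, max_loop = 4,
                         max_mismatch = 0)
  # a perfect palindrome: one non-redundant hit over the whole span
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 0L)
  expect_gte(hit$arm_len, 3L)
  expect_equal(c(hit$start, hit$end), c(1L, 10L))
  # the printed 31-mer is almost palindromic: arms around its 15-nt core
  p31 <- palindrome_scan("CACGTAGCTTTATTAATTAATATGCTACGTG",
                         min_arm = 8, max_loop = 15, max_mismatch = 2)
  expect_gte(nrow(p31), 1)
  expect_gte(max(p31$end - p31$start + 1), 24)
  expect_true(all(p31$mismatches <= 2))
  # the planted near-palindrome around the 5' motif
  tr <- fix$truth
  ph <- palindrome_scan(substr(fix$genome$sequence$residues, 1, 60))
  expect_true(any(ph$start == tr$palindrome$start_abs &
                    ph$end == tr$palindrome$end_abs &
                    ph$arm_len >= tr$palindrome$arm_len))
})

test_that("palindrome scanning equals the enumeration oracle", {
  set.seed(23)
  for (rep in 1:8) {
    s <- random_dna(sample(40:120, 1))
    got <- palindrome_scan(s, min_arm = 4, max_loop = 6, max_mismatch = 1)
    want <- oracle_palindromes(s, min_arm = 4, max_loop = 6,
                               max_mismatch = 1)
    expect_equal(got, want, label = paste("palindromes of", s))
  }
})

test_that("host-sequence matching recovers planted fragments", {
  g <- simulate_genome(la_genome_params("LAlus4-EX229"), seed = 3)
  p <- partition_genome(g$sequence, anchor_5 = "GAAAAA",
                        anchor_3 = "CCATATGC")
  hits <- match_host_sequences(p, "FIVE_EXTRA", g$host_db)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$host_id, g$truth$host$host_id)
  expect_equal(hits$identity, 100)
  expect_equal(hits$length, g$truth$host$length)
  expect_equal(hits$strand, "+")
  # ~7% substitutions bring identity close to the induced mismatch level
  set.seed(31)
  res <- chars(g$sequence$residues)
  span <- g$truth$host$extra_span
  sites <- sample(span[1]:span[2], round(0.07 * g$truth$host$length))
  for (i in sites) res[i] <- sample(setdiff(c("A", "C", "G", "T"), res[i]), 1)
  vs <- viral_sequence("div", paste(res, collapse = ""))
  p2 <- partition_genome(vs, anchor_5 = "GAAAAA", anchor_3 = "CCATATGC")
  hits2 <- match_host_sequences(p2, "FIVE_EXTRA", g$host_db)
  expect_gte(nrow(hits2), 1)
  induced <- 100 * (1 - length(sites) / g$truth$host$length)
  expect_lt(abs(hits2$identity[1] - induced), 3)
  # identity is invariant under query/subject swap
  frag <- substr(g$sequence$residues, 1, g$truth$host$length)
  host_seq <- g$host_db[[1]]$residues
  a1 <- Biostrings::pairwiseAlignment(frag, host_seq, type = "local")
  a2 <- Biostrings::pairwiseAlignment(host_seq, frag, type = "local")
  expect_equal(Biostrings::pid(a1), Biostrings::pid(a2))
  expect_error(match_host_sequences(p, "FIVE_EXTRA", list()),
               "no host records")
})
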