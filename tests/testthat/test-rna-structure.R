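test_that("hairpin folding matches structure expectations on designed cases", {
  expect_null(fold_hairpin("AAAAAAAAAA"))          # nothing can pair
  h <- fold_hairpin("GGGGAAAACCCC")
  expect_equal(nrow(h$pairs), 4)
  expect_equal(h$loop_seq, "AAAA")
  expect_equal(h$dot_bracket, "((((....))))")
  # energy equals the independent enumeration oracle
  expect_equal(h$dG_kcal, oracle_mfe("GGGGAAAACCCC"), tolerance = 1e-9)
  expect_error(fold_hairpin("GGGG"), "too short")
  expect_error(fold_hairpin(random_dna(300)), "too long")
  expect_error(fold_hairpin("GGGGXAAACCCC"), "bad alphabet")
})

test_that("dynamic programming equals brute-force enumeration on short RNA", {
  set.seed(7)
  for (rep in 1:18) {
    s <- random_dna(sample(8:22, 1), gc = runif(1, 0.3, 0.7))
    h <- fold_hairpin(s)
    o <- oracle_mfe(s)
    if (is.null(h)) {
      expect_null(o)
    } else {
      expect_equal(h$dG_kcal, o, tolerance = 1e-9,
                   label = paste("MFE of", s))
    }
  }
})

test_that("folding is invariant under T/U and flanks never worsen the MFE", {
  set.seed(8)
  for (rep in 1:10) {
    s <- random_dna(sample(15:40, 1))
    h1 <- fold_hairpin(s)
    h2 <- fold_hairpin(chartr("T", "U", s))
    if (is.null(h1)) {
      expect_null(h2)
      next
    }
    expect_equal(h1$dG_kcal, h2$dG_kcal)
    expect_equal(h1$dG_kJ / h1$dG_kcal, 4.184)
    hf <- fold_hairpin(paste0("AAAAA", s, "AAAAA"))
    expect_lte(hf$dG_kcal, h1$dG_kcal + 1e-9)
  }
})

test_that("near-optimal enumeration matches the oracle's energy window", {
  # single stem: exactly one hairpin
  hs <- enumerate_hairpins("GGGGGGAAAACCCCCC", suboptimality_percent = 5)
  expect_length(hs, 1)
  # suboptimality 0 keeps only ties with the minimum
  hs0 <- enumerate_hairpins("GGGGGGAAAACCCCCC", suboptimality_percent = 0)
  expect_true(all(vapply(hs0, function(h) h$dG_kcal, 0) ==
                    hs0[[1]]$dG_kcal))
  set.seed(9)
  for (rep in 1:6) {
    s <- random_dna(25, gc = 0.6)
    hs <- enumerate_hairpins(s, suboptimality_percent = 5, max_count = 50)
    all_closed <- oracle_fold_all(s)
    if (is.null(all_closed) || min(all_closed$e) >= 0) {
      expect_length(hs, 0)
      next
    }
    mfe <- min(all_closed$e)
    want <- all_closed[all_closed$e <= mfe + abs(mfe) * 0.05 + 1e-9 &
                         all_closed$e < 0, ]
    got <- data.frame(i = vapply(hs, function(h) h$span[1], 0L),
                      j = vapply(hs, function(h) h$span[2], 0L),
                      e = vapply(hs, function(h) h$dG_kcal, 0))
    expect_equal(nrow(got), nrow(want))
    ord <- order(want$i, want$j)
    ord2 <- order(got$i, got$j)
    expect_equal(got$i[ord2], want$i[ord])
    expect_equal(got$j[ord2], want$j[ord])
    expect_equal(got$e[ord2], want$e[ord], tolerance = 1e-9)
  }
})

test_that("the printed 31-mer folds to the reported hairpin", {
  h <- fold_hairpin("CACGTAGCTTTATTAATTAATATGCTACGTG")
  expect_false(is.null(h))
  # the first four canonical nucleotides sit unpaired in the loop
  expect_true(grepl("AAUU", h$loop_seq))
  # reported free energy -50 kJ/mol, within the declared 10% band
  expect_lt(h$dG_kJ, -45)
  expect_gt(h$dG_kJ, -55)
})

test_that("folding agrees with an independent thermodynamic implementation", {
  seqs <- c("CACGUAGCUUUAUUAAUUAAUAUGCUACGUG",
            "GGGGGGAAAACCCCCC",
            "GGCGCAAACAGCGCC")
  for (s in seqs) {
    out <- system2("RNAfold", c("--noPS", "-d0"), input = s,
                   stdout = TRUE)
    mfe_vienna <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)$", "\\1",
                                 out[2]))
    h <- fold_hairpin(s)
    # same parameter family; small differences expected from the generic
    # treatment of tabulated small interior loops and dangles
    expect_lt(abs(h$dG_kcal - mfe_vienna), 1.5)
  }
})

test_that("kissing complexes count the longest antiparallel duplex", {
  expect_equal(kissing_pairs("AAUU", "AAUU")$n_pairs, 4)
  expect_equal(kissing_pairs("AUAU", "AUAU")$n_pairs, 4)
  expect_equal(kissing_pairs("AAAA", "GGGG")$n_pairs, 0)
  expect_equal(kissing_pairs("GGGG", "UUUU", allow_gu = TRUE)$n_pairs, 4)
  expect_equal(kissing_pairs("GGGG", "UUUU", allow_gu = FALSE)$n_pairs, 0)
  expect_error(kissing_pairs("", "AAUU"), "non-empty")
  # symmetry on random loops
  set.seed(10)
  for (rep in 1:20) {
    a <- random_dna(sample(3:10, 1))
    b <- random_dna(sample(3:10, 1))
    expect_equal(kissing_pairs(a, b)$n_pairs, kissing_pairs(b, a)$n_pairs)
  }
})

test_that("all five cis-signals are recovered at planted coordinates", {
  tr <- fix$truth
  sg <- find_signal_stemloops(fix$partition, fix$gagpol,
                              ref_packaging_loop = tr$signals$packaging_loop)
  off <- tr$five_extra_len
  expect_equal(sg$FIVE_PRIME_MOTIF$abs_span, off + tr$signals$five_prime_motif)
  expect_equal(sg$AU_RICH$abs_span, off + tr$signals$au_rich)
  expect_equal(sg$AU_RICH$au_fraction, 1.0)
  expect_equal(sg$FRAMESHIFT_SL$abs_span, off + tr$signals$frameshift_sl)
  expect_equal(sg$PACKAGING_SL$abs_span, off + tr$signals$packaging_sl)
  expect_equal(sg$REPLICATION_SL$abs_span, off + tr$signals$replication_sl)
  # stem loops actually fold with negative energy
  for (nm in c("FRAMESHIFT_SL", "PACKAGING_SL", "REPLICATION_SL")) {
    expect_lt(sg[[nm]]$hairpin$dG_kcal, 0)
  }
  # the frameshift hairpin starts within 12 nt of the heptamer
  h7_abs <- off + tr$slippery_pos + 6L
  expect_lte(sg$FRAMESHIFT_SL$abs_span[1] - h7_abs, 12L)
})
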