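test_that("zone lengths partition the full sequence and match planted truth", {
  p <- fix$partition
  tr <- fix$truth
  expect_equal(p$five_extra_len, tr$five_extra_len)
  expect_equal(p$canonical_len, tr$canonical_len)
  expect_equal(p$three_extra_len, tr$three_extra_len)
  expect_equal(p$five_extra_len + p$canonical_len + p$three_extra_len,
               p$sequence$length)
  # the published LA geometry this preset mirrors: 14 / 4591 / 17 = 4622
  expect_equal(c(p$five_extra_len, p$canonical_len, p$three_extra_len),
               c(14L, 4591L, 17L))
  expect_equal(p$sequence$length, 4622L)
  expect_identical(substr(canonical_seq(p), 1, 6), tr$motif5)
})

test_that("a sequence equal to its own canonical zone has empty extras", {
  vs <- viral_sequence("bare", paste0("GAAAAA", random_dna(100)))
  p <- partition_genome(vs, anchor_5 = "GAAAAA", anchor_3 = NULL)
  expect_equal(p$five_extra_len, 0L)
  expect_equal(p$three_extra_len, 0L)
  expect_equal(p$canonical_len, vs$length)
})

test_that("anchor errors are raised as specified", {
  vs <- viral_sequence("x", random_dna(200))
  expect_error(partition_genome(vs, anchor_5 = "GAAAAAGGGCCC"),
               "unanchorable")
  vs2 <- viral_sequence("y", paste0(random_dna(500), "GAAAAA",
                                    random_dna(60)))
  expect_error(partition_genome(vs2, anchor_5 = "GAAAAA", max_extra = 400L),
               "ambiguous anchor")
  expect_error(partition_genome(fix$partition$sequence, anchor_5 = "GANAAA"),
               "anchors must not contain N")
})

test_that("signed coordinates convert as the convention dictates", {
  p <- fix$partition   # 14 / 4591 / 17
  c1 <- to_signed_coord(p, 15)
  expect_equal(c1$zone, "CANONICAL")
  expect_equal(c1$index, 1L)
  c2 <- to_signed_coord(p, 1)
  expect_equal(c2$zone, "FIVE_EXTRA")
  expect_equal(c2$index, 14L)
  c3 <- to_signed_coord(p, 4622)
  expect_equal(c3$zone, "THREE_EXTRA")
  expect_equal(c3$index, 17L)
  expect_equal(from_signed_coord(p, signed_coord("CANONICAL", 401)), 415L)
  expect_equal(from_signed_coord(p, signed_coord("FIVE_EXTRA", 1)), 14L)
  expect_equal(from_signed_coord(p, signed_coord("THREE_EXTRA", 2)), 4607L)
  expect_error(to_signed_coord(p, 0), "out of bounds")
  expect_error(to_signed_coord(p, 4623), "out of bounds")
  expect_error(from_signed_coord(p, signed_coord("THREE_EXTRA", 18)),
               "out of bounds")
})

test_that("coordinate conversion is a bijection over the whole sequence", {
  set.seed(11)
  for (rep in 1:5) {
    five <- sample(0:30, 1)
    three <- sample(0:30, 1)
    canon <- paste0("GAAAAA", random_dna(80))
    vs <- viral_sequence(paste0("r", rep),
                         paste0(if (five) random_dna(five) else "",
                                canon,
                                if (three) random_dna(three) else ""))
    p <- try(partition_genome(vs, anchor_5 = "GAAAAA",
                              anchor_3 = substr(canon, 79, 86)), silent = TRUE)
    if (inherits(p, "try-error")) next  # chance extra anchor occurrence
    for (i in seq_len(vs$length)) {
      expect_equal(from_signed_coord(p, to_signed_coord(p, i)), i)
    }
  }
})

test_that("span lengths count closed intervals across zone boundaries", {
  p <- fix$partition
  expect_equal(span_length(p, signed_coord("FIVE_EXTRA", 14),
                           signed_coord("CANONICAL", 37)), 51L)
  expect_equal(span_length(p, signed_coord("CANONICAL", 7),
                           signed_coord("CANONICAL", 7)), 1L)
  expect_error(span_length(p, signed_coord("CANONICAL", 10),
                           signed_coord("CANONICAL", 5)), "negative span")
  # geometry of a 4580 + 42 genome: canonical 4579 to (+)42 is 44 nt
  vs <- viral_sequence("g", paste0("GAAAAA", random_dna(4574),
                                   random_dna(42)))
  p2 <- structure(list(sequence = vs, five_extra_len = 0L,
                       canonical_len = 4580L, three_extra_len = 42L,
                       anchor_5 = "GAAAAA", anchor_3 = NULL,
                       anchor_method = "motif"), class = "la_partition")
  expect_equal(span_length(p2, signed_coord("CANONICAL", 4579),
                           signed_coord("THREE_EXTRA", 42)), 44L)
  # consistency with the absolute positions
  a <- signed_coord("CANONICAL", 100)
  b <- signed_coord("THREE_EXTRA", 3)
  expect_equal(span_length(p, a, b),
               from_signed_coord(p, b) - from_signed_coord(p, a) + 1L)
})

test_that("reference-projected partitioning reproduces reference boundaries", {
  p <- fix_small
  copy <- viral_sequence("copy", p$sequence$residues)
  q <- partition_genome(copy, reference = p)
  expect_equal(q$anchor_method, "reference_alignment")
  expect_equal(q$five_extra_len, p$five_extra_len)
  expect_equal(q$canonical_len, p$canonical_len)
  expect_equal(q$three_extra_len, p$three_extra_len)
})

test_that("partition exports validate as GFF3 and JSON", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  partition_gff3(fix_small, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "##gff-version 3")
  body <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(body) == 9L))
  starts <- as.integer(vapply(body, `[[`, "", 4))
  ends <- as.integer(vapply(body, `[[`, "", 5))
  expect_true(all(starts >= 1 & ends <= fix_small$sequence$length))
  rep <- partition_report(fix_small)
  expect_equal(rep$five_extra_len + rep$canonical_len + rep$three_extra_len,
               rep$length)
})
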