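test_that("direct-repeat excision releases the spacer plus one full hybrid
           site", {
  b <- build_construct_map("pMC479", seed = 3)
  expect_equal(as.integer(digest(b$mol, b$enzyme)), c(3207L, 1366L))
  res <- site_recombine(b$mol, "attL88", "attB44")
  expect_equal(res$reaction, "excision")
  lens <- vapply(res$products, `[[`, 0L, "length")
  expect_equal(lens, c(849L, 3724L))
  expect_equal(sum(lens), b$mol$length)          # nucleotide conservation
  ## the excised circle is NdeI-free; the backbone gives the recombined
  ## fragment pattern
  circ_dig <- digest(res$products[[1]], b$enzyme)
  expect_equal(attr(circ_dig, "status"), "uncut_circular")
  expect_equal(as.integer(digest(res$products[[2]], b$enzyme)),
               c(2358L, 1366L))
  ## hybrid site on the circle is full-length (87 bp)
  hyb <- res$products[[1]]$features
  hyb <- hyb[hyb$type == "att", , drop = FALSE]
  expect_equal(hyb$end - hyb$start, 87L)
})

test_that("excision and integration are mutually inverse (Campbell
           reversibility)", {
  b <- build_construct_map("pMC479", seed = 13)
  ex <- site_recombine(b$mol, "attL88", "attB44")
  circ <- ex$products[[1]]; back <- ex$products[[2]]
  hyb_c <- circ$features$name[circ$features$type == "att"]
  hyb_b <- back$features$name[back$features$type == "att"]
  re <- site_recombine(back, hyb_b[length(hyb_b)], hyb_c[length(hyb_c)],
                       molB = circ)
  expect_equal(re$reaction, "integration")
  expect_equal(re$products[[1]]$length, b$mol$length)
  expect_true(circular_equal(re$products[[1]]$seq, b$mol$seq))
})

test_that("inversion reverse-complements the inter-core segment and is an
           involution", {
  b <- build_construct_map("pMC477", seed = 4)
  expect_equal(as.integer(digest(b$mol, b$enzyme)), c(2796L, 1777L))
  inv <- site_recombine(b$mol, "attL88", "attB44")
  expect_equal(inv$reaction, "inversion")
  prod <- inv$products[[1]]
  expect_equal(prod$length, b$mol$length)
  ## manual sequence-level oracle
  cuts <- inv$cuts
  manual <- paste0(substr(b$mol$seq, 1, cuts[1]),
                   reverse_complement(substr(b$mol$seq, cuts[1] + 1,
                                             cuts[2])),
                   substr(b$mol$seq, cuts[2] + 1, b$mol$length))
  expect_identical(prod$seq, manual)
  expect_equal(as.integer(digest(prod, b$enzyme)), c(2358L, 2215L))
  again <- site_recombine(prod, "attL88", "attB44")
  expect_identical(again$products[[1]]$seq, b$mol$seq)
})

test_that("recombination requires identical cores", {
  set.seed(8)
  core1 <- random_test_dna(43); core2 <- random_test_dna(43)
  feats <- rbind(att_feature("siteLeu", 100L, 143L, "+"),
                 att_feature("siteThr", 900L, 943L, "-"))
  seq <- random_test_dna(2000)
  substr(seq, 101, 143) <- substr(core1, 1, 43)
  substr(seq, 901, 943) <- substr(core2, 1, 43)
  mol <- molecule("mismatched", seq, circular = FALSE, features = feats)
  expect_error(site_recombine(mol, "siteLeu", "siteThr"),
               "incompatible sites")
})

test_that("repeated integration builds multimers of increasing size", {
  set.seed(9)
  mono <- molecule("unit", random_test_dna(3000), circular = TRUE)
  prod <- mono
  for (n in 1:3) {
    hr <- homologous_recombine(prod, mono, min_core = 100L)
    expect_gte(length(hr), 1L)
    prod <- hr[[1]]$products[[1]]
    expect_equal(prod$length, (n + 1L) * 3000L)
  }
})

test_that("low-specificity reactions respect the shared-segment threshold", {
  set.seed(10)
  seg <- random_test_dna(100)
  lin <- molecule("lac100",
                  paste0(random_test_dna(500), seg, random_test_dna(800),
                         reverse_complement(seg), random_test_dna(600)),
                  circular = FALSE)
  h100 <- homologous_recombine(lin, min_core = 100L)
  expect_length(h100, 1L)
  expect_equal(h100[[1]]$reaction, "inversion")
  expect_equal(h100[[1]]$core_len, 100L)
  expect_length(homologous_recombine(lin, min_core = 101L), 0L)
  ## product equals the hand-built expectation (crossover at core midpoint)
  c1 <- 500L + 50L; c2 <- 1400L + 50L
  manual <- paste0(substr(lin$seq, 1, c1),
                   reverse_complement(substr(lin$seq, c1 + 1, c2)),
                   substr(lin$seq, c2 + 1, lin$length))
  expect_identical(h100[[1]]$products[[1]]$seq, manual)
})

test_that("an intermolecular shared segment gives one verified co-integrate", {
  set.seed(11)
  seg <- random_test_dna(120)
  a <- molecule("a", paste0(random_test_dna(700), seg,
                            random_test_dna(400)), circular = TRUE)
  b <- molecule("b", paste0(random_test_dna(300), seg,
                            random_test_dna(900)), circular = TRUE)
  hr <- homologous_recombine(a, b, min_core = 100L)
  expect_length(hr, 1L)
  expect_equal(hr[[1]]$core_len, 120L)
  prod <- hr[[1]]$products[[1]]
  expect_equal(prod$length, a$length + b$length)
  cutA <- 700L + 60L; cutB <- 300L + 60L
  manual <- paste0(substr(a$seq, 1, cutA),
                   substr(b$seq, cutB + 1, b$length),
                   substr(b$seq, 1, cutB),
                   substr(a$seq, cutA + 1, a$length))
  expect_identical(prod$seq, manual)
})

test_that("digest counts fragments per topology and conserves length", {
  set.seed(12)
  repeat {   # backbone free of the motif on either strand
    seq <- random_test_dna(1000)
    if (!grepl("GGTCTC", seq) && !grepl("GAGACC", seq)) break
  }
  seq <- paste0(substr(seq, 1, 400), "GGTCTC", substr(seq, 407, 1000))
  lin <- molecule("lin", seq, circular = FALSE)
  expect_equal(as.integer(digest(lin, "GGTCTC")), c(600L, 400L))
  ## found identically via the opposite strand
  expect_equal(as.integer(digest(lin, reverse_complement("GGTCTC"))),
               c(600L, 400L))
  circ <- molecule("circ", seq, circular = TRUE)
  expect_equal(length(digest(circ, "GGTCTC")), 1L)
  expect_equal(sum(digest(circ, "GGTCTC")), 1000L)
  uncut <- digest(molecule("u", random_test_dna(800), circular = TRUE),
                  "GCGGCCGCAA")
  expect_equal(attr(uncut, "status"), "uncut_circular")
  expect_error(digest(lin, "ACG"), ">= 4")
})

test_that("PCR products require convergent primers within range", {
  set.seed(14)
  tpl <- random_test_dna(2000)
  fwd <- substr(tpl, 301, 320)
  rev <- reverse_complement(substr(tpl, 581, 600))
  lin <- molecule("t", tpl, circular = FALSE)
  expect_equal(pcr_predict(lin, fwd, rev), 300L)
  ## divergent (outward) primers on a linear template: nothing
  expect_length(pcr_predict(lin, rev, fwd), 0L)
  ## on a circular template the outward pair converges the long way round
  circ <- molecule("t", tpl, circular = TRUE)
  expect_equal(pcr_predict(circ, reverse_complement(rev),
                           reverse_complement(fwd), max_len = 5000L),
               2000L - 300L + 40L)
  expect_error(pcr_predict(lin, "ACGTACGT", rev), ">= 15")
})

test_that("integrated-element PCR is excision-dependent", {
  tk <- build_construct_map("TKV4", seed = 5)
  expect_length(pcr_predict(tk$mol, tk$primers$fwd, tk$primers$rev), 0L)
  ex <- site_recombine(tk$mol, "attL", "attR")
  lens <- vapply(ex$products, `[[`, 0L, "length")
  expect_equal(sum(lens), tk$mol$length)
  circ <- ex$products[[1]]
  expect_true(circ$circular)
  expect_equal(circ$length, tk$truth$circle_len)
  expect_equal(pcr_predict(circ, tk$primers$fwd, tk$primers$rev), 1710L)
})

test_that("molecule maps round-trip through JSON", {
  b <- build_construct_map("pMC479", seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_molecule(b$mol, f)
  back <- read_molecule(f)
  expect_identical(back$seq, b$mol$seq)
  expect_identical(back$circular, b$mol$circular)
  expect_equal(back$features$start, b$mol$features$start)
  expect_equal(back$features$core_end, b$mol$features$core_end)
})
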