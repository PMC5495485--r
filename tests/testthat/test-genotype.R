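test_that("error-free reads map uniquely at their true positions", {
  sim <- make_genome_with_repeats(20000, pair_specs = data.frame(
    core_len = 150L, orientation = "inverted"),
    min_separation = 3000L, seed = 81)
  rd <- simulate_reads(list(sim$genome), fractions = 1, coverage = 3,
                       read_len = 100L, err = 0, seed = 1)
  m <- map_reads(rd$reads, sim$genome)
  expect_equal(nrow(m), nrow(rd$reads))
  ## counts conserved across statuses
  expect_equal(sum(table(m$status)), nrow(rd$reads))
  mapped <- m$status == "mapped"
  truth_pos <- as.integer(read_meta(rd$reads$id, "pos"))
  expect_true(all(m$pos[mapped] == truth_pos[mapped]))
  ## reads wholly inside a two-copy exact repeat are ambiguous
  p <- sim$truth$pairs
  inside <- truth_pos >= p$a_start & truth_pos + 100L <= p$a_end |
    truth_pos >= p$b_start & truth_pos + 100L <= p$b_end
  expect_true(all(m$status[inside] == "ambiguous"))
  expect_true(all(m$status[!inside] == "mapped"))
})

test_that("the mapper agrees with a brute-force aligner on noisy reads", {
  set.seed(82)
  ref <- genome_record("r", random_test_dna(4000), circular = TRUE)
  rd <- simulate_reads(list(ref), fractions = 1, coverage = 3,
                       read_len = 100L, err = 0.01, seed = 2)
  m <- map_reads(rd$reads, ref)
  for (i in seq_len(nrow(rd$reads))) {
    o <- oracle_map_read(rd$reads$seq[i], ref$seq, circular = TRUE)
    if (o$best > 3L) {
      expect_equal(m$status[i], "unmapped")
    } else if (o$n_best > 1L) {
      expect_equal(m$status[i], "ambiguous")
    } else {
      expect_equal(m$status[i], "mapped")
      expect_equal(m$pos[i], o$pos)
      expect_equal(m$mismatches[i], o$best)
      expect_equal(m$strand[i], o$strand)
    }
  }
})

test_that("two-pass assignment sends junction reads to the derived pass", {
  specs <- data.frame(core_len = 104L, orientation = rep("inverted", 4))
  sim <- make_genome_with_repeats(30000, pair_specs = specs,
                                  min_separation = 2500L, seed = 301)
  h <- apply_truth_history(sim$genome, sim$truth, 2, seed = 2)
  ## pure ancestral reads: the derived pass is (nearly) empty
  rd_a <- simulate_reads(list(sim$genome), fractions = 1, coverage = 20,
                         read_len = 250L, err = 0.005, seed = 3)
  tp_a <- two_pass_assign(rd_a$reads, sim$genome, h$genome,
                          max_mismatch = 8L)
  expect_lt(tp_a$summary[["mapped_derived"]], 3L)
  expect_equal(sum(tp_a$summary[c("mapped_ancestral",
                                  "ambiguous_ancestral",
                                  "mapped_derived", "ambiguous_derived",
                                  "unmapped")]),
               tp_a$summary[["total"]])
  ## a read straddling a derived junction core fails pass 1, maps in pass 2
  j <- chromoflip::truth_junction_table(h$truth)[1, ]
  s <- j$junction - j$core_half - 40L
  jr <- data.frame(id = "jread",
                   seq = substr(h$genome$seq, s + 1, s + 250))
  tp_j <- two_pass_assign(jr, sim$genome, h$genome, max_mismatch = 8L)
  expect_equal(tp_j$pass1$status, "unmapped")
  expect_equal(tp_j$pass2$status, "mapped")
  expect_equal(tp_j$pass2$pos, s)
})

test_that("breakpoint classification recovers mixture fractions", {
  specs <- data.frame(core_len = 104L, orientation = rep("inverted", 4))
  sim <- make_genome_with_repeats(30000, pair_specs = specs,
                                  min_separation = 2500L, seed = 301)
  h <- apply_truth_history(sim$genome, sim$truth, 2, seed = 2)
  jt <- truth_junction_table(h$truth)
  diags <- make_site_diagnostics(sim$genome, h$genome, jt,
                                 read_len = 250L)
  expect_equal(nrow(diags), 8L)   # 2 positions x 4 junctions
  ## all-ancestral reads give fraction 0
  rd0 <- simulate_reads(list(sim$genome), fractions = 1, coverage = 40,
                        read_len = 250L, err = 0, seed = 4)
  tp0 <- two_pass_assign(rd0$reads, sim$genome, h$genome,
                         max_mismatch = 8L)
  est0 <- classify_breakpoint_reads(tp0, rd0$reads, diags)
  expect_true(all(est0$derived_fraction == 0))
  expect_true(all(est0$n_other == 0))
  ## 60/40 mixture: estimate within the Wilson interval of the read-label
  ## truth at every junction
  rd <- simulate_reads(list(sim$genome, h$genome),
                       fractions = c(0.4, 0.6), coverage = 100,
                       read_len = 250L, err = 0.01, seed = 5)
  tp <- two_pass_assign(rd$reads, sim$genome, h$genome, max_mismatch = 8L)
  est <- classify_breakpoint_reads(tp, rd$reads, diags)
  rc <- attr(est, "read_calls")
  for (b in est$breakpoint_id) {
    sub <- rc[rc$breakpoint_id == b & rc$call %in% c("ancestral",
                                                     "derived"), ]
    lab <- mean(read_meta(sub$read_id, "src") == h$genome$id)
    row <- est[est$breakpoint_id == b, ]
    expect_gte(lab, row$ci_lo)
    expect_lte(lab, row$ci_hi)
  }
  ## an uncovered diagnostic yields an explicit NA
  far <- diags
  far$anchor <- far$anchor + 29000L
  est_na <- classify_breakpoint_reads(tp, rd$reads,
                                      far[far$breakpoint_id == 1, ])
  expect_true(is.na(est_na$derived_fraction))
  expect_equal(est_na$n_informative, 0L)
})

test_that("sequencing errors at diagnostic positions land in the other
           column", {
  set.seed(85)
  anc <- genome_record("anc", random_test_dna(4000))
  der_seq <- anc$seq
  p <- 2000L
  alt <- setdiff(c("A", "C", "G", "T"), substr(der_seq, p + 1, p + 1))[1]
  substr(der_seq, p + 1, p + 1) <- alt
  der <- genome_record("der", der_seq)
  diags <- data.frame(breakpoint_id = 1L, junction = p, side = "left",
                      anchor = p - 50L, check_start = p - 50L,
                      check_bases = substr(anc$seq, p - 49L, p - 46L),
                      pos = p, base_anc = substr(anc$seq, p + 1, p + 1),
                      base_der = alt)
  third <- setdiff(c("A", "C", "G", "T"),
                   c(substr(anc$seq, p + 1, p + 1), alt))[1]
  rseq <- substr(anc$seq, p - 99L, p + 100L)   # 0-based [p-100, p+100)
  substr(rseq, 101L, 101L) <- third        # error base at the diagnostic
  reads <- data.frame(id = c("clean", "err"),
                      seq = c(substr(anc$seq, p - 99L, p + 100L), rseq))
  tp <- two_pass_assign(reads, anc, der, max_mismatch = 3L)
  est <- classify_breakpoint_reads(tp, reads, diags)
  expect_equal(est$n_ancestral, 1L)
  expect_equal(est$n_other, 1L)
  expect_equal(est$derived_fraction, 0)
})

test_that("depth ratios recover relative copy number", {
  set.seed(86)
  ## a region measured against itself has ratio exactly 1
  ref <- genome_record("c", random_test_dna(8000), circular = TRUE)
  rd <- simulate_reads(list(ref), fractions = 1, coverage = 30,
                       read_len = 100L, err = 0, seed = 7)
  al <- map_reads(rd$reads, ref)
  self <- depth_ratio(al, ref, 100L, target = c(1000L, 3000L),
                      mask = data.frame(start = c(0L, 3000L),
                                        end = c(1000L, 8000L)))
  expect_equal(self$ratio, 1.0)
  ## uniform coverage: any region vs the rest is ~1
  unif <- depth_ratio(al, ref, 100L, target = c(2000L, 4000L))
  expect_lt(abs(unif$ratio - 1), 0.1)
  ## integrated plasmid at 0.5 episomal copies per chromosome
  pl_seq <- random_test_dna(3000)
  chrom <- genome_record("chrom",
                         paste0(random_test_dna(6000), pl_seq,
                                random_test_dna(6000)), circular = TRUE)
  plasmid <- genome_record("pl", pl_seq, circular = TRUE)
  rd2 <- simulate_reads(list(chrom, plasmid), copies = c(1, 0.5),
                        coverage = 50, read_len = 100L, seed = 9)
  al2 <- map_reads(rd2$reads, chrom)
  dr <- depth_ratio(al2, chrom, 100L, target = c(6000L, 9000L),
                    mask = data.frame(start = 6000L, end = 9000L),
                    target_baseline_copies = 1)
  expect_gt(dr$copies_per_chromosome, 0.4)
  expect_lt(dr$copies_per_chromosome, 0.6)
  expect_error(depth_ratio(al2[0, ], chrom, 100L,
                           target = c(0L, 3000L)), "zero baseline")
})
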