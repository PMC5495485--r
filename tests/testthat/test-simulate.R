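test_that("genome generation is seed-deterministic and truth-consistent", {
  a <- make_genome_with_repeats(80000, min_separation = 8000L, seed = 91)
  b <- make_genome_with_repeats(80000, min_separation = 8000L, seed = 91)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth$pairs, b$truth$pairs)
  c <- make_genome_with_repeats(80000, min_separation = 8000L, seed = 92)
  expect_false(identical(a$genome$seq, c$genome$seq))
  ## planted copies verify: equal (direct) or reverse complements
  ## (inverted), and maximal shared segments are exactly the core length
  p <- a$truth$pairs
  for (r in seq_len(nrow(p))) {
    ca <- substr(a$genome$seq, p$a_start[r] + 1, p$a_end[r])
    cb <- substr(a$genome$seq, p$b_start[r] + 1, p$b_end[r])
    if (p$orientation[r] == "inverted") {
      expect_identical(cb, reverse_complement(ca))
    } else expect_identical(cb, ca)
    win <- 400L
    fa <- substr(a$genome$seq, p$a_start[r] + 1 - win, p$a_end[r] + win)
    fb <- substr(a$genome$seq, p$b_start[r] + 1 - win, p$b_end[r] + win)
    got <- longest_shared_segment(fa, fb, p$orientation[r])
    expect_equal(got$core_len, p$core_len[r])
  }
  expect_error(make_genome_with_repeats(
    30000, pair_specs = data.frame(core_len = rep(500L, 12),
                                   orientation = "inverted")),
    "packing|too large")
})

test_that("a genome without repeats compares to itself as a single block", {
  sim <- make_genome_with_repeats(
    40000, pair_specs = data.frame(core_len = integer(0),
                                   orientation = character(0))[0, ],
    seed = 93)
  expect_equal(nrow(sim$truth$pairs), 0L)
  cmp <- compare_genomes(sim$genome, sim$genome)
  expect_equal(cmp$permutation, 1L)
})

test_that("truth histories are minimal, junction-active and re-playable", {
  sim <- make_genome_with_repeats(150000, pair_specs = data.frame(
    core_len = c(104L, 176L, 284L, 620L, 150L, 400L),
    orientation = c(rep("inverted", 5), "direct")),
    min_separation = 9000L, seed = 94)
  h1 <- apply_truth_history(sim$genome, sim$truth, 1, seed = 1)
  cmp1 <- compare_genomes(sim$genome, h1$genome)
  expect_equal(nrow(cmp1$inversions), 1L)
  h4 <- apply_truth_history(sim$genome, sim$truth, 4, seed = 1)
  expect_equal(h4$truth$distance, 4L)
  expect_equal(nrow(h4$truth$events), 4L)
  expect_identical(
    apply_truth_history(sim$genome, sim$truth, 4, seed = 1)$genome$seq,
    h4$genome$seq)
  ## replaying the events through the timeline reproduces the genome
  tl <- repeat_orientation_timeline(sim$genome, sim$truth$pairs,
                                    h4$truth$events$pair)
  expect_identical(tl$genome$seq, h4$genome$seq)
})

test_that("an initially direct pair can become a substrate after an
           overlapping inversion", {
  ## hand-built geometry: an inverted pair spanning a direct pair's copy
  found <- FALSE
  for (s in 1:20) {
    sim <- make_genome_with_repeats(120000, pair_specs = data.frame(
      core_len = c(200L, 150L, 300L, 250L),
      orientation = c("inverted", "direct", "inverted", "direct")),
      min_separation = 9000L, seed = 600 + s)
    h <- try(apply_truth_history(sim$genome, sim$truth, 3, seed = s),
             silent = TRUE)
    if (inherits(h, "try-error")) next
    direct_used <- intersect(
      h$truth$used_pairs,
      sim$truth$pairs$pair[sim$truth$pairs$orientation == "direct"])
    if (length(direct_used) > 0L) {
      found <- TRUE
      ## the timeline must show it direct at step 0 and inverted when used
      tl <- repeat_orientation_timeline(sim$genome, sim$truth$pairs,
                                        h$truth$events$pair)
      col <- paste0("pair_", direct_used[1])
      step_used <- h$truth$events$step[h$truth$events$pair ==
                                         direct_used[1]]
      expect_equal(tl$timeline[[col]][1], "direct")
      expect_equal(tl$timeline[[col]][step_used], "inverted")
      break
    }
  }
  expect_true(found)
})

test_that("read simulation respects counts, determinism and the error
           model", {
  sim <- make_genome_with_repeats(20000, pair_specs = data.frame(
    core_len = c(120L, 200L), orientation = "inverted"),
    min_separation = 2500L, seed = 95)
  rd0 <- simulate_reads(list(sim$genome), fractions = 1, coverage = 5,
                        read_len = 100L, err = 0, seed = 11)
  expect_equal(nrow(rd0$reads), round(5 * 20000 / 100))
  ## error-free reads occur verbatim in the (circular) genome
  ext <- paste0(sim$genome$seq, substr(sim$genome$seq, 1, 100))
  ext_rc <- reverse_complement(ext)
  hit <- vapply(rd0$reads$seq, function(s)
    grepl(s, ext, fixed = TRUE) || grepl(s, ext_rc, fixed = TRUE), TRUE)
  expect_true(all(hit))
  expect_identical(
    simulate_reads(list(sim$genome), fractions = 1, coverage = 5,
                   read_len = 100L, err = 0, seed = 11)$reads,
    rd0$reads)
  ## fractions weight read counts
  rd <- simulate_reads(list(sim$genome, sim$genome),
                       fractions = c(0.3, 0.7), coverage = 10,
                       read_len = 100L, err = 0, seed = 12)
  expect_equal(as.integer(rd$truth$n_reads), c(600L, 1400L))
  ## substitution rate close to nominal
  rde <- simulate_reads(list(sim$genome), fractions = 1, coverage = 5,
                        read_len = 100L, err = 0.02, seed = 13)
  pos <- as.integer(read_meta(rde$reads$id, "pos"))
  strand <- read_meta(rde$reads$id, "strand")
  tpl <- substring(ext, pos + 1, pos + 100)
  neg <- strand == "-"
  tpl[neg] <- reverse_complement(tpl[neg])
  mm <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
               rde$reads$seq, tpl)
  rate <- sum(mm) / (100 * nrow(rde$reads))
  expect_gt(rate, 0.015); expect_lt(rate, 0.025)
  expect_error(simulate_reads(list(sim$genome), fractions = 1,
                              copies = 1), "exactly one")
})

test_that("construct builders satisfy their printed-size constraints", {
  b79 <- build_construct_map("pMC479", seed = 21)
  expect_equal(b79$mol$length, 4573L)
  expect_equal(as.integer(digest(b79$mol, "CATATG")), c(3207L, 1366L))
  b77 <- build_construct_map("pMC477", seed = 22)
  expect_equal(as.integer(digest(b77$mol, "CATATG")), c(2796L, 1777L))
  expect_error(build_construct_map("pMC477", seed = 1,
                                   pre_digest = c(4000L, 573L),
                                   post_digest = c(4001L, 572L)),
               "unsatisfiable|sum")
  tk <- build_construct_map("TKV4", seed = 23)
  expect_equal(tk$truth$circle_len, 5000L - 43L)
  ## determinism
  expect_identical(build_construct_map("pMC479", seed = 21)$mol$seq,
                   b79$mol$seq)
})

test_that("the neutral passage model conserves frequencies and responds to
           the inversion rate", {
  sim <- make_genome_with_repeats(100000, pair_specs = data.frame(
    core_len = c(104L, 176L, 284L), orientation = "inverted"),
    min_separation = 9000L, seed = 96)
  quiet <- simulate_passaging(sim$truth$pairs, inv_rate = 0,
                              generations = 12L, pop_size = 200L,
                              seed = 1)
  expect_equal(quiet$n_events, 0L)
  expect_true(all(vapply(split(quiet$trajectory$freq,
                               quiet$trajectory$generation), sum, 0) - 1 <
                    1e-9))
  expect_equal(unique(quiet$trajectory$state),
               quiet$trajectory$state[1])
  busy <- simulate_passaging(sim$truth$pairs, inv_rate = 0.01,
                             generations = 24L, pop_size = 200L, seed = 2)
  expect_gt(busy$n_events, 0L)
  expect_gt(length(busy$states), 1L)
  fr <- vapply(split(busy$trajectory$freq, busy$trajectory$generation),
               sum, 0)
  expect_true(all(abs(fr - 1) < 1e-9))
})
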