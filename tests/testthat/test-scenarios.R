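test_that("slice inversions reverse, sign-flip and self-invert", {
  expect_equal(apply_inversions(c(1L, 2L, 3L), cbind(2, 2)),
               c(1L, -2L, 3L))
  expect_equal(apply_inversions(c(1L, 2L, 3L),
                                rbind(c(2, 2), c(2, 2))), 1:3)
  expect_equal(apply_inversions(1:4, cbind(2, 4)), c(1L, -4L, -3L, -2L))
  expect_error(apply_inversions(1:3, cbind(2, 5)), "out of range")
})

test_that("unconstrained BFS distance matches exhaustive enumeration", {
  expect_equal(min_inversion_distance(1:4, 1:4), 0L)
  expect_equal(min_inversion_distance(1:3, c(1L, -2L, 3L)), 1L)
  ## one reversal of slice 2..3 flips both signs: distance 1, confirmed
  ## by the enumeration oracle
  expect_equal(min_inversion_distance(1:4, c(1L, -3L, -2L, 4L)),
               oracle_inv_distance(1:4, c(1L, -3L, -2L, 4L)))
  expect_equal(min_inversion_distance(1:4, c(1L, -3L, -2L, 4L)), 1L)
  expect_equal(min_inversion_distance(1:4, c(1L, 3L, -2L, 4L)), 2L)
  set.seed(13)
  for (i in 1:15) {
    n <- sample(3:5, 1)
    k <- sample(1:3, 1)
    der <- seq_len(n)
    for (e in seq_len(k)) {
      ij <- sort(sample(n, 2, replace = TRUE))
      der <- apply_inversions(der, cbind(ij[1], ij[2]))
    }
    d_bfs <- min_inversion_distance(seq_len(n), der)
    d_enum <- oracle_inv_distance(seq_len(n), der, max_d = 3L)
    expect_equal(d_bfs, d_enum)
    ## metric symmetry (relabel derived frame back to identity not needed:
    ## BFS works between arbitrary states)
    expect_equal(min_inversion_distance(der, seq_len(n)), d_bfs)
  }
  expect_error(min_inversion_distance(1:13, 13:1), "max_n")
  expect_error(min_inversion_distance(1:3, c(1L, 2L, 4L)), "universe")
})

test_that("minimal scenarios are enumerated, verified and canonical", {
  one <- enumerate_minimal_scenarios(1:3, c(1L, -2L, 3L))
  expect_equal(one$distance, 1L)
  expect_length(one$scenarios, 1L)
  expect_equal(one$scenarios[[1]][[1]], c(2L, 2L))
  ## two independent inversions commute: both orders enumerated
  two <- enumerate_minimal_scenarios(1:5, c(1L, -2L, 3L, -4L, 5L))
  expect_equal(two$distance, 2L)
  expect_length(two$scenarios, 2L)
  expect_false(two$truncated)
})

test_that("endpoint constraints restrict the move set", {
  ## one inverted pair around block 2: only (+1 -2 +3) is reachable
  pairs <- data.frame(pair = 1L, pos_a = 1L, pos_b = 2L,
                      strand_a = "+", strand_b = "-")
  expect_equal(min_inversion_distance(1:3, c(1L, -2L, 3L), pairs = pairs),
               1L)
  expect_equal(min_inversion_distance(1:3, c(-2L, -1L, 3L),
                                      pairs = pairs), Inf)
  ## a direct-orientation pair is no substrate (failed tRNA-Leu x tRNA-Thr
  ## analogue)
  direct <- data.frame(pair = 1L, pos_a = 1L, pos_b = 2L,
                       strand_a = "+", strand_b = "+")
  expect_equal(min_inversion_distance(1:3, c(1L, -2L, 3L),
                                      pairs = direct), Inf)
  ## constrained distance >= unconstrained distance
  set.seed(17)
  for (i in 1:10) {
    sim <- make_genome_with_repeats(
      150000, pair_specs = data.frame(core_len = c(104L, 176L, 284L,
                                                   620L, 150L, 400L),
                                      orientation = "inverted"),
      min_separation = 9000L, seed = 500 + i)
    h <- apply_truth_history(sim$genome, sim$truth,
                             n_events = sample(2:3, 1), seed = i)
    n <- 2L * length(h$truth$used_pairs) + 1L
    d_con <- h$truth$distance
    d_un <- min_inversion_distance(seq_len(n), h$truth$perm_derived)
    expect_gte(d_con, d_un)
  }
})

test_that("an inversion flips exactly the pairs with one copy in its span", {
  set.seed(19)
  for (i in 1:20) {
    np <- sample(3:6, 1)
    starts <- sort(sample(seq(1000, 90000, by = 100), 2L * np))
    pairs <- data.frame(pair = seq_len(np),
                        a_start = starts[seq(1, 2 * np, 2)],
                        b_start = starts[seq(2, 2 * np, 2)])
    pairs$a_end <- pairs$a_start + 100L; pairs$b_end <- pairs$b_start + 100L
    pairs$a_strand <- "+"
    pairs$b_strand <- sample(c("+", "-"), np, replace = TRUE)
    inv <- pairs$pair[pairs$a_strand != pairs$b_strand]
    if (length(inv) == 0L) next
    ev <- inv[sample.int(length(inv), 1)]
    upd <- chromoflip:::pair_inversion_coords(pairs, ev)
    for (r in seq_len(np)) {
      if (pairs$pair[r] == ev) next
      inside <- c(pairs$a_start[r] >= upd$m1 & pairs$a_end[r] <= upd$m2,
                  pairs$b_start[r] >= upd$m1 & pairs$b_end[r] <= upd$m2)
      before <- pairs$a_strand[r] == pairs$b_strand[r]
      after <- upd$pairs$a_strand[r] == upd$pairs$b_strand[r]
      if (sum(inside) == 1L) expect_false(before == after)
      else expect_true(before == after)
    }
  }
})

test_that("the orientation timeline matches sequence-level re-detection", {
  specs <- data.frame(core_len = c(150L, 200L, 120L),
                      orientation = c("inverted", "inverted", "direct"))
  sim <- make_genome_with_repeats(80000, pair_specs = specs,
                                  min_separation = 8000L, seed = 61)
  tl0 <- repeat_orientation_timeline(sim$genome, sim$truth$pairs,
                                     integer(0))
  expect_equal(tl0$timeline$pair_1, "inverted")
  expect_equal(tl0$timeline$pair_3, "direct")
  expect_identical(tl0$genome$seq, sim$genome$seq)

  h <- apply_truth_history(sim$genome, sim$truth, 2, seed = 3)
  tl <- repeat_orientation_timeline(sim$genome, sim$truth$pairs,
                                    h$truth$events$pair)
  expect_identical(tl$genome$seq, h$genome$seq)
  ## final orientations agree with direct sequence extraction
  fin <- tl$pairs
  for (r in seq_len(nrow(fin))) {
    a <- substr(tl$genome$seq, fin$a_start[r] + 1, fin$a_end[r])
    b <- substr(tl$genome$seq, fin$b_start[r] + 1, fin$b_end[r])
    expected_b <- if (fin$a_strand[r] == fin$b_strand[r]) a else
      reverse_complement(a)
    expect_identical(b, expected_b)
  }
  ## events only legal on inverted pairs
  direct_pairs <- sim$truth$pairs
  expect_error(invert_between_pair(sim$genome, direct_pairs, 3L),
               "direct orientation")
})

test_that("enumerated scenarios reach the derived genome at sequence level", {
  sim <- make_genome_with_repeats(
    150000, pair_specs = data.frame(core_len = c(104L, 176L, 284L, 620L,
                                                 150L, 400L),
                                    orientation = "inverted"),
    min_separation = 9000L, seed = 71)
  h <- apply_truth_history(sim$genome, sim$truth, 3, seed = 5)
  rec <- recover_history(sim$genome, h$genome)
  expect_equal(rec$distance, 3L)
  map <- match_pairs_to_truth(rec$repeat_pairs, sim$truth$pairs)
  expect_false(anyNA(map))
  for (sc in rec$scenarios[seq_len(min(3, length(rec$scenarios)))]) {
    tl <- repeat_orientation_timeline(sim$genome, sim$truth$pairs,
                                      map[unlist(sc)])
    cmp <- compare_genomes(tl$genome, h$genome)
    expect_equal(nrow(cmp$inversions), 0L)
  }
})
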