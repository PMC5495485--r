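#' Recover an inversion history between two genomes
#'
#' Runs the three comparative stages end to end: exact-match anchoring and
#' synteny blocks ([compare_genomes()]), breakpoint repeat forensics
#' ([characterize_breakpoints()]), and endpoint-constrained scenario
#' search ([min_inversion_distance()], [enumerate_minimal_scenarios()]).
#'
#' @param g1 ancestral [genome_record()].
#' @param g2 derived [genome_record()].
#' @param window forensics flank window (default 2000 bp).
#' @param min_core smallest repeat core usable as an inversion endpoint
#'   (default 100 bp, the smallest substrate active in vitro).
#' @param enumerate also enumerate minimal scenarios (default TRUE).
#' @param max_scenarios scenario cap (default 1000).
#' @param ... passed to [compare_genomes()].
#' @return list with `comparison` (stage 1), `repeat_pairs` (stage 2),
#'   `marker_pairs`, `distance` and `scenarios` (stage 3; scenario events
#'   are row indices into `repeat_pairs`).
#' @export
recover_history <- function(g1, g2, window = 2000L, min_core = 100L,
                            enumerate = TRUE, max_scenarios = 1000L, ...) {
  cmp <- compare_genomes(g1, g2, ...)
  rp <- characterize_breakpoints(g1, cmp$breakpoints, window = window,
                                 min_core = min_core)
  n <- nrow(cmp$blocks)
  if (nrow(rp) == 0L || n == 0L)
    return(list(comparison = cmp, repeat_pairs = rp, marker_pairs = NULL,
                distance = if (length(cmp$inversions) && nrow(cmp$inversions) == 0L) 0L else NA_integer_,
                scenarios = list()))
  mk <- ancestral_marker_table(cmp$blocks, rp)
  dist <- min_inversion_distance(seq_len(n), cmp$permutation, pairs = mk)
  sc <- if (enumerate && is.finite(dist))
    enumerate_minimal_scenarios(seq_len(n), cmp$permutation, pairs = mk,
                                max_scenarios = max_scenarios)
  else list(distance = dist, scenarios = list(), truncated = FALSE)
  list(comparison = cmp, repeat_pairs = rp, marker_pairs = mk,
       distance = dist, scenarios = sc$scenarios,
       truncated = sc$truncated)
}

#' Match recovered repeat pairs to a generator truth table
#'
#' @param repeat_pairs data.frame from [characterize_breakpoints()].
#' @param truth_pairs generator pair table (`truth$pairs`).
#' @param slack coordinate tolerance in bp (default 50).
#' @return integer vector: for each recovered pair, the matching truth
#'   `pair` id (NA if none).
#' @export
match_pairs_to_truth <- function(repeat_pairs, truth_pairs, slack = 50L) {
  vapply(seq_len(nrow(repeat_pairs)), function(r) {
    hits <- which(
      (abs(truth_pairs$a_start - repeat_pairs$a_start[r]) <= slack &
       abs(truth_pairs$b_start - repeat_pairs$b_start[r]) <= slack) |
      (abs(truth_pairs$a_start - repeat_pairs$b_start[r]) <= slack &
       abs(truth_pairs$b_start - repeat_pairs$a_start[r]) <= slack))
    if (length(hits) == 1L) truth_pairs$pair[hits] else NA_integer_
  }, 0L)
}
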