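#!/usr/bin/env Rscript
# Step 7 (illustrative): a neutral Wright-Fisher serial-passage model of
# inversion dynamics. Each generation every lineage can fire an inversion
# at each currently-invertible repeat pair; sequential 50-fold dilutions
# impose periodic bottlenecks. The per-pair rate is not calibrated to any
# organism; the model only illustrates that rearranged genomes can reach
# high frequency within ~60 generations under drift alone when inversions
# fire often enough, in a minority of replicates.
suppressMessages(library(chromoflip))
dir.create("results", showWarnings = FALSE)

specs <- data.frame(core_len = c(104L, 176L, 284L, 620L),
                    orientation = "inverted")
sim <- make_genome_with_repeats(150000, pair_specs = specs,
                                min_separation = 9000L, seed = 50)

reached <- 0L
for (rep in 1:5) {
  tr <- simulate_passaging(sim$truth$pairs, inv_rate = 0.005,
                           generations = 60L, dilution = 50L,
                           pop_size = 1000L, seed = rep)
  fin <- tr$trajectory[tr$trajectory$generation == 60L, ]
  anc_state <- tr$trajectory$state[1]
  top_derived <- max(c(0, fin$freq[fin$state != anc_state]))
  if (top_derived > 0.5) reached <- reached + 1L
  cat(sprintf("replicate %d: %d inversion events, %d states, top derived
state at %.2f after 60 generations\n", rep, tr$n_events,
              length(unique(fin$state)), top_derived))
  if (rep == 1L)
    write.table(tr$trajectory, "results/passage_trajectory.tsv",
                sep = "\t", row.names = FALSE, quote = FALSE)
}
cat(sprintf("a derived state reached majority in %d/5 replicates\n",
            reached))
cat("wrote results/passage_trajectory.tsv (replicate 1)\n")
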