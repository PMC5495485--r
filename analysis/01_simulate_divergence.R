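#!/usr/bin/env Rscript
# Step 1: simulate a laboratory-evolution experiment. An ancestral
# circular genome (200 kb) carries seven pairs of paralogous repeats with
# perfectly conserved cores of 104-620 bp (the sizes observed at natural
# inversion breakpoints), most in inverted orientation. A derived genome
# is produced by four sequential inversions, each bounded by a repeat
# pair that is in inverted orientation at the time of the event.
suppressMessages(library(chromoflip))
dir.create("results", showWarnings = FALSE)

specs <- data.frame(
  core_len = c(104L, 176L, 284L, 620L, 150L, 400L, 250L),
  orientation = c("inverted", "inverted", "inverted", "direct",
                  "inverted", "inverted", "direct"))
sim <- make_genome_with_repeats(200000, pair_specs = specs,
                                min_separation = 9000L, seed = 20170619)
hist <- apply_truth_history(sim$genome, sim$truth, n_events = 4,
                            seed = 66)

write_genome(sim$genome, "results/ancestral.fa")
write_genome(hist$genome, "results/derived.fa")
write.table(sim$truth$pairs, "results/truth_pairs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(hist$truth$events, "results/truth_events.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("ancestral genome: %d bp, %d repeat pairs\n",
            sim$genome$length, nrow(sim$truth$pairs)))
cat(sprintf("derived genome: %d inversions (pairs %s), constrained
minimal distance %d\n", nrow(hist$truth$events),
            paste(hist$truth$events$pair, collapse = ","),
            hist$truth$distance))
cat("wrote results/ancestral.fa, derived.fa, truth_pairs.tsv,",
    "truth_events.tsv\n")
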