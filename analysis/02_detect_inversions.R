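#!/usr/bin/env Rscript
# Step 2: whole-genome comparison of the ancestral and derived sequences
# (the dotplot stage). Exact-match anchors are chained into signed
# synteny blocks; the derived genome's block order gives a signed
# permutation, its non-conserved adjacencies give breakpoints, and
# maximal minus-runs give inversion segments with their bp spans.
suppressMessages(library(chromoflip))

anc <- load_genome("results/ancestral.fa", circular = TRUE)[[1]]
der <- load_genome("results/derived.fa", circular = TRUE)[[1]]
cmp <- compare_genomes(anc, der)

write.table(cmp$anchors, "results/anchors.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cmp$blocks, "results/blocks.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cmp$breakpoints, "results/breakpoints.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cmp$inversions, "results/inversions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
writeLines(paste(cmp$permutation, collapse = " "),
           "results/permutation.txt")

cat(sprintf("%d anchors -> %d blocks; permutation: %s\n",
            nrow(cmp$anchors), nrow(cmp$blocks),
            paste(cmp$permutation, collapse = " ")))
cat(sprintf("%d breakpoints; %d inversion segments (q-spans: %s kb)\n",
            nrow(cmp$breakpoints), nrow(cmp$inversions),
            paste(round(cmp$inversions$q_span / 1000, 1),
                  collapse = ", ")))
cat("coordinates are 0-based, half-open throughout\n")
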