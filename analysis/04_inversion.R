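#!/usr/bin/env Rscript
# Demarcate the planted inversion between the two chromosome versions:
# map the alternate against the reference, chain collinear synteny
# blocks, and call maximal reverse-orientation runs as inversions.
# Requires analysis/01_simulate.R to have run.

suppressMessages(library(parcensus))
say <- function(...) message("[04_inversion] ", ...)

pair <- read_fasta("scratch/sim/inversion_pair.fasta")
truth <- read_truth_json("results/sim/inversion_truth.json")

segs <- anchor_map(pair[["altX"]], pair[["refX"]],
                   query_id = "altX", target_id = "refX")
dotplot_points(segs, "results/inversion_dotplot.tsv")
blocks <- chain_blocks(segs)
utils::write.table(blocks, "results/synteny_blocks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
say(nrow(blocks), " synteny blocks (",
    sum(blocks$orientation == "-"), " reverse)")

inv <- detect_inversions(blocks)
utils::write.table(inv, "results/inversion_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_bed(data.frame(chrom = "refX", start = inv$ref_start,
                     end = inv$ref_end, name = "inversion"),
          "results/inversion_calls.bed")
for (i in seq_len(nrow(inv)))
  say("inversion ", i, ": [", inv$ref_start[i], ", ", inv$ref_end[i],
      "] size ", round(inv$size[i] / 1000), " kb, flanked ", inv$flanked[i],
      " (planted [", truth$inversion$start, ", ",
      truth$inversion$end, "])")
say("done")
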