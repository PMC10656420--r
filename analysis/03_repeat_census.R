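#!/usr/bin/env Rscript
# Census the simulated macrosatellite arrays and the ampliconic family:
# infer the monomer period, enumerate full/partial copies per scaffold,
# scan the CTCF word, relate full copies by identity and a
# neighbor-joining tree, and tier amplicon copies by identity.
# Requires analysis/01_simulate.R to have run.

suppressMessages(library(parcensus))
say <- function(...) message("[03_census] ", ...)
cfg <- pipeline_config()

arrays <- read_fasta("scratch/sim/dxz4_arrays.fasta")
monomer <- arrays[["monomer"]]

## monomer period from raw sequence --------------------------------------
im <- infer_monomer(arrays[["horseX_array"]], k = 21)
say("inferred monomer period: ", im$period, " bp (support ",
    round(im$support, 2), ")")

## per-scaffold census ---------------------------------------------------
targets <- arrays[c("horseX_array", "donkeyX_array", "donkey_scaf127")]
cen <- enumerate_copies(monomer, targets, cfg)
utils::write.table(cen$summary, "results/dxz4_census.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_bed(data.frame(chrom = cen$copies$target_id, start = cen$copies$start,
                     end = cen$copies$end, name = cen$copies$copy_class,
                     strand = cen$copies$strand),
          "results/dxz4_copies.bed")
for (i in seq_len(nrow(cen$summary)))
  say(cen$summary$target_id[i], ": ", cen$summary$n_full[i], " full + ",
      cen$summary$n_partial[i], " partial, span ",
      round(cen$summary$span[i] / 1000), " kb")
say("donkey full copies total: ",
    sum(cen$summary$n_full[cen$summary$target_id != "horseX_array"]))

## CTCF word in the monomer ----------------------------------------------
ctcf <- scan_motif(monomer, cfg$ctcf_motif, max_mismatch = 3)
say("CTCF motif hits in the monomer: ", nrow(ctcf))

## identity among full copies + NJ tree ----------------------------------
full <- cen$copies[cen$copies$copy_class == "full", ]
full <- full[order(full$target_id, full$start), ]
copy_seqs <- vapply(seq_len(nrow(full)), function(i)
  substr(targets[[full$target_id[i]]], full$start[i], full$end[i]),
  character(1))
names(copy_seqs) <- sprintf("%s_%02d", sub("_array|_scaf", "",
                                           full$target_id),
                            seq_len(nrow(full)))
# keep the comparison tractable: 8 horse-like + 8 donkey-like copies
pick <- c(grep("horse", names(copy_seqs), value = TRUE)[1:8],
          grep("donkey", names(copy_seqs), value = TRUE)[1:8])
pid <- pairwise_identity(copy_seqs[pick])
cross <- pid$identity[grep("horse", pick), grep("donkey", pick)]
say("mean cross-population full-copy identity: ",
    round(mean(cross), 1), "%")
tree <- nj_tree(pid$distance)
write_newick(tree, "results/dxz4_copies.nwk")
say("NJ tree of ", length(pick), " full copies written (unrooted)")

## amplicon census and tiers ---------------------------------------------
genome <- read_fasta("scratch/sim/amplicon_genome.fasta")
ref_amp <- read_fasta("scratch/sim/amplicon_ref.fasta")[[1]]
amp <- enumerate_copies(ref_amp, genome, cfg)
amp$copies <- tier_by_identity(amp$copies, cfg)
utils::write.table(amp$summary, "results/amplicon_census.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
dist_tab <- distribution_report(amp$copies, "results/amplicon_distribution.tsv")
tier_by_chrom <- table(amp$copies$target_id, amp$copies$tier)
print(tier_by_chrom)
say("X-linked copies are ", round(100 * mean(
  amp$copies$tier[amp$copies$target_id == "chrX_scaf"] == "high")),
  "% high-tier; autosomal copies are ", round(100 * mean(
  amp$copies$tier[amp$copies$target_id != "chrX_scaf"] == "low")),
  "% low-tier")
say("done")
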