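#!/usr/bin/env Rscript
# Build the synthetic study system used by the downstream analyses:
#   - an X/Y haplotype pair sharing a 100 kb PAR (99.9% identity) with a
#     PAB-spanning three-exon gene and a TATAWAW promoter word planted
#     35 bp upstream of exon3,
#   - male long reads (30x per haplotype, 10 kb, 1% error),
#   - macrosatellite-like tandem arrays: a "horse X" array (9 full + 2
#     partial copies of an 8 kb monomer) and a "donkey" pair of arrays
#     (8 full + 3 partial on the X; 12 full + 2 partial on a small
#     unplaced scaffold),
#   - an ampliconic family scattered over an X-like scaffold (high
#     identity tier) and three autosome-like scaffolds (low tier; 6, 26
#     and 14 copies),
#   - a 1.4 Mb chromosome carrying a 180 kb inversion (a 1:100 scale
#     analogue of an ~18 Mb pericentric inversion).
# Sequences go to scratch/sim/ (bulky), ground truth to results/sim/.

suppressMessages(library(parcensus))
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

say <- function(...) message("[01_simulate] ", ...)

## X/Y pair + male reads -------------------------------------------------
sim <- sim_config(par_len = 100000, x_specific_len = 150000,
                  y_specific_len = 150000, par_divergence = 0.001,
                  read_depth = 30, read_len_mean = 10000,
                  read_len_sd = 1000, read_err = 0.01, seed = 101)
pp <- make_par_pair(sim)
rd <- simulate_reads(c(X = pp$x_seq, Y = pp$y_seq), sim)
write_fasta(c(X = pp$x_seq, Y = pp$y_seq), "scratch/sim/xy_pair.fasta")
write_fasta(rd$reads, "scratch/sim/male_reads.fasta")
write_truth_json(pp$truth, "results/sim/xy_truth.json")
utils::write.table(rd$origins, "results/sim/read_origins.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
say("X/Y pair: PAB planted at ", pp$truth$pab_x, "; ",
    length(rd$reads), " male reads")

## tandem arrays ---------------------------------------------------------
# the CTCF binding word is planted three times per monomer, as in the
# macrosatellite this array emulates
ctcf_sites <- data.frame(motif = pipeline_config()$ctcf_motif,
                         offset = c(1000L, 3500L, 6200L))
horse <- make_tandem_array(8000, 9, c(0.5, 0.4), 0.01, seed = 102,
                           motif_placements = ctcf_sites, prefix_len = 5000)
donk1 <- make_tandem_array(8000, 8, c(0.5, 0.4, 0.3), 0.02, seed = 103,
                           monomer = horse$monomer, prefix_len = 5000)
donk2 <- make_tandem_array(8000, 12, c(0.5, 0.3), 0.02, seed = 104,
                           monomer = horse$monomer, prefix_len = 5000)
write_fasta(c(horseX_array = horse$seq, donkeyX_array = donk1$seq,
              donkey_scaf127 = donk2$seq, monomer = horse$monomer),
            "scratch/sim/dxz4_arrays.fasta")
write_truth_json(list(horseX = horse$truth, donkeyX = donk1$truth,
                      donkey_scaf127 = donk2$truth),
                 "results/sim/dxz4_truth.json")
say("arrays: horse 9+2, donkey 8+3 and 12+2 copies of an 8 kb monomer")

## amplicon family -------------------------------------------------------
backbones <- withr::with_seed(105, c(
  chrX_scaf = paste(sample(c("A", "C", "G", "T"), 1500000, TRUE), collapse = ""),
  chr2 = paste(sample(c("A", "C", "G", "T"), 400000, TRUE), collapse = ""),
  chr26 = paste(sample(c("A", "C", "G", "T"), 600000, TRUE), collapse = ""),
  chr31 = paste(sample(c("A", "C", "G", "T"), 400000, TRUE), collapse = "")))
ref_amp <- withr::with_seed(106,
  paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""))
placements <- data.frame(
  scaffold = c("chrX_scaf", "chrX_scaf", "chr2", "chr26", "chr31"),
  count = c(50, 10, 6, 26, 14),
  divergence = c(0.02, 0.02, 0.20, 0.20, 0.20),
  len_min = c(2800, 1200, 3000, 1500, 1500),
  len_max = c(3000, 2000, 3000, 3000, 3000),
  tier = c("high", "high", "low", "low", "low"))
amp <- scatter_amplicons(backbones, ref_amp, placements, seed = 107)
write_fasta(amp$genome, "scratch/sim/amplicon_genome.fasta")
write_fasta(c(ref_amp = ref_amp), "scratch/sim/amplicon_ref.fasta")
utils::write.table(amp$truth, "results/sim/amplicon_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
say("amplicons: ", nrow(amp$truth), " copies over ",
    length(unique(amp$truth$scaffold)), " scaffolds")

## inversion -------------------------------------------------------------
ref_chr <- withr::with_seed(108,
  paste(sample(c("A", "C", "G", "T"), 1400000, TRUE), collapse = ""))
alt_chr <- apply_inversion(ref_chr, 600001, 780000)
write_fasta(c(refX = ref_chr, altX = alt_chr), "scratch/sim/inversion_pair.fasta")
write_truth_json(list(inversion = list(start = 600001, end = 780000)),
                 "results/sim/inversion_truth.json")
say("inversion: 180 kb segment at [600001, 780000] of a 1.4 Mb chromosome")
say("done")
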