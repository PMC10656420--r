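#!/usr/bin/env Rscript
# Locate the pseudoautosomal boundary on the simulated X three ways and
# annotate the PAB-spanning gene:
#   1. homology transition: where idealized Y-source alignment stops but
#      X-source alignment continues,
#   2. read-depth changepoint: where male read coverage drops to ~50% of
#      the PAR-side baseline (step and auto model),
#   3. drop-off clustering: Y-origin reads whose X alignments end at a
#      common position.
# Then classify exon sex linkage and scan for the TATA box upstream of
# exon3. Requires analysis/01_simulate.R to have run.

suppressMessages(library(parcensus))
say <- function(...) message("[02_pab] ", ...)
cfg <- pipeline_config()

xy <- read_fasta("scratch/sim/xy_pair.fasta")
reads <- read_fasta("scratch/sim/male_reads.fasta")
truth <- read_truth_json("results/sim/xy_truth.json")

## 1. homology transition ------------------------------------------------
ysegs <- anchor_map(xy[["Y"]], xy[["X"]], k = cfg$k,
                    query_id = "Ysrc", target_id = "X")
xsegs <- anchor_map(xy[["X"]], xy[["X"]], k = cfg$k,
                    query_id = "Xsrc", target_id = "X")
hom <- call_pab_homology(ysegs, xsegs, nchar(xy[["X"]]), cfg)
say("homology transition PAB: ", hom$position,
    " (planted ", truth$pab_x, ")")

## 2. coverage changepoint -----------------------------------------------
idx <- kmer_index(xy[["X"]], k = cfg$k, max_occ = 100)
segs <- map_reads(reads, idx, primary_only = TRUE, target_id = "X")
trk <- depth_track(segs, nchar(xy[["X"]]), window = cfg$window)
write_depth_tsv(trk, "results/depth_track_X.tsv")
cov_step <- call_pab_coverage(trk, "step", cfg)
cov_auto <- call_pab_coverage(trk, "auto", cfg)
say("coverage step PAB: ", cov_step$position, "; post/pre depth ratio ",
    round(cov_step$ratio, 3), " (model chosen by auto: ", cov_auto$method, ")")

## 3. read drop-off clustering -------------------------------------------
drop <- cluster_dropoffs(segs, tol = 50, min_reads = 5,
                         target_len = nchar(xy[["X"]]))
say("drop-off clusters: ", nrow(drop), "; largest at ",
    if (nrow(drop)) drop$position[which.max(drop$n_reads)] else NA,
    " with ", if (nrow(drop)) max(drop$n_reads) else 0, " reads")

calls <- rbind(
  data.frame(method = hom$method, position = hom$position,
             ratio = NA_real_, status = hom$status),
  data.frame(method = cov_step$method, position = cov_step$position,
             ratio = cov_step$ratio, status = cov_step$status))
utils::write.table(calls, "results/pab_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_bed(data.frame(chrom = "X", start = calls$position,
                     end = calls$position, name = calls$method),
          "results/pab_calls.bed")

## exon sex linkage + promoter scan --------------------------------------
yidx <- kmer_index(xy[["Y"]], k = cfg$k)
exon_calls <- do.call(rbind, lapply(names(truth$exon_seqs), function(e) {
  es <- truth$exon_seqs[[e]]
  assign_exon_linkage(es,
                      anchor_map(es, idx, query_id = e, target_id = "X"),
                      anchor_map(es, yidx, query_id = e, target_id = "Y"),
                      exon_id = e)
}))
utils::write.table(exon_calls, "results/exon_linkage.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
say("exon linkage: ", paste(exon_calls$exon_id, exon_calls$label,
                            sep = "=", collapse = ", "))

exon3_start <- truth$exons$start[truth$exons$exon_id == "exon3"]
tata <- find_tata(xy[["X"]], exon3_start, window = 100,
                  motif = cfg$tata_motif)
utils::write.table(tata, "results/tata_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
say("TATA boxes upstream of exon3 at distances: ",
    paste(tata$distance_upstream, collapse = ", "))
say("done")
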