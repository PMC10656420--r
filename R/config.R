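#' Pipeline configuration shared by the boundary and census stages
#'
#' Holds the filtering and motif parameters used downstream of alignment:
#' the minimum alignment hit length retained in a census, the monomer
#' coverage defining a "full" repeat copy, the identity tiers separating
#' X-linked from autosomal amplicon copies, merge/flank distances for
#' homology-transition boundary calling, the depth-track window, the
#' anchor-aligner k-mer size, the core-promoter and CTCF motifs, and the
#' minimum log-likelihood gain for a depth changepoint call.
#'
#' @param min_hit_len Minimum retained alignment hit length (bases). Hits
#'   shorter than this are discarded before copy enumeration.
#' @param full_frac Monomer coverage fraction at or above which a repeat
#'   copy is classed `full` (below: `partial`).
#' @param tier_hi Identity (percent) at or above which a copy is tier
#'   `high`.
#' @param tier_lo Identity (percent) below which a copy is tier `low`;
#'   `[tier_lo, tier_hi)` is tier `mid`.
#' @param merge_gap Maximum gap (bases) bridged when merging homology
#'   segments of one source class into a block.
#' @param flank Minimum extent (bases) of X-source homology beyond a
#'   candidate boundary required to call it.
#' @param window Depth-track window size (bases).
#' @param k K-mer size of the built-in anchor aligner.
#' @param tata_motif IUPAC core-promoter motif.
#' @param ctcf_motif CTCF binding-domain sequence scanned in repeat
#'   monomers.
#' @param changepoint_min_delta_loglik Minimum log-likelihood improvement
#'   of the two-mean depth model over the single-mean null for a
#'   changepoint to be reported as called.
#' @param ramp_f_threshold F-like statistic above which the flat-linear-
#'   flat (ramp) depth model is preferred over the abrupt step when model
#'   selection is automatic.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_hit_len = 1000L,
                            full_frac = 0.9,
                            tier_hi = 90,
                            tier_lo = 85,
                            merge_gap = 5000L,
                            flank = 10000L,
                            window = 1000L,
                            k = 15L,
                            tata_motif = "TATAWAW",
                            ctcf_motif = "AGTTTCGCTTGATGGCAGTGTTGCACCACGAAT",
                            changepoint_min_delta_loglik = 10,
                            ramp_f_threshold = 20) {
  stopifnot(tier_lo < tier_hi,
            full_frac > 0, full_frac <= 1,
            min_hit_len > 0, merge_gap >= 0, flank >= 0,
            window > 0, k >= 3,
            changepoint_min_delta_loglik >= 0)
  ok_iupac <- function(m) grepl("^[ACGTRYSWKMBDHVN]+$", m)
  if (!ok_iupac(tata_motif) || !ok_iupac(ctcf_motif))
    stop("motifs must be IUPAC DNA strings")
  structure(list(min_hit_len = as.integer(min_hit_len),
                 full_frac = full_frac,
                 tier_hi = tier_hi, tier_lo = tier_lo,
                 merge_gap = as.integer(merge_gap),
                 flank = as.integer(flank),
                 window = as.integer(window),
                 k = as.integer(k),
                 tata_motif = tata_motif,
                 ctcf_motif = ctcf_motif,
                 changepoint_min_delta_loglik = changepoint_min_delta_loglik,
                 ramp_f_threshold = ramp_f_threshold),
            class = "pipeline_config")
}
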