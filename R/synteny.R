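#' Chain alignment segments into collinear synteny blocks
#'
#' Same-orientation segments that are collinear on both the reference
#' (target) and alternate (query) axes within `max_gap` are merged into
#' one block; blocks shorter than `min_block` on the reference are
#' dropped. Blocks are reported sorted by reference start and never
#' overlap on the reference axis.
#'
#' Segments shorter than `min_seg_len` are discarded first: chance k-mer
#' collisions between unrelated sequence produce sporadic few-anchor
#' chains tens of bases long, and bridging them across `max_gap` would
#' fabricate blocks.
#'
#' @param segments `segment_alignment` rows between one alternate (query)
#'   and one reference (target) sequence.
#' @param min_block Minimum block length on the reference (bases).
#' @param max_gap Maximum bridged gap on either axis (bases).
#' @param min_seg_len Minimum input segment length (bases).
#' @return Data frame of blocks: ref_start, ref_end, alt_start, alt_end,
#'   orientation, n_segments, identity (alignment-length-weighted mean).
#' @export
chain_blocks <- function(segments, min_block = 5000L, max_gap = 50000L,
                         min_seg_len = 100L) {
  segments <- segments[segments$aln_len >= min_seg_len, , drop = FALSE]
  if (!nrow(segments))
    return(data.frame(ref_start = integer(0), ref_end = integer(0),
                      alt_start = integer(0), alt_end = integer(0),
                      orientation = character(0), n_segments = integer(0),
                      identity = numeric(0)))
  if (length(unique(segments$target_id)) > 1 ||
      length(unique(segments$query_id)) > 1)
    stop("segments must involve a single reference and a single alternate")
  segs <- segments[order(segments$target_start), , drop = FALSE]
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(ref_start = cur$ref_start, ref_end = cur$ref_end,
               alt_start = cur$alt_start, alt_end = cur$alt_end,
               orientation = cur$orientation, n_segments = cur$n,
               identity = cur$id_sum / cur$len_sum,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    joined <- FALSE
    if (!is.null(cur) && s$strand == cur$orientation) {
      rgap <- s$target_start - cur$ref_end - 1L
      if (rgap <= max_gap) {
        # collinearity on the alternate axis depends on orientation
        if (s$strand == "+") {
          agap <- s$query_start - cur$alt_end - 1L
          ok <- agap <= max_gap && s$query_start > cur$alt_start
        } else {
          agap <- cur$alt_start - s$query_end - 1L
          ok <- agap <= max_gap && s$query_end < cur$alt_end
        }
        if (ok) {
          cur$ref_end <- max(cur$ref_end, s$target_end)
          cur$alt_start <- min(cur$alt_start, s$query_start)
          cur$alt_end <- max(cur$alt_end, s$query_end)
          cur$n <- cur$n + 1L
          cur$id_sum <- cur$id_sum + s$identity * s$aln_len
          cur$len_sum <- cur$len_sum + s$aln_len
          joined <- TRUE
        }
      }
    }
    if (!joined) {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur)
      cur <- list(ref_start = s$target_start, ref_end = s$target_end,
                  alt_start = s$query_start, alt_end = s$query_end,
                  orientation = s$strand, n = 1L,
                  id_sum = s$identity * s$aln_len, len_sum = s$aln_len)
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur)
  out <- do.call(rbind, blocks)
  out <- out[out$ref_end - out$ref_start + 1L >= min_block, , drop = FALSE]
  out <- out[order(out$ref_start), , drop = FALSE]
  # enforce non-overlap on the reference axis (anchor-resolution slack can
  # leave a few shared bases at block joints; trim the later block)
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      if (out$ref_start[i] <= out$ref_end[i - 1])
        out$ref_start[i] <- out$ref_end[i - 1] + 1L
    }
    out <- out[out$ref_start <= out$ref_end, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Demarcate inversions from orientation switches in synteny blocks
#'
#' A maximal run of reverse-orientation blocks bounds one inversion call:
#' the breakpoints are the run's outermost reference coordinates
#' (inclusive). Runs are split when consecutive reverse blocks are
#' separated by more than `max_gap` on the reference (an assembly gap up
#' to `max_gap`, e.g. a poorly assembled centromere inside a pericentric
#' inversion, stays within one call). `flanked` records whether forward
#' blocks exist on both sides of the run. Calls carry a `+-max_gap`
#' resolution bound inherited from block chaining.
#'
#' @param blocks Data frame from [chain_blocks()], sorted by ref_start.
#' @param min_inversion Minimum reported inversion size (bases).
#' @param max_gap Maximum within-run reference gap (bases).
#' @return Data frame: ref_start, ref_end, size, n_blocks, flanked.
#' @export
detect_inversions <- function(blocks, min_inversion = 10000L,
                              max_gap = 50000L) {
  empty <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      size = integer(0), n_blocks = integer(0),
                      flanked = character(0))
  if (!nrow(blocks)) return(empty)
  blocks <- blocks[order(blocks$ref_start), , drop = FALSE]
  neg <- which(blocks$orientation == "-")
  if (!length(neg)) return(empty)
  # split runs at intervening forward blocks or large reference gaps
  run_id <- cumsum(c(1L, (diff(neg) > 1L) |
                       (blocks$ref_start[neg[-1]] -
                          blocks$ref_end[neg[-length(neg)]] - 1L > max_gap)))
  calls <- lapply(split(neg, run_id), function(ix) {
    rs <- min(blocks$ref_start[ix]); re <- max(blocks$ref_end[ix])
    has_left <- any(blocks$orientation == "+" & blocks$ref_start < rs)
    has_right <- any(blocks$orientation == "+" & blocks$ref_end > re)
    data.frame(ref_start = rs, ref_end = re, size = re - rs + 1L,
               n_blocks = length(ix),
               flanked = if (has_left && has_right) "both" else "one_side",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[out$size >= min_inversion, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export dot-plot points for external plotting
#'
#' One row per alignment segment with its midpoints on both axes and
#' orientation — the minimal table a dot-plot renderer needs.
#'
#' @param segments `segment_alignment` rows.
#' @param path Optional TSV output path.
#' @export
dotplot_points <- function(segments, path = NULL) {
  df <- data.frame(ref_mid = (segments$target_start + segments$target_end) / 2,
                   alt_mid = (segments$query_start + segments$query_end) / 2,
                   orientation = segments$strand,
                   len = segments$aln_len)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
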