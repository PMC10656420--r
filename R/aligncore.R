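#' Construct a segment-alignment table
#'
#' The package's common currency for alignment evidence: one row per local
#' homology segment between a query and a target. Coordinates are 1-based
#' inclusive and ascending on both axes; strand `-` means the query's
#' reverse complement aligns to the target's forward strand.
#'
#' @param query_id,target_id Sequence identifiers.
#' @param query_start,query_end,target_start,target_end 1-based inclusive
#'   coordinates, start <= end.
#' @param strand `"+"` or `"-"`.
#' @param identity Percent identity in \[0, 100\].
#' @param matches Matching bases.
#' @param aln_len Alignment block length (bases).
#' @return A data frame of class `segment_alignment`.
#' @export
segments_df <- function(query_id = character(0), query_start = integer(0),
                        query_end = integer(0), target_id = character(0),
                        target_start = integer(0), target_end = integer(0),
                        strand = character(0), identity = numeric(0),
                        matches = integer(0), aln_len = integer(0)) {
  df <- data.frame(query_id = as.character(query_id),
                   query_start = as.integer(query_start),
                   query_end = as.integer(query_end),
                   target_id = as.character(target_id),
                   target_start = as.integer(target_start),
                   target_end = as.integer(target_end),
                   strand = as.character(strand),
                   identity = as.numeric(identity),
                   matches = as.integer(matches),
                   aln_len = as.integer(aln_len),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$query_start <= df$query_end),
              all(df$target_start <= df$target_end),
              all(df$strand %in% c("+", "-")),
              all(df$identity >= 0 & df$identity <= 100))
  }
  class(df) <- c("segment_alignment", "data.frame")
  df
}

#' Parse alignments from PAF or tabular BLAST (outfmt 6)
#'
#' PAF coordinates (0-based half-open) are converted to the internal
#' 1-based inclusive convention; BLAST6 rows with subject start > subject
#' end are normalized to ascending target coordinates with strand `-`.
#' Identity is preserved as reported by the producing tool (PAF: residue
#' matches / block length; BLAST6: the pident column).
#'
#' @param path Input file.
#' @param fmt `"PAF"` or `"BLAST6"`.
#' @return A `segment_alignment` data frame.
#' @export
parse_alignments <- function(path, fmt = c("PAF", "BLAST6")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(segments_df())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (fmt == "PAF") {
    bad <- which(lengths(fields) < 12)
    if (length(bad)) stop("malformed PAF row at line ", bad[1])
    m <- do.call(rbind, lapply(fields, `[`, 1:12))
    qs <- as.integer(m[, 3]); qe <- as.integer(m[, 4])
    ts <- as.integer(m[, 8]); te <- as.integer(m[, 9])
    nm <- as.integer(m[, 10]); bl <- as.integer(m[, 11])
    if (anyNA(qs) || anyNA(ts) || anyNA(nm) || anyNA(bl))
      stop("malformed PAF row at line ",
           which(is.na(qs) | is.na(ts) | is.na(nm) | is.na(bl))[1])
    segments_df(query_id = m[, 1],
                query_start = qs + 1L, query_end = qe,
                target_id = m[, 6],
                target_start = ts + 1L, target_end = te,
                strand = m[, 5],
                identity = 100 * nm / bl,
                matches = nm, aln_len = bl)
  } else {
    bad <- which(lengths(fields) < 12)
    if (length(bad)) stop("malformed BLAST6 row at line ", bad[1])
    m <- do.call(rbind, lapply(fields, `[`, 1:12))
    pid <- as.numeric(m[, 3]); alen <- as.integer(m[, 4])
    qs <- as.integer(m[, 7]); qe <- as.integer(m[, 8])
    ss <- as.integer(m[, 9]); se <- as.integer(m[, 10])
    if (anyNA(pid) || anyNA(qs) || anyNA(ss))
      stop("malformed BLAST6 row at line ",
           which(is.na(pid) | is.na(qs) | is.na(ss))[1])
    strand <- ifelse(ss <= se, "+", "-")
    segments_df(query_id = m[, 1],
                query_start = qs, query_end = qe,
                target_id = m[, 2],
                target_start = pmin(ss, se), target_end = pmax(ss, se),
                strand = strand,
                identity = pid,
                matches = as.integer(round(pid / 100 * alen)),
                aln_len = alen)
  }
}

#' Write segment alignments as PAF or BLAST6
#'
#' Inverse of [parse_alignments()]: internal 1-based inclusive coordinates
#' are converted back to each dialect's native convention (PAF 0-based
#' half-open; BLAST6 1-based with strand `-` encoded as descending subject
#' coordinates).
#'
#' @param segs A `segment_alignment` data frame.
#' @param path Output file.
#' @param fmt `"PAF"` or `"BLAST6"`.
#' @param query_lens,target_lens Optional named vectors of sequence
#'   lengths for the PAF length columns (default: the max end seen).
#' @export
write_alignments <- function(segs, path, fmt = c("PAF", "BLAST6"),
                             query_lens = NULL, target_lens = NULL) {
  fmt <- match.arg(fmt)
  if (!nrow(segs)) { writeLines(character(0), path); return(invisible(path)) }
  len_of <- function(ids, ends, table) {
    if (is.null(table)) {
      stats::ave(ends, ids, FUN = max)
    } else as.integer(table[ids])
  }
  if (fmt == "PAF") {
    out <- paste(segs$query_id,
                 len_of(segs$query_id, segs$query_end, query_lens),
                 segs$query_start - 1L, segs$query_end,
                 segs$strand,
                 segs$target_id,
                 len_of(segs$target_id, segs$target_end, target_lens),
                 segs$target_start - 1L, segs$target_end,
                 segs$matches, segs$aln_len, 60L,
                 sep = "\t")
  } else {
    ss <- ifelse(segs$strand == "+", segs$target_start, segs$target_end)
    se <- ifelse(segs$strand == "+", segs$target_end, segs$target_start)
    mism <- segs$aln_len - segs$matches
    out <- paste(segs$query_id, segs$target_id,
                 sprintf("%.3f", segs$identity), segs$aln_len,
                 mism, 0L,
                 segs$query_start, segs$query_end, ss, se,
                 "1e-100", 1000L,
                 sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Encode all k-mers of a sequence as numeric codes
#'
#' Base-4 rolling encoding; k <= 24 keeps codes exact in doubles.
#' Positions containing non-ACGT letters yield NA.
#' @keywords internal
kmer_codes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k")
  x <- utf8ToInt(seq)
  code <- integer(length(x))
  code[x == utf8ToInt("A")] <- 0L
  code[x == utf8ToInt("C")] <- 1L
  code[x == utf8ToInt("G")] <- 2L
  code[x == utf8ToInt("T")] <- 3L
  bad <- !(x %in% c(65L, 67L, 71L, 84L))  # A C G T
  v <- as.numeric(code)
  # rolling weighted sum over windows of k via filter (sides = 1)
  w <- 4^((k - 1):0)
  s <- stats::filter(v, w, sides = 1)
  out <- as.numeric(s)[k:n]
  if (any(bad)) {
    badpos <- which(bad)
    hit <- unique(unlist(lapply(badpos, function(p)
      max(1L, p - k + 1L):min(n - k + 1L, p))))
    out[hit] <- NA_real_
  }
  out
}

#' Build a k-mer index of a target sequence
#'
#' @param target DNA string.
#' @param k K-mer size.
#' @param max_occ K-mers occurring more than this many times in the target
#'   are masked as repeats for chaining (use `Inf` to keep all, e.g. when
#'   mapping a monomer against a tandem array).
#' @return An opaque index object for [anchor_map()].
#' @export
kmer_index <- function(target, k = 15L, max_occ = 100L) {
  codes <- kmer_codes(target, k)
  dt <- data.table::data.table(code = codes, tpos = seq_along(codes))
  dt <- dt[!is.na(code)]
  if (is.finite(max_occ)) {
    occ <- dt[, .N, by = code]
    keep <- occ[occ$N <= max_occ, ]$code
    dt <- dt[dt$code %in% keep, ]
  }
  data.table::setkey(dt, code)
  structure(list(dt = dt, k = as.integer(k), target_len = nchar(target)),
            class = "kmer_index")
}

# chain anchors (qpos, tpos) of one strand into segments.
# anchors within one target locality (gaps <= max_chain_gap) are split into
# diagonal bands (forward: tpos - qpos; reverse: tpos + qpos) and chained
# along the query axis; ties and ordering are deterministic.
chain_anchors <- function(qpos, tpos, strand, k, max_chain_gap, min_anchors,
                          qlen, diag_band = 100L) {
  if (!length(qpos)) return(NULL)
  o <- order(tpos, qpos)
  qpos <- qpos[o]; tpos <- tpos[o]
  tclust <- cumsum(c(1L, diff(tpos) > max_chain_gap))
  # within each target locality, band by diagonal, then split chains at
  # query gaps; all grouping is vectorized into one composite key
  diag <- if (strand == "+") tpos - qpos else tpos + qpos
  o2 <- order(tclust, diag, qpos)
  qpos <- qpos[o2]; tpos <- tpos[o2]
  tclust <- tclust[o2]; diag <- diag[o2]
  band <- cumsum(c(1L, diff(diag) > diag_band | diff(tclust) != 0))
  o3 <- order(band, qpos)
  qpos <- qpos[o3]; tpos <- tpos[o3]; band <- band[o3]
  chain <- cumsum(c(1L, diff(qpos) > max_chain_gap | diff(band) != 0))
  dt <- data.table::data.table(qpos = qpos, tpos = tpos, chain = chain)
  agg <- dt[, list(qs = min(qpos), qe = max(qpos) + k - 1L,
                   ts = min(tpos), te = max(tpos) + k - 1L,
                   n = .N), by = "chain"]
  agg <- agg[agg$n >= min_anchors, ]
  if (!nrow(agg)) return(NULL)
  span <- agg$qe - agg$qs + 1L
  frac <- agg$n / (span - k + 1L)
  id_est <- pmin(100, 100 * frac^(1 / k))
  qs <- agg$qs; qe <- agg$qe
  if (strand == "-") {
    # map query coordinates back to the original (forward) read
    qs <- qlen - agg$qe + 1L
    qe <- qlen - agg$qs + 1L
  }
  data.frame(query_start = qs, query_end = qe,
             target_start = agg$ts, target_end = agg$te,
             strand = strand, identity = id_est,
             matches = as.integer(round(id_est / 100 * span)),
             aln_len = span, n_anchors = agg$n)
}

#' Map a query against a target with k-mer anchor chaining
#'
#' A light-weight aligner sufficient for substitution-diverged synthetic
#' sequence (documented limit: ~10 percent divergence; no affine-gap
#' extension). Exact shared k-mers are anchors; per strand, anchors in one
#' target locality and diagonal band are chained when successive query
#' gaps do not exceed `max_chain_gap`. Identity is estimated from anchor
#' density as `100 * f^(1/k)` with `f` the anchored fraction of the query
#' span. Chains are reported sorted by target start (leftmost first).
#'
#' @param query DNA string.
#' @param target DNA string, or a prebuilt [kmer_index()] (recommended
#'   when mapping many reads against one target).
#' @param k K-mer size (ignored when `target` is an index).
#' @param max_chain_gap Maximum anchor gap (bases) within one chain.
#' @param min_anchors Minimum anchors per reported segment.
#' @param max_occ Repeat-masking threshold for target k-mers.
#' @param query_id,target_id Identifiers stamped on the output rows.
#' @return A `segment_alignment` data frame.
#' @export
anchor_map <- function(query, target, k = 15L, max_chain_gap = 1000L,
                       min_anchors = 3L, max_occ = 100L,
                       query_id = "query", target_id = "target") {
  if (inherits(target, "kmer_index")) {
    idx <- target
  } else {
    if (nchar(target) < k) stop("target shorter than k")
    idx <- kmer_index(target, k = k, max_occ = max_occ)
  }
  k <- idx$k
  if (nchar(query) < k) stop("query shorter than k")
  qlen <- nchar(query)
  segs <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") query else revcomp(query)
    qc <- kmer_codes(qseq, k)
    qdt <- data.table::data.table(code = qc, qpos = seq_along(qc))
    qdt <- qdt[!is.na(code)]
    hits <- idx$dt[qdt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
    s <- chain_anchors(hits$qpos, hits$tpos, strand, k,
                       max_chain_gap, min_anchors, qlen)
    if (!is.null(s)) segs[[strand]] <- s
  }
  if (!length(segs)) return(segments_df())
  out <- do.call(rbind, segs)
  out <- out[order(out$target_start, out$target_end), , drop = FALSE]
  segments_df(query_id = query_id, query_start = out$query_start,
              query_end = out$query_end, target_id = target_id,
              target_start = out$target_start, target_end = out$target_end,
              strand = out$strand, identity = out$identity,
              matches = out$matches, aln_len = out$aln_len)
}

#' Map many reads against one target, keeping primary hits
#'
#' Builds the target index once and maps each read with [anchor_map()].
#' With `primary_only = TRUE` (default) only the best-scoring segment
#' (most matches) per read is kept, mirroring a primary-alignment filter:
#' pseudoautosomal reads from either haplotype then contribute one depth
#' count each.
#'
#' @param reads Named character vector of read sequences.
#' @param target DNA string or [kmer_index()].
#' @param k,max_chain_gap,min_anchors,max_occ As in [anchor_map()].
#' @param primary_only Keep only the top segment per read.
#' @param target_id Identifier for the target.
#' @return A `segment_alignment` data frame.
#' @export
map_reads <- function(reads, target, k = 15L, max_chain_gap = 1000L,
                      min_anchors = 3L, max_occ = 100L, primary_only = TRUE,
                      target_id = "target") {
  if (!inherits(target, "kmer_index"))
    target <- kmer_index(target, k = k, max_occ = max_occ)
  out <- vector("list", length(reads))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  for (i in seq_along(reads)) {
    s <- anchor_map(reads[[i]], target, max_chain_gap = max_chain_gap,
                    min_anchors = min_anchors, query_id = ids[i],
                    target_id = target_id)
    if (!nrow(s)) next
    if (primary_only) s <- s[which.max(s$matches), , drop = FALSE]
    out[[i]] <- s
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(segments_df())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("segment_alignment", "data.frame")
  res
}

#' Windowed read-depth track over a target
#'
#' `depth[w]` is the total overlap of the segments with window `w` divided
#' by the window size, so that `sum(window * depth)` equals the total
#' aligned bases (mass conservation; the last window uses the same divisor
#' even if truncated by the target end).
#'
#' @param read_segments `segment_alignment` rows, all on one target.
#' @param target_len Target length (bases).
#' @param window Window size (bases).
#' @return A list of class `coverage_track` with `target_id`, `window`,
#'   `depth` (numeric vector of length `ceiling(target_len / window)`).
#' @export
depth_track <- function(read_segments, target_len, window = 1000L) {
  stopifnot(window > 0, target_len > 0)
  nw <- ceiling(target_len / window)
  tid <- if (nrow(read_segments)) read_segments$target_id[1] else NA_character_
  if (nrow(read_segments)) {
    if (length(unique(read_segments$target_id)) > 1)
      stop("segments span multiple targets")
    if (any(read_segments$target_end > target_len))
      stop("segment exceeds target length")
    cov <- IRanges::coverage(
      IRanges::IRanges(read_segments$target_start, read_segments$target_end),
      width = target_len)
    starts <- seq.int(1L, by = window, length.out = nw)
    ends <- pmin(starts + window - 1L, target_len)
    sums <- IRanges::viewSums(IRanges::Views(cov, start = starts, end = ends))
    depth <- as.numeric(sums) / window
  } else {
    depth <- numeric(nw)
  }
  structure(list(target_id = tid, window = as.integer(window), depth = depth,
                 target_len = as.integer(target_len)),
            class = "coverage_track")
}

#' Write a coverage track as TSV
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_depth_tsv <- function(track, path) {
  n <- length(track$depth)
  df <- data.frame(target_id = track$target_id,
                   start = seq.int(1L, by = track$window, length.out = n),
                   end = pmin(seq.int(track$window, by = track$window,
                                      length.out = n), track$target_len),
                   depth = track$depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
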