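#' Infer the tandem-repeat monomer period by k-mer recurrence
#'
#' Every k-mer occurring more than once contributes the distances between
#' its consecutive occurrences; distances within `[min_period,
#' max_period]` are histogrammed in 100-bp bins and the modal bin center
#' is the period, provided the mode carries at least 20 percent of the
#' recurrence distances (otherwise the region is reported as not tandem).
#' The representative copy is the first window of one period starting at
#' the earliest recurrent k-mer.
#'
#' @param region_seq DNA string (length >= 2 * min_period).
#' @param k K-mer size.
#' @param min_period,max_period Period search range (bases).
#' @param min_support Minimal fraction of recurrence distances in the
#'   modal bin.
#' @return A list: `status` ("tandem" or "not_tandem"), `period` (bases),
#'   `representative` (c(start, end)), `support` (modal fraction).
#' @export
infer_monomer <- function(region_seq, k = 21L, min_period = 1000L,
                          max_period = 20000L, min_support = 0.2) {
  if (nchar(region_seq) < 2 * min_period)
    stop("region shorter than twice min_period")
  codes <- kmer_codes(region_seq, k)
  dt <- data.table::data.table(code = codes, pos = seq_along(codes))
  dt <- dt[!is.na(code)]
  data.table::setorder(dt, code, pos)
  gaps <- dt[, list(d = diff(pos), p = pos[-.N]), by = "code"]
  gaps <- gaps[gaps$d >= min_period & gaps$d <= max_period, ]
  not_tandem <- list(status = "not_tandem", period = NA_integer_,
                     representative = NULL, support = 0)
  if (!nrow(gaps)) return(not_tandem)
  bin <- floor(gaps$d / 100)
  tab <- table(bin)
  mode_bin <- as.integer(names(tab)[which.max(tab)])
  support <- max(tab) / nrow(gaps)
  if (support < min_support) return(not_tandem)
  # refine: mean distance within the modal bin (center of mass beats the
  # coarse bin center)
  in_mode <- floor(gaps$d / 100) == mode_bin
  period <- as.integer(round(mean(gaps$d[in_mode])))
  rep_start <- min(gaps$p[in_mode])
  list(status = "tandem", period = period,
       representative = c(start = rep_start,
                          end = min(rep_start + period - 1L, nchar(region_seq))),
       support = unname(support))
}

# merge same-strand segments into copies: hits separated by <= chain_gap
# on the target with compatible monomer (query) coordinates become one
# copy. Compatibility: the query gap direction matches the strand and the
# implied indel is small.
merge_copy_hits <- function(segs, chain_gap = 100L) {
  if (nrow(segs) <= 1) return(segs)
  segs <- segs[order(segs$target_start), , drop = FALSE]
  out <- list()
  cur <- segs[1, ]
  for (i in 2:nrow(segs)) {
    s <- segs[i, ]
    tgap <- s$target_start - cur$target_end - 1L
    compatible <- FALSE
    if (s$strand == cur$strand && tgap <= chain_gap && tgap > -cur$aln_len) {
      qgap <- if (s$strand == "+") s$query_start - cur$query_end - 1L
      else cur$query_start - s$query_end - 1L
      compatible <- abs(qgap - tgap) <= chain_gap && qgap > -chain_gap
    }
    if (compatible) {
      cur$target_end <- max(cur$target_end, s$target_end)
      cur$query_start <- min(cur$query_start, s$query_start)
      cur$query_end <- max(cur$query_end, s$query_end)
      cur$matches <- cur$matches + s$matches
      cur$aln_len <- cur$aln_len + s$aln_len
      cur$identity <- 100 * cur$matches / cur$aln_len
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- s
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

#' Enumerate monomer copies across target scaffolds
#'
#' Aligns the monomer to both strands of every target (built-in anchor
#' aligner, no repeat masking since the query is an explicit monomer),
#' discards hits shorter than `min_hit_len`, chains same-strand hits with
#' compatible monomer coordinates separated by at most 100 bases into one
#' copy, and classifies copies as full when the aligned monomer fraction
#' reaches `full_frac`. Per-target array summaries cluster copies
#' separated by at most `span_gap` and report the span of the largest
#' cluster.
#'
#' @param monomer Monomer sequence (length >= `min_hit_len`).
#' @param targets Named character vector of target sequences, or a
#'   precomputed `segment_alignment` table via `hits`.
#' @param cfg A [pipeline_config()].
#' @param hits Optional precomputed hits (e.g. parsed BLAST6) with the
#'   monomer as query; when given, `targets` may be a named vector of
#'   target lengths instead of sequences.
#' @param span_gap Clustering gap for array span (bases).
#' @return A list with `copies` (data frame: target_id, start, end,
#'   strand, identity, monomer_cov, copy_class) and `summary` (per-target:
#'   n_full, n_partial, span).
#' @export
enumerate_copies <- function(monomer, targets, cfg = pipeline_config(),
                             hits = NULL, span_gap = 50000L) {
  mono_len <- nchar(monomer)
  if (mono_len < cfg$min_hit_len)
    stop("monomer shorter than min_hit_len")
  if (is.null(hits)) {
    if (!length(targets)) stop("empty target set")
    stopifnot(!is.null(names(targets)))
    hit_list <- lapply(names(targets), function(tn) {
      anchor_map(monomer, targets[[tn]], k = cfg$k,
                 max_chain_gap = 1000L, min_anchors = 3L, max_occ = Inf,
                 query_id = "monomer", target_id = tn)
    })
    hits <- do.call(rbind, hit_list)
  }
  copies <- list()
  if (nrow(hits)) {
    for (tn in unique(hits$target_id)) {
      h <- hits[hits$target_id == tn, , drop = FALSE]
      h <- merge_copy_hits(h, chain_gap = 100L)
      h <- h[h$target_end - h$target_start + 1L >= cfg$min_hit_len, ,
             drop = FALSE]
      if (!nrow(h)) next
      # resolve residual boundary overlaps between adjacent copies
      h <- h[order(h$target_start), , drop = FALSE]
      if (nrow(h) > 1) {
        for (ii in 2:nrow(h)) {
          if (h$target_start[ii] <= h$target_end[ii - 1])
            h$target_start[ii] <- h$target_end[ii - 1] + 1L
        }
        h <- h[h$target_start <= h$target_end, , drop = FALSE]
      }
      cov <- pmin(1, (h$query_end - h$query_start + 1L) / mono_len)
      copies[[tn]] <- data.frame(
        target_id = tn, start = h$target_start, end = h$target_end,
        strand = h$strand, identity = h$identity, monomer_cov = cov,
        copy_class = ifelse(cov >= cfg$full_frac, "full", "partial"),
        stringsAsFactors = FALSE)
    }
  }
  copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(target_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), identity = numeric(0),
               monomer_cov = numeric(0), copy_class = character(0))
  rownames(copies) <- NULL
  summ <- lapply(split(copies, copies$target_id), function(cc) {
    cc <- cc[order(cc$start), , drop = FALSE]
    cl <- cumsum(c(1L, diff(cc$start) > span_gap))
    spans <- vapply(split(seq_len(nrow(cc)), cl), function(ix)
      max(cc$end[ix]) - min(cc$start[ix]) + 1L, numeric(1))
    data.frame(target_id = cc$target_id[1],
               n_full = sum(cc$copy_class == "full"),
               n_partial = sum(cc$copy_class == "partial"),
               span = as.integer(max(spans)), stringsAsFactors = FALSE)
  })
  summ <- if (length(summ)) do.call(rbind, summ) else
    data.frame(target_id = character(0), n_full = integer(0),
               n_partial = integer(0), span = integer(0))
  rownames(summ) <- NULL
  list(copies = copies, summary = summ)
}

#' Label repeat copies by identity tier
#'
#' `high`: identity >= `tier_hi`; `mid`: in `[tier_lo, tier_hi)`; `low`:
#' below `tier_lo`. The high/low split mirrors the distinction between
#' X-linked copies (> 90 percent to the X reference) and autosomal copies
#' (< 85 percent).
#'
#' @param copies Data frame with an `identity` column.
#' @param cfg A [pipeline_config()].
#' @return `copies` with a `tier` column appended.
#' @export
tier_by_identity <- function(copies, cfg = pipeline_config()) {
  copies$tier <- ifelse(copies$identity >= cfg$tier_hi, "high",
                        ifelse(copies$identity >= cfg$tier_lo, "mid", "low"))
  copies
}

#' Scan a sequence for an IUPAC motif with mismatches
#'
#' Reports every position where the motif matches under IUPAC semantics
#' with at most `max_mismatch` mismatches, on the forward and (optionally)
#' reverse strand, sorted by position. A reverse-strand hit at position p
#' means the motif's reverse complement occurs at p on the forward
#' sequence.
#'
#' @param seq DNA string.
#' @param motif_iupac IUPAC motif.
#' @param max_mismatch Maximum mismatches.
#' @param both_strands Scan the reverse strand too.
#' @return Data frame with `start`, `end`, `strand`, `mismatches`.
#' @export
scan_motif <- function(seq, motif_iupac, max_mismatch = 0L,
                       both_strands = TRUE) {
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif_iupac))
    stop("invalid IUPAC letter in motif")
  if (nchar(motif_iupac) > nchar(seq))
    stop("motif longer than sequence")
  subj <- Biostrings::DNAString(seq)
  scan1 <- function(m, strand) {
    hits <- Biostrings::matchPattern(m, subj, max.mismatch = max_mismatch,
                                     fixed = FALSE)
    # with mismatches allowed, matches overhanging the sequence ends are
    # reported too; only fully contained windows count
    hits <- hits[IRanges::start(hits) >= 1 &
                   IRanges::end(hits) <= length(subj)]
    if (!length(hits)) return(NULL)
    mm <- vapply(seq_along(hits), function(i)
      Biostrings::neditAt(m, subj, at = IRanges::start(hits)[i],
                          fixed = FALSE), integer(1))
    data.frame(start = IRanges::start(hits), end = IRanges::end(hits),
               strand = strand, mismatches = mm, stringsAsFactors = FALSE)
  }
  out <- scan1(motif_iupac, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif_iupac)))
    if (rc != motif_iupac) {
      out <- rbind(out, scan1(rc, "-"))
    } else if (!is.null(out)) {
      # palindromic motif: forward hits are also reverse hits
      rev_hits <- out; rev_hits$strand <- "-"
      out <- rbind(out, rev_hits)
    }
  }
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise identity matrix from global alignments
#'
#' Identity between two sequences is `matches / alignment columns` of an
#' optimal global (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' gap -2 (linear); gap columns count as non-matching columns. The
#' distance is `1 - identity / 100`.
#'
#' @param seqs Named character vector of sequences (each <= 20 kb).
#' @return A list with `identity` and `distance` (symmetric matrices,
#'   zero diagonal on `distance`).
#' @export
pairwise_identity <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  if (any(nchar(seqs) == 0)) stop("empty sequence")
  if (any(nchar(seqs) > 20000)) stop("sequence longer than 20 kb")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  idm <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(seqs[[j]]),
        type = "global", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2)
      a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      id <- 100 * sum(a == b) / length(a)
      idm[i, j] <- idm[j, i] <- id
    }
  }
  list(identity = idm, distance = 1 - idm / 100)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing
#' the Q criterion is joined; ties are broken by the lowest label-index
#' pair for determinism; negative branch lengths are clamped to zero. The
#' result is an unrooted `phylo` object (no outgroup, not midpoint
#' rooted).
#'
#' @param D Symmetric distance matrix with labels, >= 3 taxa.
#' @return An [ape::ape-package] `phylo` object.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels  # Newick fragment per active cluster, order-stable
  d <- D
  fmt <- function(x) sprintf("%.12g", max(0, x))
  while (length(frag) > 3) {
    m <- length(frag)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    others <- setdiff(seq_len(m), c(i, j))
    newd <- 0.5 * (d[i, others] + d[j, others] - d[i, j])
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, newd), c(newd, 0))
    frag <- c(frag[others], newfrag)
  }
  # final trifurcation via the three-point formulas (unrooted output)
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                ",", frag[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a copy-distribution table for ideogram plotting
#'
#' One row per copy: chromosome, position, copy class and identity tier,
#' sorted by chromosome then position — the layout consumed by
#' ideogram/phenogram-style plotting tools.
#'
#' @param copies Data frame from [enumerate_copies()] (tiered via
#'   [tier_by_identity()]).
#' @param path Output TSV path.
#' @return The table (invisibly written to `path` if given).
#' @export
distribution_report <- function(copies, path = NULL) {
  df <- data.frame(chrom = copies$target_id,
                   pos = copies$start,
                   class = copies$copy_class,
                   tier = if (!is.null(copies$tier)) copies$tier else
                     rep(NA_character_, nrow(copies)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
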