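# Independent oracles and tiny fixture builders used across the suite.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = ""))
  } else {
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  }
}

# base-wise mismatch count between equal-length strings
bf_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# brute-force sliding-window IUPAC motif scan with mismatches
bf_motif_scan <- function(seq, motif, max_mismatch = 0, both_strands = TRUE) {
  scan1 <- function(m, strand) {
    mv <- strsplit(m, "")[[1]]
    sv <- strsplit(seq, "")[[1]]
    L <- length(mv); n <- length(sv)
    hits <- list()
    for (s in seq_len(n - L + 1)) {
      mm <- 0L
      for (j in seq_len(L)) {
        if (!(sv[s + j - 1] %in% IUPAC_SETS[[mv[j]]])) mm <- mm + 1L
      }
      if (mm <= max_mismatch)
        hits[[length(hits) + 1L]] <- data.frame(start = s, end = s + L - 1L,
                                                strand = strand,
                                                mismatches = mm)
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  out <- scan1(motif, "+")
  if (both_strands) out <- rbind(out, scan1(parcensus::revcomp(motif), "-"))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force Poisson changepoint scan: plain double loop, no shared code
# with the implementation
bf_step_changepoint <- function(y) {
  n <- length(y)
  ll_of <- function(v) {
    m <- mean(v)
    if (m == 0) return(0)
    sum(ifelse(v > 0, v * log(m), 0)) - length(v) * m
  }
  ll0 <- ll_of(y)
  best_b <- NA_integer_; best_delta <- -Inf
  for (b in 1:(n - 1)) {
    delta <- ll_of(y[1:b]) + ll_of(y[(b + 1):n]) - ll0
    if (delta > best_delta + 1e-12) { best_delta <- delta; best_b <- b }
  }
  list(breakpoint = best_b, delta_loglik = best_delta)
}

# fragment an interval [1, hi] into noiseless alignment segments with
# inter-fragment gaps, as idealized BAC/assembly alignment evidence
fragment_segments <- function(hi, target_id, query_id, frag = 20000L,
                              gap = 1000L, jitter = 0L, lo = 1L) {
  starts <- seq(lo, hi, by = frag + gap)
  # avoid a terminal sliver shorter than typical length filters: fold it
  # into the previous fragment
  if (length(starts) > 1 && hi - starts[length(starts)] < 2000L)
    starts <- starts[-length(starts)]
  ends <- pmin(starts + frag - 1L, hi)
  ends[length(ends)] <- hi
  if (jitter > 0) {
    starts <- pmax(lo, starts + sample(-jitter:jitter, length(starts), TRUE))
    ends <- pmin(hi, pmax(starts + 100L, ends + sample(-jitter:jitter,
                                                       length(ends), TRUE)))
  }
  parcensus::segments_df(
    query_id = query_id, query_start = starts - lo + 1L,
    query_end = ends - lo + 1L, target_id = target_id,
    target_start = starts, target_end = ends, strand = "+",
    identity = 100, matches = ends - starts + 1L,
    aln_len = ends - starts + 1L)
}
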