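#' Call the pseudoautosomal boundary from X/Y homology transitions
#'
#' Implements the "where the alignment stopped" logic: homology segments
#' from Y-derived sources and X-derived sources against one target
#' (typically an X assembly) are filtered (identity >= `tier_hi`, length
#' >= `min_hit_len`) and merged per source class across gaps up to
#' `merge_gap`. The PAR-anchored Y-homology block is the merged Y interval
#' nearest the PAR end of the target (position 1); the boundary is its
#' right end — the last base still shared with the Y source. The call is
#' issued only when X-source homology extends at least `flank` bases
#' beyond that boundary (evidence the target continues as X-specific
#' sequence rather than simply ending).
#'
#' @param y_source_segments,x_source_segments `segment_alignment` rows of
#'   the two source classes against one target.
#' @param target_len Target length (bases).
#' @param cfg A [pipeline_config()].
#' @return A one-row data frame (`boundary_call`): target_id, position,
#'   method = "homology_transition", status `"called"` or
#'   `"no_transition"`.
#' @export
call_pab_homology <- function(y_source_segments, x_source_segments,
                              target_len, cfg = pipeline_config()) {
  if (!nrow(y_source_segments) || !nrow(x_source_segments))
    stop("need at least one segment from each source class")
  tid <- y_source_segments$target_id[1]
  keep <- function(s) s[s$identity >= cfg$tier_hi &
                          s$aln_len >= cfg$min_hit_len, , drop = FALSE]
  ys <- keep(y_source_segments)
  xs <- keep(x_source_segments)
  no_call <- data.frame(target_id = tid, position = NA_integer_,
                        method = "homology_transition",
                        status = "no_transition", stringsAsFactors = FALSE)
  if (!nrow(ys)) return(no_call)
  merge_cls <- function(s) {
    IRanges::reduce(IRanges::IRanges(s$target_start, s$target_end),
                    min.gapwidth = cfg$merge_gap + 1L)
  }
  ym <- merge_cls(ys)
  # Y homology must be anchored in the PAR half of the target
  par_half <- IRanges::IRanges(1L, as.integer(ceiling(target_len / 2)))
  anchored <- which(IRanges::countOverlaps(ym, par_half) > 0)
  if (!length(anchored)) return(no_call)
  yblock <- ym[anchored[which.min(IRanges::start(ym)[anchored])]]
  pab <- IRanges::end(yblock)
  if (pab >= target_len) return(no_call)  # Y homology runs to the end
  if (nrow(xs)) {
    xm <- merge_cls(xs)
    beyond <- IRanges::restrict(xm, start = pab + 1L)
    x_extent <- if (length(beyond)) max(IRanges::end(beyond)) - pab else 0L
  } else x_extent <- 0L
  if (x_extent < cfg$flank) return(no_call)
  data.frame(target_id = tid, position = as.integer(pab),
             method = "homology_transition", status = "called",
             stringsAsFactors = FALSE)
}

# Poisson changepoint scan over all breakpoints, vectorized with
# cumulative sums; log-likelihood up to terms constant in the means
# (y log lambda - lambda summed over windows).
step_changepoint <- function(y) {
  n <- length(y)
  cs <- cumsum(y)
  tot <- cs[n]
  b <- seq_len(n - 1L)
  s1 <- cs[b]; n1 <- b
  s2 <- tot - s1; n2 <- n - b
  m1 <- s1 / n1; m2 <- s2 / n2
  xlogy <- function(s, m) ifelse(s > 0, s * log(m), 0)
  ll <- xlogy(s1, m1) - n1 * m1 + xlogy(s2, m2) - n2 * m2
  m0 <- tot / n
  ll0 <- ifelse(tot > 0, tot * log(m0), 0) - n * m0
  delta <- ll - ll0
  best <- which.max(delta)  # which.max takes the leftmost tie
  list(breakpoint = best, delta_loglik = delta[best],
       mean_before = m1[best], mean_after = m2[best])
}

# flat-linear-flat least-squares fit over a (s, e) grid; the ramp runs
# linearly from level1 at window s to level2 at window e.
ramp_fit <- function(y, stride = NULL) {
  n <- length(y)
  if (is.null(stride)) stride <- max(1L, n %/% 100L)
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y^2))
  cyi <- c(0, cumsum(y * seq_len(n)))
  best <- list(rss = Inf)
  eval_pair <- function(s, e) {
    n1 <- s; n2 <- n - e + 1L
    m1 <- cy[s + 1] / n1
    m2 <- (cy[n + 1] - cy[e]) / n2
    rss1 <- (cyy[s + 1]) - n1 * m1^2
    rss2 <- (cyy[n + 1] - cyy[e]) - n2 * m2^2
    rssr <- 0
    if (e - s > 1) {
      i <- (s + 1):(e - 1)
      yhat <- m1 + (m2 - m1) * (i - s) / (e - s)
      sy <- cy[e] - cy[s + 1]
      syy <- cyy[e] - cyy[s + 1]
      syi <- cyi[e] - cyi[s + 1]
      # expand sum((y - yhat)^2) using cumulants
      a <- m1 - (m2 - m1) * s / (e - s)
      bcoef <- (m2 - m1) / (e - s)
      sii <- sum(i^2); si <- sum(i); ni <- length(i)
      rssr <- syy - 2 * (a * sy + bcoef * syi) +
        ni * a^2 + 2 * a * bcoef * si + bcoef^2 * sii
    }
    rss1 + rss2 + rssr
  }
  grid_s <- unique(c(seq(1L, n - 2L, by = stride), n - 2L))
  for (s in grid_s) {
    grid_e <- unique(c(seq(s + 1L, n, by = stride), n))
    for (e in grid_e) {
      r <- eval_pair(s, e)
      if (r < best$rss - 1e-12) best <- list(rss = r, s = s, e = e)
    }
  }
  # local refinement at stride 1
  if (stride > 1L) {
    for (s in max(1L, best$s - stride):min(n - 2L, best$s + stride)) {
      for (e in max(s + 1L, best$e - stride):min(n, best$e + stride)) {
        r <- eval_pair(s, e)
        if (r < best$rss - 1e-12) best <- list(rss = r, s = s, e = e)
      }
    }
  }
  n1 <- best$s; n2 <- n - best$e + 1L
  best$level1 <- cy[best$s + 1] / n1
  best$level2 <- (cy[n + 1] - cy[best$e]) / n2
  best
}

#' Call a boundary from a male read-depth changepoint
#'
#' Two models of hemizygosity onset along a depth track. `step`: for each
#' candidate breakpoint, the Poisson log-likelihood with side-wise MLE
#' means is compared to a single-mean null; the argmax breakpoint
#' (leftmost on ties) is reported with `ratio = mean_after / mean_before`
#' and is `called` only when the log-likelihood gain reaches
#' `changepoint_min_delta_loglik`. `ramp`: a flat-linear-flat least-squares
#' fit locates a gradual transition region `(ramp_start, ramp_end)` with
#' the ratio of the two flat levels — the gradual-homology-decline
#' scenario. `auto` fits both and reports the ramp when its residual
#' improvement exceeds an F-like threshold.
#'
#' Positions are in bases: the step boundary is the end of the last
#' pre-transition window (i.e. the last pseudoautosomal base at window
#' resolution).
#'
#' @param track A `coverage_track` from [depth_track()].
#' @param model `"step"`, `"ramp"` or `"auto"`.
#' @param cfg A [pipeline_config()].
#' @return A one-row data frame: target_id, position (step) or
#'   ramp_start/ramp_end (ramp), method, ratio, delta_loglik, status.
#' @export
call_pab_coverage <- function(track, model = c("step", "ramp", "auto"),
                              cfg = pipeline_config()) {
  model <- match.arg(model)
  y <- track$depth
  if (length(y) < 20) stop("need at least 20 windows")
  if (all(y == 0)) stop("all-zero depth track")
  w <- track$window
  st <- step_changepoint(y)
  if (model %in% c("ramp", "auto")) rp <- ramp_fit(y)
  use_ramp <- FALSE
  if (model == "ramp") use_ramp <- TRUE
  if (model == "auto") {
    n <- length(y)
    rss_step <- sum((y[seq_len(st$breakpoint)] - st$mean_before)^2) +
      sum((y[(st$breakpoint + 1):n] - st$mean_after)^2)
    f_like <- ((rss_step - rp$rss) / 2) / (rp$rss / max(1, n - 4))
    use_ramp <- is.finite(f_like) && f_like > cfg$ramp_f_threshold
  }
  if (use_ramp) {
    ratio <- rp$level2 / rp$level1
    return(data.frame(target_id = track$target_id,
                      ramp_start = as.integer((rp$s - 1L) * w + 1L),
                      ramp_end = as.integer(rp$e * w),
                      method = "coverage_ramp",
                      ratio = ratio, delta_loglik = st$delta_loglik,
                      status = "called", stringsAsFactors = FALSE))
  }
  called <- st$delta_loglik >= cfg$changepoint_min_delta_loglik
  data.frame(target_id = track$target_id,
             position = if (called) as.integer(st$breakpoint * w) else NA_integer_,
             method = "coverage_step",
             ratio = if (called) st$mean_after / st$mean_before else NA_real_,
             delta_loglik = st$delta_loglik,
             status = if (called) "called" else "no_transition",
             stringsAsFactors = FALSE)
}

#' Cluster read alignment drop-off positions
#'
#' Reads originating from the Y chromosome align to the X only up to the
#' boundary and "drop off" at a common position. Alignment right ends
#' within `tol` of each other (single-linkage on the sorted ends) form a
#' cluster; clusters with at least `min_reads` members are reported with
#' their member reads, sorted by position. Ends within `tol` of
#' `target_len` (reads reaching the end of the target, uninformative) are
#' excluded when `target_len` is given.
#'
#' @param read_segments `segment_alignment` rows on one target.
#' @param tol Clustering tolerance (bases).
#' @param min_reads Minimum cluster size.
#' @param target_len Optional target length used to discard ends at the
#'   target boundary.
#' @return A data frame with columns `position` (median end) , `n_reads`
#'   and a list-column `read_ids`.
#' @export
cluster_dropoffs <- function(read_segments, tol = 50L, min_reads = 5L,
                             target_len = NULL) {
  empty <- data.frame(position = integer(0), n_reads = integer(0))
  empty$read_ids <- list()
  if (!nrow(read_segments)) return(empty)
  ends <- read_segments$target_end
  ids <- read_segments$query_id
  if (!is.null(target_len)) {
    keep <- ends < target_len - tol
    ends <- ends[keep]; ids <- ids[keep]
  }
  if (!length(ends)) return(empty)
  o <- order(ends)
  ends <- ends[o]; ids <- ids[o]
  cl <- cumsum(c(1L, diff(ends) > tol))
  out <- lapply(split(seq_along(ends), cl), function(ix) {
    if (length(ix) < min_reads) return(NULL)
    data.frame(position = as.integer(round(stats::median(ends[ix]))),
               n_reads = length(ix))
  })
  members <- split(ids, cl)
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) return(empty)
  res <- do.call(rbind, out[keep])
  res$read_ids <- unname(members[keep])
  res <- res[order(res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify an exon's sex linkage from assembly alignments
#'
#' An exon is "present" in an assembly when some alignment segment covers
#' at least `cov_frac` of the exon at identity >= `min_id`. Present in
#' both X and Y: pseudoautosomal; Y only: Y_specific; X only: X_specific;
#' neither: absent.
#'
#' @param exon_seq Exon sequence (>= 50 bases).
#' @param x_assembly_segments,y_assembly_segments `segment_alignment` rows
#'   with the exon as query against each assembly.
#' @param cov_frac Minimum covered fraction of the exon.
#' @param min_id Minimum percent identity.
#' @param exon_id Identifier stamped on the output.
#' @return A one-row data frame: exon_id, label, x_coverage_frac,
#'   y_coverage_frac, best_identity_x, best_identity_y.
#' @export
assign_exon_linkage <- function(exon_seq, x_assembly_segments,
                                y_assembly_segments, cov_frac = 0.8,
                                min_id = 90, exon_id = "exon") {
  elen <- nchar(exon_seq)
  if (elen < 50) stop("exon shorter than 50 bases")
  cov_of <- function(s) {
    s <- s[s$identity >= min_id, , drop = FALSE]
    if (!nrow(s)) return(c(cov = 0, id = NA_real_))
    ir <- IRanges::reduce(IRanges::IRanges(
      pmax(1L, s$query_start), pmin(elen, s$query_end)))
    c(cov = sum(IRanges::width(ir)) / elen, id = max(s$identity))
  }
  xc <- cov_of(x_assembly_segments)
  yc <- cov_of(y_assembly_segments)
  x_present <- xc["cov"] >= cov_frac
  y_present <- yc["cov"] >= cov_frac
  label <- if (x_present && y_present) "pseudoautosomal"
  else if (y_present) "Y_specific"
  else if (x_present) "X_specific"
  else "absent"
  data.frame(exon_id = exon_id, label = label,
             x_coverage_frac = unname(xc["cov"]),
             y_coverage_frac = unname(yc["cov"]),
             best_identity_x = unname(xc["id"]),
             best_identity_y = unname(yc["id"]),
             stringsAsFactors = FALSE)
}

#' Find core-promoter (TATA-box) motifs upstream of an anchor
#'
#' Scans the `window` bases immediately upstream of `anchor_pos` (an exon
#' start) for forward-strand matches of the IUPAC motif (default TATAWAW,
#' W = A or T). `distance_upstream = anchor_pos - motif_start` in the
#' package's 1-based convention, so a motif starting 35 bases before the
#' exon reports distance 35.
#'
#' @param seq DNA string.
#' @param anchor_pos 1-based anchor (exon start).
#' @param window Upstream window size (bases).
#' @param motif IUPAC motif.
#' @return Data frame with `motif_start` and `distance_upstream`, one row
#'   per match.
#' @export
find_tata <- function(seq, anchor_pos, window = 100L, motif = "TATAWAW") {
  if (anchor_pos < 1 || anchor_pos > nchar(seq))
    stop("anchor outside sequence")
  win_start <- max(1L, anchor_pos - window)
  if (win_start >= anchor_pos) stop("empty upstream window")
  region <- substr(seq, win_start, anchor_pos - 1L)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(region),
                                   fixed = FALSE)
  starts <- IRanges::start(hits) + win_start - 1L
  # motif must lie fully upstream of the anchor
  keep <- starts + nchar(motif) - 1L < anchor_pos
  starts <- starts[keep]
  data.frame(motif_start = as.integer(starts),
             distance_upstream = as.integer(anchor_pos - starts))
}
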