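#' Simulation configuration for a synthetic X/Y pair and reads
#'
#' Defines a two-haplotype male design: an X and a Y chromosome sharing a
#' high-identity pseudoautosomal region (PAR) followed by unrelated
#' sex-specific tails, plus a long-read model. All lengths are bases; all
#' divergences are per-base substitution fractions.
#'
#' @param par_len PAR length shared by X and Y.
#' @param x_specific_len,y_specific_len Lengths of the X- and Y-specific
#'   tails beyond the pseudoautosomal boundary (PAB).
#' @param par_divergence X-vs-Y substitution divergence inside the PAR
#'   (in \[0, 0.05\]). The within-species PAR-X/PAR-Y identity is not a
#'   measured quantity; the default 0.001 (99.9 percent identity) is a free
#'   parameter of the simulation.
#' @param species_divergence Between-species substitution divergence,
#'   default 0.02 (~98 percent genome identity between sister equids).
#' @param monomer_len Tandem-repeat monomer length, default 8000.
#' @param per_copy_divergence Per-copy substitution divergence of repeat
#'   copies from their monomer.
#' @param read_depth Fold-coverage per haplotype for the read simulator.
#' @param read_len_mean,read_len_sd Read length distribution (bases).
#' @param read_err Per-base read substitution error rate.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(par_len = 200000L,
                       x_specific_len = 300000L,
                       y_specific_len = 300000L,
                       par_divergence = 0.001,
                       species_divergence = 0.02,
                       monomer_len = 8000L,
                       per_copy_divergence = 0.01,
                       read_depth = 40,
                       read_len_mean = 10000L,
                       read_len_sd = 1000L,
                       read_err = 0.01,
                       seed = 1L) {
  stopifnot(par_len > 0, x_specific_len > 0, y_specific_len > 0,
            monomer_len > 0, read_len_mean > 0, read_len_sd >= 0,
            par_divergence >= 0, par_divergence <= 0.05,
            species_divergence >= 0, species_divergence < 1,
            per_copy_divergence >= 0, per_copy_divergence < 1,
            read_err >= 0, read_err < 1, read_depth >= 0)
  structure(list(par_len = as.integer(par_len),
                 x_specific_len = as.integer(x_specific_len),
                 y_specific_len = as.integer(y_specific_len),
                 par_divergence = par_divergence,
                 species_divergence = species_divergence,
                 monomer_len = as.integer(monomer_len),
                 per_copy_divergence = per_copy_divergence,
                 read_depth = read_depth,
                 read_len_mean = as.integer(read_len_mean),
                 read_len_sd = read_len_sd,
                 read_err = read_err,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an X/Y chromosome pair sharing a PAR, with ground truth
#'
#' Builds two haplotypes: `X = PAR + X-specific tail` and
#' `Y = PAR' + Y-specific tail`, where `PAR'` is the PAR mutated at
#' `par_divergence` and the two tails are independent random sequence.
#' A three-exon gene is planted spanning the PAB on Y: exons 1 and 2 lie in
#' the Y-specific tail and exon 3 in the PAR (hence on both haplotypes), a
#' layout mirroring a PAB-spanning gametolog. A TATAWAW core-promoter word
#' is planted so that its start is exactly `tata_upstream` bases upstream
#' of exon 3 on both haplotypes.
#'
#' The PAB truth convention is: `pab` is the coordinate of the LAST
#' pseudoautosomal base (here `par_len` on both haplotypes).
#'
#' @param cfg A [sim_config()].
#' @param exon_lens Lengths of exons 1..3.
#' @param tata_upstream Distance (bases) from the planted motif start to
#'   the exon-3 start, default 35.
#' @param line_decoy If `TRUE`, insert a duplicated LINE-like decoy element
#'   just proximal to the PAB on X (overwrites background sequence), to
#'   stress boundary callers with repetitive flanks.
#' @return A list with `x_seq`, `y_seq` (character strings) and `truth`, a
#'   list holding `pab_x`, `pab_y`, `exons` (data frame: exon_id, chrom,
#'   start, end, expected_label), `tata_sites` (data frame: chrom, pos,
#'   distance_upstream) and the planted motif word.
#' @export
make_par_pair <- function(cfg, exon_lens = c(200L, 180L, 220L),
                          tata_upstream = 35L, line_decoy = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), length(exon_lens) == 3)
  exon3_len <- exon_lens[3]
  # exon3 sits inside the PAR just before the PAB, leaving room upstream
  # for the promoter word
  exon3_end <- cfg$par_len - 200L
  exon3_start <- exon3_end - exon3_len + 1L
  if (exon3_start - tata_upstream - 7L < 1L)
    stop("par_len too short to place exon3 and its upstream promoter")

  withr::with_seed(cfg$seed, {
    par_seq <- random_dna(cfg$par_len)
    # plant the promoter word (concrete instance of TATAWAW) and exon3 in
    # the shared PAR so both haplotypes inherit them
    tata_word <- paste0("TATA",
                        paste(sample(c("A", "T"), 1), collapse = ""),
                        "A",
                        paste(sample(c("A", "T"), 1), collapse = ""))
    tata_start <- exon3_start - tata_upstream
    par_seq <- overwrite_seq(par_seq, tata_start, tata_start + 6L, tata_word)

    x_tail <- random_dna(cfg$x_specific_len)
    y_tail <- random_dna(cfg$y_specific_len)

    # exons 1 and 2 in the Y-specific tail (coordinates on Y)
    e1_start <- cfg$par_len + as.integer(0.6 * cfg$y_specific_len)
    e2_start <- cfg$par_len + as.integer(0.3 * cfg$y_specific_len)
    exon1 <- random_dna(exon_lens[1])
    exon2 <- random_dna(exon_lens[2])
    y_tail <- overwrite_seq(y_tail, e1_start - cfg$par_len,
                            e1_start - cfg$par_len + exon_lens[1] - 1L, exon1)
    y_tail <- overwrite_seq(y_tail, e2_start - cfg$par_len,
                            e2_start - cfg$par_len + exon_lens[2] - 1L, exon2)

    if (line_decoy) {
      line <- random_dna(500L)
      d1 <- cfg$par_len - 20000L
      if (d1 > 1000L) {
        par_decoy_x <- paste0(line, line)
        x_full <- paste0(par_seq, x_tail)
        x_full <- overwrite_seq(x_full, d1, d1 + nchar(par_decoy_x) - 1L,
                                par_decoy_x)
        par_seq_x <- substr(x_full, 1L, cfg$par_len)
        x_tail <- substr(x_full, cfg$par_len + 1L, nchar(x_full))
      } else {
        par_seq_x <- par_seq
      }
    } else {
      par_seq_x <- par_seq
    }

    par_y <- mutate_seq(par_seq, cfg$par_divergence)
    x_seq <- paste0(par_seq_x, x_tail)
    y_seq <- paste0(par_y, y_tail)
  })

  exons <- data.frame(
    exon_id = c("exon1", "exon2", "exon3"),
    chrom = c("Y", "Y", "Y"),
    start = c(e1_start, e2_start, exon3_start),
    end = c(e1_start + exon_lens[1] - 1L,
            e2_start + exon_lens[2] - 1L,
            exon3_end),
    expected_label = c("Y_specific", "Y_specific", "pseudoautosomal"),
    stringsAsFactors = FALSE)
  tata <- data.frame(chrom = c("X", "Y"),
                     pos = c(tata_start, tata_start),
                     distance_upstream = c(tata_upstream, tata_upstream))

  truth <- list(pab_x = cfg$par_len, pab_y = cfg$par_len,
                exons = exons, tata_sites = tata,
                tata_word = tata_word,
                exon_seqs = list(exon1 = exon1, exon2 = exon2,
                                 exon3 = substr(par_seq, exon3_start, exon3_end)),
                x_len = nchar(x_seq), y_len = nchar(y_seq))
  list(x_seq = x_seq, y_seq = y_seq, truth = truth)
}

#' Simulate a tandem-repeat array with known copy structure
#'
#' Concatenates `n_full` full monomer copies followed by one partial copy
#' (a monomer prefix) per element of `partial_fracs`. Each copy is mutated
#' independently at `per_copy_divergence` (substitutions only, so with
#' zero divergence the array length is exactly
#' `(n_full + sum(partial_fracs)) * monomer_len`). Motifs can be planted
#' at fixed offsets of the monomer template so that every full copy
#' carries them.
#'
#' @param monomer_len Monomer length (bases); ignored if `monomer` given.
#' @param n_full Number of full copies.
#' @param partial_fracs Numeric vector of partial-copy fractions in (0,1).
#' @param per_copy_divergence Per-copy substitution divergence.
#' @param motif_placements Optional data frame with columns `motif`
#'   (character) and `offset` (1-based start within the monomer).
#' @param seed Integer seed.
#' @param monomer Optional explicit monomer sequence (overrides
#'   `monomer_len`).
#' @param prefix_len Bases of random flanking sequence added before and
#'   after the array (default 0).
#' @return A list with `seq`, `monomer` and `truth`; `truth$copies` is a
#'   data frame (start, end, copy_class, monomer_cov) in 1-based inclusive
#'   coordinates of `seq`.
#' @export
make_tandem_array <- function(monomer_len = 8000L, n_full, partial_fracs = numeric(0),
                              per_copy_divergence = 0, motif_placements = NULL,
                              seed = 1L, monomer = NULL, prefix_len = 0L) {
  stopifnot(n_full >= 0, all(partial_fracs > 0), all(partial_fracs < 1))
  withr::with_seed(as.integer(seed), {
    if (is.null(monomer)) monomer <- random_dna(monomer_len)
    monomer_len <- nchar(monomer)
    if (!is.null(motif_placements)) {
      for (i in seq_len(nrow(motif_placements))) {
        m <- motif_placements$motif[i]
        off <- motif_placements$offset[i]
        if (nchar(m) > monomer_len) stop("motif longer than monomer")
        if (off < 1 || off + nchar(m) - 1 > monomer_len)
          stop("motif offset outside monomer")
        monomer <- overwrite_seq(monomer, off, off + nchar(m) - 1L, m)
      }
    }
    lens <- c(rep(monomer_len, n_full),
              as.integer(round(partial_fracs * monomer_len)))
    classes <- c(rep("full", n_full), rep("partial", length(partial_fracs)))
    copies <- character(length(lens))
    for (i in seq_along(lens)) {
      copies[i] <- mutate_seq(substr(monomer, 1L, lens[i]), per_copy_divergence)
    }
    left <- if (prefix_len > 0) random_dna(prefix_len) else ""
    right <- if (prefix_len > 0) random_dna(prefix_len) else ""
    arr <- paste0(left, paste(copies, collapse = ""), right)
  })
  ends <- prefix_len + cumsum(lens)
  starts <- ends - lens + 1L
  truth <- list(copies = data.frame(start = as.integer(starts),
                                    end = as.integer(ends),
                                    copy_class = classes,
                                    monomer_cov = lens / monomer_len,
                                    stringsAsFactors = FALSE),
                monomer_len = monomer_len)
  list(seq = arr, monomer = monomer, truth = truth)
}

#' Scatter amplicon copies of a reference sequence across backbones
#'
#' Plants non-overlapping copies of `ref_copy` (possibly truncated to a
#' prefix, modelling partial copies) into the given backbone scaffolds,
#' each mutated at its placement's divergence so the realized identity to
#' the reference falls in the requested tier band.
#'
#' @param backbones Named character vector of scaffold sequences.
#' @param ref_copy Reference amplicon sequence.
#' @param placements Data frame with columns `scaffold`, `count`,
#'   `divergence` and optionally `len_min`, `len_max` (copy length range,
#'   default the full reference length) and `tier` (a free-text label
#'   recorded in truth).
#' @param seed Integer seed.
#' @param full_frac Monomer coverage at or above which a planted copy is
#'   recorded as `full` in the truth (default 0.9).
#' @return A list with `genome` (named character vector) and `truth`, a
#'   data frame of planted intervals (scaffold, start, end, length,
#'   copy_class, tier, divergence).
#' @export
scatter_amplicons <- function(backbones, ref_copy, placements, seed = 1L,
                              full_frac = 0.9) {
  stopifnot(is.character(backbones), !is.null(names(backbones)),
            all(placements$scaffold %in% names(backbones)))
  ref_len <- nchar(ref_copy)
  truth <- list()
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(placements))) {
      p <- placements[i, ]
      if (p$count == 0) next
      sc <- p$scaffold
      len_min <- if (!is.null(placements$len_min) && !is.na(p$len_min)) p$len_min else ref_len
      len_max <- if (!is.null(placements$len_max) && !is.na(p$len_max)) p$len_max else ref_len
      tier <- if (!is.null(placements$tier)) p$tier else NA_character_
      occupied <- IRanges::IRanges()
      # previously planted intervals on this scaffold stay reserved
      for (tr in truth) {
        prev <- tr[tr$scaffold == sc, , drop = FALSE]
        if (nrow(prev))
          occupied <- c(occupied, IRanges::IRanges(prev$start, prev$end))
      }
      bb_len <- nchar(backbones[[sc]])
      for (j in seq_len(p$count)) {
        L <- if (len_min == len_max) len_min else sample(len_min:len_max, 1L)
        placed <- FALSE
        for (try in 1:2000) {
          s <- sample.int(bb_len - L + 1L, 1L)
          cand <- IRanges::IRanges(s, s + L - 1L)
          if (length(occupied) == 0 ||
              sum(IRanges::countOverlaps(cand, occupied)) == 0) {
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("insufficient backbone space on scaffold ", sc)
        occupied <- c(occupied, cand)
        copy_seq <- mutate_seq(substr(ref_copy, 1L, L), p$divergence)
        backbones[[sc]] <- overwrite_seq(backbones[[sc]], s, s + L - 1L, copy_seq)
        truth[[length(truth) + 1L]] <- data.frame(
          scaffold = sc, start = s, end = s + L - 1L, length = L,
          copy_class = if (L / ref_len >= full_frac) "full" else "partial",
          tier = tier, divergence = p$divergence,
          stringsAsFactors = FALSE)
      }
    }
  })
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               length = integer(0), copy_class = character(0),
               tier = character(0), divergence = numeric(0))
  truth_df <- truth_df[order(truth_df$scaffold, truth_df$start), , drop = FALSE]
  rownames(truth_df) <- NULL
  list(genome = backbones, truth = truth_df)
}

#' Invert a segment of a sequence in place
#'
#' Replaces `seq[start..end]` (1-based inclusive) with its reverse
#' complement, leaving flanks unchanged. Applying the same inversion twice
#' restores the original sequence.
#'
#' @param seq DNA string.
#' @param start,end 1-based inclusive interval, `start < end`.
#' @export
apply_inversion <- function(seq, start, end) {
  if (!(start >= 1 && start < end && end <= nchar(seq)))
    stop("invalid inversion interval [", start, ",", end, "]")
  overwrite_seq(seq, start, end, revcomp(substr(seq, start, end)))
}

#' Simulate long reads from one or more haplotypes
#'
#' Per haplotype, the read count is Poisson with mean
#' `depth * haplotype_len / read_len_mean`; read lengths are normal
#' (truncated to \[200, haplotype length\]), start positions uniform,
#' strands random, and substitution errors i.i.d. at `read_err`.
#'
#' @param haplotypes Named character vector of haplotype sequences.
#' @param cfg A [sim_config()] supplying `read_depth`, `read_len_mean`,
#'   `read_len_sd`, `read_err` and `seed`.
#' @return A list with `reads` (named character vector) and `origins`, a
#'   data frame (read_id, haplotype, start, end, strand).
#' @export
simulate_reads <- function(haplotypes, cfg) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(names(haplotypes)))
  for (h in haplotypes)
    if (cfg$read_len_mean > nchar(h))
      stop("read_len_mean exceeds a haplotype length")
  reads <- character(0)
  origins <- list()
  withr::with_seed(cfg$seed + 1L, {
    for (hname in names(haplotypes)) {
      hseq <- haplotypes[[hname]]
      hlen <- nchar(hseq)
      n <- stats::rpois(1L, cfg$read_depth * hlen / cfg$read_len_mean)
      if (n == 0) next
      lens <- pmin(pmax(as.integer(round(
        stats::rnorm(n, cfg$read_len_mean, cfg$read_len_sd))), 200L), hlen)
      starts <- vapply(lens, function(L) sample.int(hlen - L + 1L, 1L), integer(1))
      strands <- sample(c("+", "-"), n, replace = TRUE)
      ids <- sprintf("%s_read%05d", hname, seq_len(n))
      rs <- character(n)
      for (i in seq_len(n)) {
        r <- substr(hseq, starts[i], starts[i] + lens[i] - 1L)
        if (strands[i] == "-") r <- revcomp(r)
        rs[i] <- mutate_seq(r, cfg$read_err)
      }
      names(rs) <- ids
      reads <- c(reads, rs)
      origins[[hname]] <- data.frame(read_id = ids, haplotype = hname,
                                     start = starts, end = starts + lens - 1L,
                                     strand = strands, stringsAsFactors = FALSE)
    }
  })
  origins <- if (length(origins)) do.call(rbind, origins) else
    data.frame(read_id = character(0), haplotype = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  rownames(origins) <- NULL
  list(reads = reads, origins = origins)
}

#' Serialize simulation ground truth to JSON
#'
#' Truth round-trips losslessly through this writer and
#' [read_truth_json()].
#'
#' @param truth A truth object (list / data frames) from a simulator.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
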