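cfg <- pipeline_config()

test_that("monomer period inference: tandem vs non-tandem", {
  expect_identical(infer_monomer(rand_seq(50000, seed = 80))$status,
                   "not_tandem")
  ta <- make_tandem_array(8000, 10, per_copy_divergence = 0.01, seed = 81)
  im <- infer_monomer(ta$seq, k = 21)
  expect_identical(im$status, "tandem")
  expect_lte(abs(im$period - 8000), 100)
  # representative window has the inferred period's length
  expect_identical(unname(im$representative["end"] -
                            im$representative["start"] + 1L), im$period)
  expect_error(infer_monomer(rand_seq(1500, seed = 82)), "shorter")
})

test_that("copy enumeration recovers planted full/partial structure", {
  # no homology: zero copies
  none <- enumerate_copies(rand_seq(2000, seed = 83),
                           c(t1 = rand_seq(30000, seed = 84)), cfg)
  expect_identical(nrow(none$copies), 0L)

  ta <- make_tandem_array(2000, 5, 0.5, per_copy_divergence = 0.01, seed = 85)
  cen <- enumerate_copies(ta$monomer, c(arr = ta$seq), cfg)
  expect_identical(cen$summary$n_full, 5L)
  expect_identical(cen$summary$n_partial, 1L)
  # copies do not overlap after merging
  ir <- IRanges::IRanges(cen$copies$start, cen$copies$end)
  expect_identical(sum(IRanges::countOverlaps(ir, ir) > 1), 0L)
  expect_error(enumerate_copies(ta$monomer, character(0), cfg), "empty")
  expect_error(enumerate_copies(rand_seq(500, seed = 1),
                                c(t = ta$seq), cfg), "min_hit_len")
})

test_that("census recovery is exact across seeds at low divergence", {
  ok <- 0L
  for (s in 1:50) {
    nf <- 3L + (s %% 5L)
    # partial copies must stay above the census length filter
    pf <- if (s %% 2 == 0) c(0.6) else c(0.7, 0.55)
    ta <- make_tandem_array(2000, nf, pf, per_copy_divergence = 0.04,
                            seed = 8000 + s, prefix_len = 1000)
    cen <- enumerate_copies(ta$monomer, c(arr = ta$seq), cfg)
    if (nrow(cen$summary) == 1 && cen$summary$n_full == nf &&
        cen$summary$n_partial == length(pf)) ok <- ok + 1L
  }
  expect_gte(ok, 48L)  # >= 95% of 50 seeds
})

test_that("census thresholds act monotonically", {
  ta <- make_tandem_array(2000, 4, c(0.3, 0.7), per_copy_divergence = 0.02,
                          seed = 86)
  base <- enumerate_copies(ta$monomer, c(arr = ta$seq), cfg)
  # lowering min_hit_len never decreases the copy count
  lo <- enumerate_copies(ta$monomer, c(arr = ta$seq),
                         pipeline_config(min_hit_len = 300))
  expect_gte(nrow(lo$copies), nrow(base$copies))
  # raising full_frac never increases n_full
  strict <- enumerate_copies(ta$monomer, c(arr = ta$seq),
                             pipeline_config(full_frac = 0.99))
  expect_lte(strict$summary$n_full, base$summary$n_full)
})

test_that("identity tiers split at the configured thresholds", {
  copies <- data.frame(target_id = "t", identity = c(100, 92, 89.9, 85, 80))
  tiers <- tier_by_identity(copies, cfg)$tier
  expect_identical(tiers, c("high", "high", "mid", "mid", "low"))
})

test_that("amplicon tiers from planted divergence land in their bands", {
  withr::with_seed(87, bb <- c(chrX = rand_seq(100000)))
  ref <- rand_seq(2000, seed = 88)
  pl <- data.frame(scaffold = "chrX", count = c(5, 5),
                   divergence = c(0.02, 0.20), tier = c("high", "low"))
  sc <- scatter_amplicons(bb, ref, pl, seed = 89)
  cen <- enumerate_copies(ref, sc$genome, cfg)
  tiered <- tier_by_identity(cen$copies, cfg)
  # anchor-density identity separates the >90% from the <85% population
  expect_identical(sum(tiered$tier == "high"), 5L)
  expect_identical(sum(tiered$tier == "low"), 5L)
})

test_that("scan_motif equals the brute-force oracle and finds planted CTCF", {
  expect_identical(nrow(scan_motif(strrep("AC", 500), "TTTGGG")), 0L)
  expect_error(scan_motif("ACGT", "QQ"), "IUPAC")

  withr::with_seed(90, {
    for (rep in 1:6) {
      s <- rand_seq(2000)
      motif <- c("TATAWAW", "ACGTN", "RYSWKM")[1 + rep %% 3]
      mm <- rep %% 3
      got <- scan_motif(s, motif, max_mismatch = mm)
      oracle <- bf_motif_scan(s, motif, max_mismatch = mm)
      expect_equal(got[c("start", "end", "strand")],
                   oracle[c("start", "end", "strand")])
    }
  })

  # planted motif with 2 substitutions is recovered at max_mismatch 3
  ctcf <- cfg$ctcf_motif
  damaged <- paste0(substr(ctcf, 1, 10), "TT", substr(ctcf, 13, nchar(ctcf)))
  s <- paste0(rand_seq(500, seed = 91), damaged, rand_seq(500, seed = 92))
  hits <- scan_motif(s, ctcf, max_mismatch = 3)
  expect_identical(hits$start[hits$strand == "+"], 501L)

  # three CTCF sites planted per monomer are found three times per copy
  mp <- data.frame(motif = ctcf, offset = c(500L, 2500L, 5000L))
  ta <- make_tandem_array(8000, 2, per_copy_divergence = 0,
                          motif_placements = mp, seed = 93)
  hits2 <- scan_motif(ta$seq, ctcf, max_mismatch = 0)
  expect_identical(nrow(hits2[hits2$strand == "+", ]), 6L)
  expect_identical(nrow(scan_motif(ta$monomer, ctcf)[
    scan_motif(ta$monomer, ctcf)$strand == "+", , drop = FALSE]), 3L)
})

test_that("pairwise identity is a global-alignment match fraction", {
  a <- rand_seq(100, seed = 94)
  self <- pairwise_identity(c(x = a, y = a))
  expect_equal(self$identity["x", "y"], 100)
  expect_equal(self$distance["x", "y"], 0)

  # 4 substitutions in 100 bp, no gaps: identity 96.0
  b <- a
  for (p in c(10, 30, 60, 90)) {
    old <- substr(b, p, p)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  pid <- pairwise_identity(c(x = a, y = b))
  expect_equal(pid$identity["x", "y"], 96.0)
  expect_identical(pid$identity, t(pid$identity))

  # invariant under simultaneous reverse complement
  pid_rc <- pairwise_identity(c(x = revcomp(a), y = revcomp(b)))
  expect_equal(pid_rc$identity["x", "y"], pid$identity["x", "y"])
  expect_error(pairwise_identity(c(x = "", y = "ACGT")), "empty")
})

test_that("neighbor joining satisfies the three-point formulas", {
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_identical(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0, 2, 4))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)))
  Dns <- D; Dns[1, 2] <- 5
  expect_error(nj_tree(Dns), "symmetric")
})

test_that("NJ reproduces additive tree metrics exactly", {
  for (s in 1:10) {
    withr::with_seed(9500 + s, {
      gen <- ape::rtree(8, rooted = FALSE)
      gen$edge.length <- runif(nrow(gen$edge), 0.05, 1)
    })
    D <- ape::cophenetic.phylo(gen)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    tr <- nj_tree(D)
    # topology identical to the generating tree
    expect_identical(as.integer(ape::dist.topo(ape::unroot(gen), tr)), 0L)
    # the tree metric is reproduced to numerical tolerance
    Dhat <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(Dhat - D)), 1e-9)
    # independent reference implementation agrees on topology
    ref <- ape::nj(D)
    expect_identical(as.integer(ape::dist.topo(ref, tr)), 0L)
  }
})

test_that("degenerate all-equal distances yield zero-length branches", {
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr <- nj_tree(D)
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  expect_true(all(tr$edge.length[internal] < 1e-9))
  expect_true(all(tr$edge.length >= 0))
})

test_that("distribution report is one sorted row per copy", {
  expect_identical(nrow(distribution_report(
    data.frame(target_id = character(0), start = integer(0),
               copy_class = character(0)))), 0L)
  copies <- data.frame(target_id = c("chr2", "chr1", "chr2"),
                       start = c(500L, 100L, 20L),
                       copy_class = c("full", "partial", "full"),
                       tier = c("high", "low", "high"))
  rep_df <- distribution_report(copies)
  expect_identical(nrow(rep_df), 3L)
  expect_identical(rep_df$chrom, c("chr1", "chr2", "chr2"))
  expect_identical(rep_df$pos, c(100L, 20L, 500L))
  f <- withr::local_tempfile(fileext = ".tsv")
  distribution_report(copies, f)
  expect_identical(nrow(utils::read.delim(f)), 3L)
})
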