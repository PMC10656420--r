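DNA_BASES <- c("A", "C", "G", "T")

#' Generate a uniform random DNA sequence
#'
#' @param n Sequence length in bases.
#' @return A single character string of `n` bases drawn uniformly from ACGT.
#' @keywords internal
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param seq A character string over ACGTN (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Mutate a sequence with i.i.d. substitutions (and optional indels)
#'
#' Each base is substituted independently with probability `rate`; a
#' substituted base is replaced by one of the three other bases chosen
#' uniformly. By default no indels are introduced, so sequence length is
#' preserved and interval arithmetic on planted features stays exact.
#' `indel_rate` > 0 enables a stress mode: at that per-base rate, a
#' single-base deletion or insertion (uniform base, before the position)
#' is applied instead, which breaks exact length arithmetic by design.
#'
#' @param seq A DNA string.
#' @param rate Per-base substitution probability in \[0, 1).
#' @param indel_rate Per-base probability of a 1-bp insertion or deletion
#'   (default 0).
#' @return The mutated string.
#' @export
mutate_seq <- function(seq, rate, indel_rate = 0) {
  stopifnot(rate >= 0, rate < 1, indel_rate >= 0, indel_rate < 1)
  if ((rate == 0 && indel_rate == 0) || nchar(seq) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    # draw a uniform alternative base for each hit position
    repl <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                   character(1), USE.NAMES = FALSE)
    ch[hit] <- repl
  }
  if (indel_rate > 0) {
    u <- stats::runif(length(ch))
    del <- u < indel_rate / 2
    ins <- u >= indel_rate / 2 & u < indel_rate
    if (any(ins)) {
      ch[ins] <- paste0(sample(DNA_BASES, sum(ins), replace = TRUE), ch[ins])
    }
    if (any(del)) ch <- ch[!del]
  }
  paste(ch, collapse = "")
}

#' Replace a subsequence in place
#'
#' @param seq DNA string; `start`,`end` 1-based inclusive; `insert` must have
#'   length `end - start + 1` (length-preserving overwrite).
#' @keywords internal
overwrite_seq <- function(seq, start, end, insert) {
  stopifnot(start >= 1, end <= nchar(seq), start <= end,
            nchar(insert) == end - start + 1)
  paste0(substr(seq, 1L, start - 1L), insert,
         substr(seq, end + 1L, nchar(seq)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom,
                    start = as.integer(df$start) - 1L,
                    end   = as.integer(df$end))
  if (!is.null(df$name))   bed$name   <- df$name
  if (!is.null(df$strand)) {
    if (is.null(bed$name)) bed$name <- "."
    bed$score  <- 0L
    bed$strand <- df$strand
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
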