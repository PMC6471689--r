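#' Deterministic synthetic sequence fixtures
#'
#' [generate_uniform()] writes reads with i.i.d. bases at a stated GC
#' content; [generate_skewed()] additionally plants a tandem-repeated
#' low-complexity motif in a fraction of each read's bases, concentrating
#' superkmer mass on the motif's signature — the "big bins" regime that
#' size-aware partitioning is designed for. Generation is a pure function
#' of its arguments: the same seed always yields byte-identical files.
#'
#' @param path Output file path.
#' @param n_records Number of reads.
#' @param read_length Read length: a scalar, or `c(min, max)` for uniform
#'   integer lengths.
#' @param gc GC content in `[0, 1]` (probability a base is G or C).
#' @param ambiguity_rate Probability a base is replaced by `N`, in `[0, 1)`.
#' @param seed Integer seed.
#' @param format `"fasta"` (default) or `"fastq"` (constant quality line).
#' @return Invisibly, `path`.
#' @export
generate_uniform <- function(path, n_records, read_length, gc = 0.5,
                             ambiguity_rate = 0, seed = 1L,
                             format = c("fasta", "fastq")) {
  generate_reads(path, n_records, read_length, gc, ambiguity_rate, seed,
                 match.arg(format), skew_motif = NULL, skew_fraction = 0)
}

#' @rdname generate_uniform
#' @param skew_motif A/C/G/T motif (length >= the signature length in use)
#'   repeated in tandem inside each read.
#' @param skew_fraction Fraction of each read's bases, in `[0, 1)`, drawn
#'   from tandem motif copies; `0` reproduces [generate_uniform()] exactly.
#' @export
generate_skewed <- function(path, n_records, read_length, skew_motif,
                            skew_fraction, gc = 0.5, ambiguity_rate = 0,
                            seed = 1L, format = c("fasta", "fastq")) {
  if (!is.character(skew_motif) || length(skew_motif) != 1L ||
      !grepl("^[ACGT]+$", skew_motif)) {
    stop("skew_motif must be a non-empty string over A/C/G/T")
  }
  generate_reads(path, n_records, read_length, gc, ambiguity_rate, seed,
                 match.arg(format), skew_motif, skew_fraction)
}

generate_reads <- function(path, n_records, read_length, gc, ambiguity_rate,
                           seed, format, skew_motif, skew_fraction) {
  stopifnot(n_records >= 0, all(read_length >= 1),
            gc >= 0, gc <= 1, ambiguity_rate >= 0, ambiguity_rate < 1,
            skew_fraction >= 0, skew_fraction < 1)
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  reads <- withr::with_seed(seed, {
    vapply(seq_len(n_records), function(i) {
      L <- if (length(read_length) == 2L) {
        sample(read_length[1]:read_length[2], 1L)
      } else {
        as.integer(read_length)
      }
      b <- sample(bases, L, replace = TRUE, prob = prob)
      s <- round(skew_fraction * L)
      if (s > 0) {
        tandem <- strsplit(strrep(skew_motif,
                                  ceiling(s / nchar(skew_motif))), "")[[1]]
        pos <- sample.int(L - s + 1L, 1L)
        b[pos:(pos + s - 1L)] <- tandem[seq_len(s)]
      }
      if (ambiguity_rate > 0) {
        b[runif(L) < ambiguity_rate] <- "N"
      }
      paste(b, collapse = "")
    }, character(1))
  })
  ids <- paste0("read_", seq_len(n_records))
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", ids), reads))
  } else {
    as.vector(rbind(paste0("@", ids), reads, "+",
                    vapply(nchar(reads), function(n)
                      strrep("I", n), character(1))))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
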