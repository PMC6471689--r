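# Independent pure-R oracles for property tests: naive string manipulation,
# no shared code with the package's C++ kernels.

rc_r <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

canonical_r <- function(s) min(s, rc_r(s))

allowed_r <- function(s) {
  !(startsWith(s, "AAA") || startsWith(s, "ACA") ||
      grepl("AA", substring(s, 2), fixed = TRUE))
}

# Brute-force signature: enumerate all m-mer windows, canonicalize each,
# prefer allowed ones, take the lexicographic minimum.
signature_oracle_r <- function(kmer, m) {
  k <- nchar(kmer)
  mm <- vapply(seq_len(k - m + 1),
               function(i) canonical_r(substr(kmer, i, i + m - 1)),
               character(1))
  ok <- vapply(mm, allowed_r, logical(1))
  if (any(ok)) {
    list(mmer = min(mm[ok]), allowed = TRUE)
  } else {
    list(mmer = min(mm), allowed = FALSE)
  }
}

# Brute-force superkmer decomposition: per-window signatures, then group
# maximal runs of equal signature.
superkmer_oracle_r <- function(frag, k, m) {
  n <- nchar(frag)
  if (n < k) {
    return(data.frame(seq = character(), signature = character(),
                      n_kmers = integer()))
  }
  sigs <- vapply(seq_len(n - k + 1), function(i) {
    signature_oracle_r(substr(frag, i, i + k - 1), m)$mmer
  }, character(1))
  r <- rle(sigs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    seq = vapply(seq_along(starts), function(j)
      substr(frag, starts[j], ends[j] + k - 1L), character(1)),
    signature = r$values,
    n_kmers = r$lengths,
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Many random fixed-length m-mers, fast.
random_mmers <- function(n, m) {
  mat <- matrix(c("A", "C", "G", "T")[sample.int(4L, n * m, replace = TRUE)],
                nrow = n)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

write_oracle_tsv <- function(records, k, mode, path) {
  write_counts(naive_count(records, k, mode), path)
}
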