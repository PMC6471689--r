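#' k-mer count tables
#'
#' A `kmer_count_table` maps k-mer text to its occurrence count. In
#' `"canonical"` mode every key is the lexicographic minimum of the k-mer
#' and its reverse complement; `"forward"` mode counts k-mers as read.
#' Inside the counting kernel keys are held 2-bit packed; at the R surface
#' they are decoded for inspection and TSV output.
#'
#' @param counts Named numeric vector, names are k-mer strings, counts >= 1.
#' @param k k-mer length.
#' @param mode `"canonical"` or `"forward"`.
#' @return A `kmer_count_table`.
#' @export
new_count_table <- function(counts, k, mode = c("canonical", "forward")) {
  mode <- match.arg(mode)
  structure(list(counts = counts, k = as.integer(k), mode = mode),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  s <- summarize_counts(x)
  cat("<kmer_count_table> k=", x$k, " mode=", x$mode, ": ", s$distinct,
      " distinct / ", format(s$total, scientific = FALSE), " total k-mers\n",
      sep = "")
  invisible(x)
}

#' Count the k-mers carried by a set of superkmers
#'
#' Every constituent k-mer of every superkmer increments its entry in a
#' hash table (canonicalized first in canonical mode). The total of all
#' counts equals the sum of `n_kmers` over the superkmers.
#'
#' @param superkmers Data.frame from [split_superkmers()], or a character
#'   vector of superkmer sequences.
#' @param k k-mer length; every superkmer must have length >= k.
#' @param mode `"canonical"` (default) or `"forward"`.
#' @return A `kmer_count_table`.
#' @examples
#' count_partition("ACGTA", k = 4, mode = "forward")
#' @export
count_partition <- function(superkmers, k, mode = c("canonical", "forward")) {
  mode <- match.arg(mode)
  seqs <- if (is.data.frame(superkmers)) superkmers$seq else superkmers
  if (any(nchar(seqs) < k)) {
    stop("superkmer shorter than k = ", k, ": inconsistent input")
  }
  res <- cpp_count_kmers(seqs, k, mode == "canonical")
  new_count_table(stats::setNames(res$count, res$kmer), k = k, mode = mode)
}

#' Merge count tables from distinct partitions
#'
#' Signature-based routing sends all instances of a k-mer to one partition,
#' so the key sets of per-partition tables must be pairwise disjoint; any
#' overlap signals broken routing and raises a partition-violation error.
#'
#' @param tables List of `kmer_count_table`s with identical `k` and `mode`.
#' @return The union `kmer_count_table`.
#' @export
merge_tables <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "kmer_count_table")))
  k <- unique(vapply(tables, `[[`, integer(1), "k"))
  mode <- unique(vapply(tables, `[[`, character(1), "mode"))
  if (length(k) != 1L || length(mode) != 1L) {
    stop("cannot merge tables with differing k or mode")
  }
  keys <- unlist(lapply(tables, function(t) names(t$counts)), use.names = FALSE)
  if (anyDuplicated(keys)) {
    stop("partition violation: k-mer '", keys[duplicated(keys)][1],
         "' appears in more than one partition table")
  }
  counts <- unlist(lapply(tables, `[[`, "counts"))
  names(counts) <- keys
  new_count_table(counts, k = k, mode = mode)
}

#' Naive sliding-window k-mer counter
#'
#' The redundant baseline: clean each record, slide a k-window over every
#' fragment and count directly, with no superkmers and no partitioning.
#' Used as the independent oracle the two-stage pipeline must reproduce
#' exactly.
#'
#' @param records Record data.frame (`id`, `seq`), raw sequences permitted.
#' @param k k-mer length.
#' @param mode `"canonical"` (default) or `"forward"`.
#' @return A `kmer_count_table`.
#' @export
naive_count <- function(records, k, mode = c("canonical", "forward")) {
  mode <- match.arg(mode)
  frags <- unlist(lapply(records$seq, cpp_clean_fragments), use.names = FALSE)
  if (is.null(frags)) frags <- character()
  res <- cpp_count_kmers(frags, k, mode == "canonical")
  new_count_table(stats::setNames(res$count, res$kmer), k = k, mode = mode)
}

#' Distinct and total k-mer statistics of a table
#'
#' @param table A `kmer_count_table`.
#' @return A list with `distinct` (number of k-mer species) and `total`
#'   (sum of occurrence counts).
#' @export
summarize_counts <- function(table) {
  stopifnot(inherits(table, "kmer_count_table"))
  list(distinct = length(table$counts),
       total = if (length(table$counts)) sum(table$counts) else 0)
}
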