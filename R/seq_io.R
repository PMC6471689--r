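#' Read sequence records from FASTA
#'
#' Multi-line bodies are concatenated; record order is preserved. Bases are
#' uppercased on read (counting is case-insensitive); ambiguity characters
#' such as N are kept and handled downstream by [clean_fragments()].
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `seq`, one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  data.frame(id = if (length(x)) names(x) else character(),
             seq = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read sequence records from 4-line FASTQ
#'
#' The id is taken from the `@` line and the sequence from the second line;
#' quality strings are read and discarded. A record count that is not a
#' multiple of four lines is a format error.
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `id` and `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  data.frame(id = if (length(x)) names(x) else character(),
             seq = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read FASTA or FASTQ, dispatching on file extension
#'
#' `.fq`/`.fastq` are read as FASTQ, anything else as FASTA.
#'
#' @param path Path to a sequence file.
#' @return A data.frame with columns `id` and `seq`.
#' @export
read_sequences <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
    read_fastq(path)
  } else {
    read_fasta(path)
  }
}

#' Group records into chunks of roughly equal base count
#'
#' Greedy fill: records accumulate into the current chunk until its total
#' base count reaches `target_chunk_bases`, at which point the chunk closes;
#' a single record at or above the target forms its own chunk. No record is
#' split and the concatenation of chunks preserves input order. Chunks stand
#' in for the input splits that feed stage-1 workers.
#'
#' @param records Record data.frame from [read_fasta()] / [read_fastq()].
#' @param target_chunk_bases Positive integer target of bases per chunk.
#' @return A list of record data.frames.
#' @export
chunk_records <- function(records, target_chunk_bases) {
  stopifnot(is.numeric(target_chunk_bases), target_chunk_bases >= 1)
  n <- nrow(records)
  if (n == 0L) return(list())
  lens <- nchar(records$seq)
  chunks <- list()
  start <- 1L
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + lens[i]
    if (acc >= target_chunk_bases && i < n) {
      chunks[[length(chunks) + 1L]] <- records[start:i, , drop = FALSE]
      start <- i + 1L
      acc <- 0
    }
  }
  if (start <= n) {
    chunks[[length(chunks) + 1L]] <- records[start:n, , drop = FALSE]
  }
  chunks
}

#' Write a count table as sorted TSV
#'
#' One line per k-mer, `KMER<TAB>COUNT`, sorted ascending lexicographically
#' (A<C<G<T) so output is bit-reproducible regardless of hash-table
#' iteration order or partitioning.
#'
#' @param table A `kmer_count_table` (see [count_partition()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "kmer_count_table"))
  kmers <- names(table$counts)
  ord <- order(kmers, method = "radix")  # C-locale byte order: A<C<G<T
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(kmers)) {
    writeLines(paste0(kmers[ord], "\t",
                      format(table$counts[ord], scientific = FALSE, trim = TRUE)),
               con)
  }
  invisible(path)
}

#' Read a count table written by [write_counts()]
#'
#' @param path TSV file path.
#' @param k k-mer length recorded in the returned table (inferred from the
#'   first k-mer when `NULL`).
#' @param mode Count mode label, `"canonical"` or `"forward"`.
#' @return A `kmer_count_table`.
#' @export
read_counts <- function(path, k = NULL, mode = "canonical") {
  if (!file.exists(path)) stop("count file not found: ", path)
  if (file.size(path) == 0) {
    return(new_count_table(stats::setNames(numeric(), character()),
                           k = k %||% 0L, mode = mode))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "numeric"),
                         col.names = c("kmer", "count"))
  new_count_table(stats::setNames(d$count, d$kmer),
                  k = k %||% nchar(d$kmer[1]), mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
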