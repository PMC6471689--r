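#' Shift-based 64-bit integer hash
#'
#' The xorshift-multiply finalizer used everywhere a signature or bin id
#' must be scattered: `z ^= z >> 30; z *= 0xBF58476D1CE4E5B9; z ^= z >> 27;
#' z *= 0x94D049BB133111EB; z ^= z >> 31`. Exposed on 16-digit hex strings
#' so the full 64 bits survive the round trip through R.
#'
#' @param x_hex Character vector of hexadecimal 64-bit values.
#' @return Character vector of 16-hex-digit hashed values.
#' @examples
#' mix64("0000000000000001")
#' @export
mix64 <- function(x_hex) cpp_mix64_hex(x_hex)

#' Map a signature to a bin by hashing its packed value
#'
#' The signature's 2-bit packed integer value is hashed with [mix64()] and
#' reduced modulo `B`. Deterministic: equal signatures always land in the
#' same bin, which is what guarantees all instances of a k-mer share a
#' partition.
#'
#' @param sig Character vector of signature m-mers (length <= 31).
#' @param B Number of bins, >= 1 (default 8192).
#' @return Integer vector of bin ids in `0:(B-1)`.
#' @export
job_key_to_partition_hash <- function(sig, B = 8192L) cpp_sig_bin(sig, B)

#' Estimate per-job k-mer workloads from a sample of the input
#'
#' Each record is independently retained with probability `fraction` under
#' a seeded generator; retained records are cleaned, split into superkmers,
#' and every job key (signature, or hashed bin id) accumulates the k-mer
#' count its superkmers carry. Accumulated counts are divided by `fraction`,
#' giving an unbiased estimate of the full-data job sizes. `fraction = 1`
#' is an exact census.
#'
#' @param records Record data.frame (`id`, `seq`).
#' @param k,m k-mer and signature lengths.
#' @param fraction Sampling fraction in (0, 1]; the pipeline default is 0.01.
#' @param seed Integer seed for the record-retention draws.
#' @param granularity `"signature"` (one job per signature, the default) or
#'   `"bin"` (signatures hashed into `B` bins).
#' @param B Number of bins when `granularity = "bin"`.
#' @return A `job_size_map`: list with `sizes` (named numeric vector of
#'   estimated k-mer counts per job key), `granularity`, `fraction`.
#' @export
estimate_job_sizes <- function(records, k, m, fraction = 0.01, seed = 1L,
                               granularity = c("signature", "bin"),
                               B = 8192L) {
  granularity <- match.arg(granularity)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("sampling fraction must lie in (0, 1], got ", fraction)
  }
  n <- nrow(records)
  keep <- if (n) withr::with_seed(seed, runif(n) < fraction) else logical()
  sk <- superkmers_of_records(records[keep, , drop = FALSE], k, m)
  sizes <- job_sizes_from_superkmers(sk, granularity, B)
  structure(list(sizes = sizes / fraction, granularity = granularity,
                 fraction = fraction),
            class = "job_size_map")
}

# Clean + split all records in one pass; returns the superkmer data.frame.
superkmers_of_records <- function(records, k, m) {
  frags <- unlist(lapply(records$seq, cpp_clean_fragments), use.names = FALSE)
  if (is.null(frags)) frags <- character()
  cpp_split_superkmers(frags, k, m)
}

job_sizes_from_superkmers <- function(sk, granularity, B) {
  if (nrow(sk) == 0L) return(stats::setNames(numeric(), character()))
  key <- job_keys(sk$signature, granularity, B)
  s <- tapply(sk$n_kmers, key, sum)
  stats::setNames(as.numeric(s), names(s))
}

# Job key of each superkmer: signature text, or hashed bin id as character.
job_keys <- function(signatures, granularity, B) {
  if (granularity == "signature") {
    signatures
  } else {
    as.character(cpp_sig_bin(signatures, B))
  }
}

#' Longest-processing-time schedule
#'
#' The LPT heuristic for multiprocessor scheduling: jobs are sorted by size
#' descending (ties broken by ascending job key, for determinism) and each
#' is assigned to the currently least-loaded partition (ties to the lowest
#' index). LPT's makespan is within `(4/3 - 1/(3t))` of the optimum.
#'
#' @param sizes A `job_size_map`, or a named numeric vector of job sizes.
#' @param t Number of partitions (machines), >= 1.
#' @return An `mps_schedule`: list with `assignment` (named integer vector,
#'   job key -> partition index in `0:(t-1)`), `t`, `loads` (per-partition
#'   totals), `makespan` (max load).
#' @examples
#' lpt_schedule(c(a = 5, b = 4, c = 3, d = 3, e = 3), t = 2)$makespan  # 10
#' @export
lpt_schedule <- function(sizes, t) {
  if (inherits(sizes, "job_size_map")) sizes <- sizes$sizes
  stopifnot(is.numeric(sizes))
  if (!is.numeric(t) || t < 1) stop("number of partitions t must be >= 1")
  t <- as.integer(t)
  keys <- names(sizes)
  if (is.null(keys) && length(sizes)) keys <- as.character(seq_along(sizes))
  ord <- order(-sizes, keys, method = "radix")
  loads <- numeric(t)
  assignment <- integer(length(sizes))
  for (i in ord) {
    j <- which.min(loads)
    assignment[i] <- j - 1L
    loads[j] <- loads[j] + sizes[i]
  }
  names(assignment) <- keys
  structure(list(assignment = assignment, t = t, loads = loads,
                 makespan = if (t) max(loads) else 0),
            class = "mps_schedule")
}

#' Baseline hash schedule
#'
#' The data-oblivious partitioner: each job key goes to
#' `mix64(key value) mod t`, ignoring job sizes. Signature keys are hashed
#' on their packed value, bin keys on the bin id.
#'
#' @inheritParams lpt_schedule
#' @param granularity `"signature"` or `"bin"` (controls how keys hash).
#' @return An `mps_schedule` (same shape as [lpt_schedule()]).
#' @export
hash_schedule <- function(sizes, t, granularity = c("signature", "bin")) {
  granularity <- match.arg(granularity)
  if (inherits(sizes, "job_size_map")) {
    granularity <- sizes$granularity
    sizes <- sizes$sizes
  }
  if (!is.numeric(t) || t < 1) stop("number of partitions t must be >= 1")
  t <- as.integer(t)
  keys <- names(sizes)
  part <- hash_partition_of(keys, granularity, t)
  loads <- numeric(t)
  for (j in seq_len(t)) loads[j] <- sum(sizes[part == j - 1L])
  structure(list(assignment = stats::setNames(part, keys), t = t,
                 loads = loads, makespan = if (t) max(loads) else 0),
            class = "mps_schedule")
}

# Hash fallback used for job keys never seen by the sampling pass.
hash_partition_of <- function(keys, granularity, t) {
  if (!length(keys)) return(integer())
  if (granularity == "signature") {
    cpp_sig_bin(keys, t)
  } else {
    cpp_int_bin(as.integer(keys), t)
  }
}

#' @export
print.mps_schedule <- function(x, ...) {
  cat("<mps_schedule> ", length(x$assignment), " job(s) on ", x$t,
      " partition(s); makespan ", format(x$makespan), "\n", sep = "")
  invisible(x)
}

#' Write a schedule as job_key<TAB>partition TSV
#'
#' @param schedule An `mps_schedule`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "mps_schedule"))
  a <- schedule$assignment
  ord <- order(names(a), method = "radix")
  writeLines(paste0(names(a)[ord], "\t", a[ord]), path)
  invisible(path)
}

#' Exact optimal makespan for small scheduling instances
#'
#' Pruned exhaustive search over all assignments; refuses instances beyond
#' 14 jobs or 4 machines. Serves as the oracle against which the LPT
#' heuristic's `(4/3 - 1/(3t))` guarantee is verified.
#'
#' @param sizes Numeric vector of job sizes (at most 14).
#' @param t Number of machines (at most 4).
#' @return The optimal makespan.
#' @examples
#' brute_force_opt(c(5, 4, 3, 3, 3), t = 2)  # 9
#' @export
brute_force_opt <- function(sizes, t) cpp_brute_force_opt(sizes, t)
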