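#' Pipeline configuration
#'
#' Bundles and validates the parameters of the two-stage counting run.
#' Defaults follow the tuned operating point for metagenomic read sets:
#' signature length `m = 10`, signature-granularity jobs scheduled by LPT,
#' `B = 8192` bins when bin granularity is selected, and a 1% sampling
#' fraction for the preliminary workload-estimation pass.
#'
#' @param k k-mer length, >= 4.
#' @param m Signature length, `3 <= m <= k` (default 10).
#' @param workers Number of partitions `p` (the LPT "machines"), >= 1.
#'   Guidance from cluster tuning is 2-4 tasks per core.
#' @param granularity Job granularity: `"signature"` (default; finest) or
#'   `"bin"` (signatures hashed into `B` bins first).
#' @param B Number of bins for bin granularity (default 8192).
#' @param partitioner `"lpt"` (default; size-aware schedule from sampled
#'   workloads) or `"hash"` (data-oblivious).
#' @param sample_fraction Sampling fraction in (0, 1] for the preliminary
#'   estimation stage (default 0.01).
#' @param seed Integer seed driving the sampling draws.
#' @param mode Count mode, `"canonical"` (default) or `"forward"`.
#' @param chunk_bases Target bases per stage-1 chunk.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(k, m = 10L, workers = 1L,
                            granularity = c("signature", "bin"), B = 8192L,
                            partitioner = c("lpt", "hash"),
                            sample_fraction = 0.01, seed = 1L,
                            mode = c("canonical", "forward"),
                            chunk_bases = 1e6) {
  granularity <- match.arg(granularity)
  partitioner <- match.arg(partitioner)
  mode <- match.arg(mode)
  if (!is.numeric(k) || k < 4) stop("k must be an integer >= 4")
  if (!is.numeric(m) || m < 3 || m > k) {
    stop("m must satisfy 3 <= m <= k (m=", m, ", k=", k, ")")
  }
  if (!is.numeric(workers) || workers < 1) stop("workers must be >= 1")
  if (!is.numeric(B) || B < 1) stop("B must be >= 1")
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 ||
      sample_fraction > 1) {
    stop("sample_fraction must lie in (0, 1]")
  }
  if (!is.numeric(chunk_bases) || chunk_bases < 1) {
    stop("chunk_bases must be >= 1")
  }
  structure(list(k = as.integer(k), m = as.integer(m),
                 workers = as.integer(workers), granularity = granularity,
                 B = as.integer(B), partitioner = partitioner,
                 sample_fraction = sample_fraction, seed = as.integer(seed),
                 mode = mode, chunk_bases = chunk_bases),
            class = "pipeline_config")
}

#' Run the two-stage k-mer counting pipeline
#'
#' Stage 1 splits cleaned sequence chunks into superkmers and routes each
#' by its job key (signature, or hashed bin) to a partition; the shuffle
#' regroups superkmers by partition; stage 2 counts each partition into a
#' hash table; the disjoint tables are merged and written as sorted TSV.
#' With the LPT partitioner a preliminary pass first estimates job sizes
#' from a sample of the records and solves the scheduling instance; job
#' keys absent from the sample fall back to the hash partitioner. The
#' output file is bit-identical for any number of workers and either
#' partitioner — balancing changes placement, never counts.
#'
#' @param config A [pipeline_config()].
#' @param input_paths Character vector of FASTA/FASTQ paths.
#' @param output_path Path of the sorted TSV to write.
#' @return A list: `distinct`, `total`, `partition_loads` (k-mers counted
#'   per partition), `schedule` (the `mps_schedule` used, or `NULL` for
#'   the hash partitioner), `timings` (seconds per stage), `table` (the
#'   merged `kmer_count_table`), `output_path`.
#' @export
run_pipeline <- function(config, input_paths, output_path) {
  stopifnot(inherits(config, "pipeline_config"))
  missing <- input_paths[!file.exists(input_paths)]
  if (length(missing)) stop("input file not found: ", missing[1])
  p <- config$workers

  t_read <- system.time({
    records <- do.call(rbind, lapply(input_paths, read_sequences))
  })[["elapsed"]]

  # Preliminary stage: sampled workload estimation + LPT schedule.
  schedule <- NULL
  t_prelim <- system.time({
    if (config$partitioner == "lpt") {
      est <- estimate_job_sizes(records, k = config$k, m = config$m,
                                fraction = config$sample_fraction,
                                seed = config$seed,
                                granularity = config$granularity,
                                B = config$B)
      schedule <- lpt_schedule(est, t = p)
    }
  })[["elapsed"]]

  # Stage 1: superkmer extraction per chunk, then routing by job key.
  t_stage1 <- system.time({
    chunks <- chunk_records(records, config$chunk_bases)
    sk <- do.call(rbind, lapply(chunks, superkmers_of_records,
                                k = config$k, m = config$m))
    if (is.null(sk)) {
      sk <- data.frame(seq = character(), signature = character(),
                       allowed = integer(), n_kmers = integer(),
                       fragment = integer())
    }
    key <- job_keys(sk$signature, config$granularity, config$B)
    if (config$partitioner == "lpt") {
      part <- unname(schedule$assignment[key])
      unseen <- is.na(part)
      if (any(unseen)) {
        part[unseen] <- hash_partition_of(key[unseen], config$granularity, p)
      }
    } else {
      part <- hash_partition_of(key, config$granularity, p)
    }
  })[["elapsed"]]

  # Shuffle: regroup superkmers by partition.
  t_shuffle <- system.time({
    buckets <- split(sk$seq, factor(part, levels = 0:(p - 1)))
  })[["elapsed"]]

  # Stage 2: per-partition hash-table counting, merge, sorted output.
  loads <- numeric(p)
  t_stage2 <- system.time({
    tables <- list()
    for (j in seq_len(p)) {
      if (!length(buckets[[j]])) next
      tab <- count_partition(buckets[[j]], k = config$k, mode = config$mode)
      loads[j] <- summarize_counts(tab)$total
      tables[[length(tables) + 1L]] <- tab
    }
    merged <- if (length(tables)) {
      merge_tables(tables)
    } else {
      new_count_table(stats::setNames(numeric(), character()),
                      k = config$k, mode = config$mode)
    }
    write_counts(merged, output_path)
  })[["elapsed"]]

  s <- summarize_counts(merged)
  list(distinct = s$distinct, total = s$total, partition_loads = loads,
       schedule = schedule,
       timings = c(read = t_read, preliminary = t_prelim, stage1 = t_stage1,
                   shuffle = t_shuffle, stage2 = t_stage2),
       table = merged, output_path = output_path)
}
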