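test_that("mix64 fixes zero, matches the frozen finalizer value, and is uniform", {
  expect_equal(mix64(strrep("0", 16)), strrep("0", 16))
  # independently evaluated xorshift-multiply chain at x = 1
  expect_equal(mix64("0000000000000001"), "5692161d100b05e5")

  buckets <- skmercount:::cpp_mix64_mod(as.numeric(0:99999), 64L)
  tab <- tabulate(buckets + 1L, nbins = 64L)
  chi <- stats::chisq.test(tab, p = rep(1 / 64, 64))
  expect_gt(chi$p.value, 0.01)
})

test_that("signature-to-bin hashing is deterministic and spreads load", {
  sig <- "ACGTACGTAC"
  expect_equal(job_key_to_partition_hash(sig, B = 1L), 0L)
  expect_equal(job_key_to_partition_hash(sig, B = 8192L),
               job_key_to_partition_hash(sig, B = 8192L))
  expect_error(job_key_to_partition_hash(sig, B = 0L), ">= 1")

  withr::local_seed(67)
  sigs <- random_mmers(1e5, 10)
  bins <- job_key_to_partition_hash(sigs, B = 8192L)
  expect_true(all(bins >= 0L & bins < 8192L))
  load <- tabulate(bins + 1L, nbins = 8192L)
  expect_lt(max(load) / mean(load), 3)
})

test_that("job-size estimation at fraction 1 is an exact census", {
  f <- withr::local_tempfile(fileext = ".fa")
  generate_uniform(f, n_records = 50, read_length = 120, seed = 71,
                   ambiguity_rate = 0.02)
  recs <- read_fasta(f)
  est <- estimate_job_sizes(recs, k = 21, m = 7, fraction = 1, seed = 5)
  # census totals must equal the naive count of all windows
  s <- summarize_counts(naive_count(recs, 21))
  expect_equal(sum(est$sizes), s$total)
  # and per-signature sizes must match a direct full decomposition
  sk <- do.call(rbind, lapply(recs$seq, function(x)
    split_superkmers(clean_fragments(x), 21, 7)))
  direct <- tapply(sk$n_kmers, sk$signature, sum)
  expect_equal(est$sizes[order(names(est$sizes))],
               stats::setNames(as.numeric(direct), names(direct)))

  empty <- estimate_job_sizes(recs[0, ], k = 21, m = 7, fraction = 0.5)
  expect_length(empty$sizes, 0L)
  expect_error(estimate_job_sizes(recs, 21, 7, fraction = 0), "\\(0, 1\\]")
  expect_error(estimate_job_sizes(recs, 21, 7, fraction = 1.5), "\\(0, 1\\]")
})

test_that("job-size estimation is seed-deterministic and scales by 1/fraction", {
  f <- withr::local_tempfile(fileext = ".fa")
  generate_uniform(f, n_records = 200, read_length = 100, seed = 73)
  recs <- read_fasta(f)
  a <- estimate_job_sizes(recs, k = 15, m = 5, fraction = 0.3, seed = 9)
  b <- estimate_job_sizes(recs, k = 15, m = 5, fraction = 0.3, seed = 9)
  expect_identical(a, b)
  # bin granularity keys fall in 0..B-1
  bb <- estimate_job_sizes(recs, k = 15, m = 5, fraction = 1,
                           granularity = "bin", B = 64L)
  expect_true(all(as.integer(names(bb$sizes)) %in% 0:63))
  expect_equal(sum(bb$sizes), summarize_counts(naive_count(recs, 15))$total)
})

test_that("LPT reproduces the classic gap instance and its degenerate cases", {
  s <- c(a = 5, b = 4, c = 3, d = 3, e = 3)
  lpt <- lpt_schedule(s, t = 2)
  expect_equal(lpt$makespan, 10)
  expect_equal(brute_force_opt(unname(s), t = 2), 9)
  expect_lte(10 / 9, 4 / 3 - 1 / 6)

  expect_equal(lpt_schedule(s, t = 1)$makespan, sum(s))
  expect_equal(lpt_schedule(c(x = 7, y = 7, z = 7), t = 5)$makespan, 7)
  expect_error(lpt_schedule(s, t = 0), ">= 1")
})

test_that("LPT respects the (4/3 - 1/(3t)) bound and load accounting", {
  withr::local_seed(79)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    t <- sample(1:4, 1)
    sizes <- stats::setNames(sample(1:100, n, replace = TRUE),
                             paste0("j", seq_len(n)))
    lpt <- lpt_schedule(sizes, t)
    opt <- brute_force_opt(unname(sizes), t)
    expect_lte(lpt$makespan, (4 / 3 - 1 / (3 * t)) * opt + 1e-9)
    expect_gte(lpt$makespan, max(max(sizes), sum(sizes) / t) - 1e-9)
    expect_equal(sum(lpt$loads), sum(sizes))
    expect_true(all(lpt$assignment >= 0L & lpt$assignment < t))
    # per-partition loads agree with the assignment
    by_part <- tapply(sizes[names(lpt$assignment)], lpt$assignment, sum)
    expect_equal(as.numeric(by_part),
                 lpt$loads[as.integer(names(by_part)) + 1L])
  }
})

test_that("LPT beats the size-oblivious hash partitioner on skewed jobs", {
  withr::local_seed(83)
  keys <- unique(random_mmers(40, 10))
  sizes <- stats::setNames(sample(10:50, length(keys), TRUE), keys)
  sizes[1] <- round(0.3 / 0.7 * sum(sizes[-1]))  # one job = 30% of mass
  lpt <- lpt_schedule(sizes, t = 8)
  hsh <- hash_schedule(sizes, t = 8, granularity = "signature")
  expect_lte(lpt$makespan, hsh$makespan)
})

test_that("brute-force MPS oracle handles base cases and refuses big instances", {
  expect_equal(brute_force_opt(42, t = 3), 42)
  expect_equal(brute_force_opt(rep(5, 8), t = 4), 10)  # symmetric split
  expect_equal(brute_force_opt(numeric(), t = 2), 0)
  expect_error(brute_force_opt(rep(1, 15), t = 2), "too large")
  expect_error(brute_force_opt(rep(1, 5), t = 5), "too large")
})

test_that("schedules serialize as job_key TAB partition", {
  s <- lpt_schedule(c(b = 2, a = 5), t = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(s, f)
  lines <- readLines(f)
  expect_match(lines, "^[ab]\t[01]$")
  expect_equal(sub("\t.*", "", lines), c("a", "b"))  # key-sorted
})
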