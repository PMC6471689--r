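#' Is an m-mer an allowed signature?
#'
#' Allowed m-mers do not start with `AAA` or `ACA` and do not contain `AA`
#' anywhere except at their very beginning. The filter discourages the most
#' frequent low-lexicographic minimizers from monopolising partitions.
#'
#' @param mmer Character vector of A/C/G/T strings of length >= 3.
#' @return Logical vector.
#' @examples
#' is_allowed(c("AAAT", "ACAG", "TCAA", "AATC"))
#' @export
is_allowed <- function(mmer) cpp_is_allowed(mmer)

#' Signature of a k-mer
#'
#' Among the `k - m + 1` m-mers of the k-mer, each taken in canonical form
#' (minimum of itself and its reverse complement), the signature is the
#' lexicographically smallest canonical m-mer passing [is_allowed()]. When
#' no window is allowed (e.g. a poly-A k-mer) the smallest canonical m-mer
#' is used as a deterministic fallback and flagged `allowed = FALSE`.
#'
#' @param kmer A/C/G/T character scalar.
#' @param m Signature length, `3 <= m <= nchar(kmer)`.
#' @return A list with `mmer` (the signature string, canonical) and
#'   `allowed` (logical).
#' @export
signature_of <- function(kmer, m) cpp_signature_of(kmer, m)

#' Split a raw sequence into clean A/C/G/T fragments
#'
#' Uppercases, then splits at every character outside A/C/G/T (N and other
#' ambiguity codes). Fragments shorter than k simply carry no k-mers and
#' are dropped by downstream consumers.
#'
#' @param seq Raw sequence string (any case, ambiguity codes permitted).
#' @return Character vector of A/C/G/T fragments (possibly empty).
#' @examples
#' clean_fragments("ACGTNNacgt")
#' @export
clean_fragments <- function(seq) cpp_clean_fragments(seq)

#' Split a fragment into superkmers
#'
#' Scans the fragment's k-mers left to right and merges consecutive k-mers
#' whose signatures are equal into one superkmer; a new superkmer starts
#' exactly where the signature changes, so adjacent superkmers overlap by
#' `k - 1` bases. This is a variant of minimum substring partitioning: the
#' sum of `n_kmers` over superkmers always equals `nchar(fragment) - k + 1`.
#'
#' @param fragment A/C/G/T string (use [clean_fragments()] first).
#' @param k k-mer length.
#' @param m Signature length, `3 <= m <= k`.
#' @return A data.frame with one row per superkmer: `seq`, `signature`
#'   (canonical m-mer), `allowed`, `n_kmers`, `fragment` (input index).
#'   Fragments shorter than k yield zero rows.
#' @examples
#' split_superkmers("ACGTACGTACGT", k = 8, m = 4)
#' @export
split_superkmers <- function(fragment, k, m) {
  df <- cpp_split_superkmers(fragment, k, m)
  df$allowed <- as.logical(df$allowed)
  df
}
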