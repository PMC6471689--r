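#' 2-bit packed DNA sequences
#'
#' A `packed_seq` stores a DNA string at two bits per base (A=0, C=1, G=2,
#' T=3) across 64-bit words holding 31 bases each; the most significant bit
#' of every word stays zero (sign bit reserved) and the last word is
#' left-padded with zero bits. The chosen code preserves lexicographic order,
#' so comparing packed words of equal-length sequences as integers agrees
#' with comparing the strings. Words are surfaced in R as 16-digit
#' hexadecimal strings, which represent the full 64 bits exactly.
#'
#' @param seq A non-empty character scalar over A/C/G/T.
#' @return An object of class `packed_seq`: a list with `words` (character
#'   vector of 16-hex-digit 64-bit words) and `length` (number of bases).
#' @examples
#' p <- pack_seq("ACGT")
#' unpack_seq(p)
#' @seealso [unpack_seq()], [reverse_complement()], [canonical()]
#' @export
pack_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  p <- cpp_pack(seq)
  structure(list(words = p$words, length = p$length), class = "packed_seq")
}

#' Decode a packed sequence back to text
#'
#' Inverse of [pack_seq()]. The word count must equal `ceiling(length / 31)`
#' and all padding bits must be zero; any mismatch raises a corruption error.
#'
#' @param p A `packed_seq` object.
#' @return The decoded A/C/G/T character scalar.
#' @export
unpack_seq <- function(p) {
  stopifnot(inherits(p, "packed_seq"))
  cpp_unpack(p$words, p$length)
}

#' @export
print.packed_seq <- function(x, ...) {
  cat("<packed_seq> ", x$length, " bases in ", length(x$words),
      " word(s)\n", sep = "")
  invisible(x)
}

#' @export
length.packed_seq <- function(x) x$length

#' Encode a single base as its 2-bit code
#'
#' @param base Character vector of single bases from A/C/G/T.
#' @return Integer vector of codes: A=0, C=1, G=2, T=3.
#' @examples
#' encode_symbol(c("A", "T"))
#' @export
encode_symbol <- function(base) cpp_encode_symbol(base)

#' Reverse complement
#'
#' Reverses the sequence and swaps A with T and C with G. Accepts either a
#' character vector of A/C/G/T strings or a `packed_seq`, returning the same
#' type.
#'
#' @param seq Character vector or `packed_seq`.
#' @return The reverse complement, same type as the input.
#' @examples
#' reverse_complement("AAAC")
#' @export
reverse_complement <- function(seq) {
  if (inherits(seq, "packed_seq")) {
    pack_seq(cpp_revcomp(unpack_seq(seq)))
  } else {
    cpp_revcomp(seq)
  }
}

#' Canonical form of a sequence
#'
#' The lexicographic minimum (A<C<G<T) of a sequence and its reverse
#' complement: the strand-neutral representative used both for signatures
#' and for canonical-mode k-mer counts.
#'
#' @param seq Character vector or `packed_seq`.
#' @return Canonical form, same type as the input.
#' @examples
#' canonical("TTT")   # "AAA"
#' canonical("ACGT")  # palindrome, unchanged
#' @export
canonical <- function(seq) {
  if (inherits(seq, "packed_seq")) {
    pack_seq(cpp_canonical(unpack_seq(seq)))
  } else {
    cpp_canonical(seq)
  }
}
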