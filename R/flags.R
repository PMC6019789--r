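#' Standard SAM flag bits
#'
#' Named integer vector mapping the 12 standard SAM flag bit names to their
#' powers of two. Names follow common samtools usage: `paired` (0x1),
#' `proper_pair` (0x2), `unmapped` (0x4), `mate_unmapped` (0x8), `reverse`
#' (0x10), `mate_reverse` (0x20), `first_in_template` (0x40),
#' `second_in_template` (0x80), `secondary` (0x100), `qc_fail` (0x200),
#' `duplicate` (0x400), `supplementary` (0x800).
#'
#' @format Named integer vector of length 12.
#' @export
sam_flag_bits <- c(
  paired             = 0x1L,
  proper_pair        = 0x2L,
  unmapped           = 0x4L,
  mate_unmapped      = 0x8L,
  reverse            = 0x10L,
  mate_reverse       = 0x20L,
  first_in_template  = 0x40L,
  second_in_template = 0x80L,
  secondary          = 0x100L,
  qc_fail            = 0x200L,
  duplicate          = 0x400L,
  supplementary      = 0x800L
)

#' Encode SAM flag bit names as an integer flag
#'
#' Combines a set of standard SAM flag bit names into the corresponding
#' integer flag value (bitwise OR of the named powers of two). For example,
#' a read that is paired, mapped in a proper pair to the reverse strand, and
#' is the first segment in the template carries flag
#' `0x1 + 0x2 + 0x10 + 0x40 = 83`.
#'
#' @param names Character vector (possibly empty) of flag bit names; see
#'   [sam_flag_bits] for the valid names.
#' @return Integer scalar flag value. Inverse of [decode_flag()].
#' @examples
#' encode_flag(c("paired", "proper_pair", "reverse", "first_in_template"))
#' @export
encode_flag <- function(names) {
  names <- as.character(names)
  unknown <- setdiff(names, base::names(sam_flag_bits))
  if (length(unknown) > 0L) {
    stop_validation("unknown SAM flag bit name(s): ",
                    paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names)) {
    names <- unique(names)
  }
  sum(sam_flag_bits[names], 0L)
}

#' Decode an integer SAM flag into bit names
#'
#' @param flag Integer scalar in `[0, 2^16)`.
#' @return Character vector of the names of the set bits (among the 12
#'   standard bits), in bit order. Inverse of [encode_flag()].
#' @examples
#' decode_flag(83)
#' @export
decode_flag <- function(flag) {
  if (length(flag) != 1L || is.na(flag) || flag < 0 || flag >= 2^16 ||
      flag != trunc(flag)) {
    stop_validation("flag must be a single integer in [0, 65536)")
  }
  flag <- as.integer(flag)
  names(sam_flag_bits)[bitwAnd(flag, sam_flag_bits) != 0L]
}

#' Parse a flag value given in decimal or 0x-hexadecimal notation
#'
#' Both notations are in common use ("83" and "0x10" denote the same kind of
#' quantity); this helper accepts either.
#'
#' @param x Character or numeric scalar, e.g. `"83"`, `"0x53"`, `83`.
#' @return Integer flag value.
#' @export
parse_flag_value <- function(x) {
  if (is.numeric(x)) {
    val <- x
  } else {
    x <- trimws(as.character(x))
    val <- if (grepl("^0[xX]", x)) strtoi(sub("^0[xX]", "", x), base = 16L)
           else suppressWarnings(as.integer(x))
  }
  if (length(val) != 1L || is.na(val) || val < 0 || val >= 2^16) {
    stop_validation("cannot parse flag value: ", deparse(x))
  }
  as.integer(val)
}

# Vectorized bit test used throughout: TRUE where `bit` is set in `flag`.
flag_has_bit <- function(flag, bit) {
  bitwAnd(as.integer(flag), as.integer(bit)) != 0L
}
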