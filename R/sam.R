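# SAM text record handling. Alignment records travel through the package as
# a plain data.frame with one row per record and the 11 mandatory SAM
# columns plus a `tags` column holding the optional-field block serialized
# exactly as in SAM text (TAG:TYPE:VALUE, tab-joined, original order; "" if
# none). This representation is lossless: format_sam_lines(parse_sam_lines(x))
# reproduces the input bytes.

SAM_COLUMNS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "rnext", "pnext", "tlen", "seq", "qual")

#' Parse SAM-format alignment lines into a record data frame
#'
#' @param lines Character vector of tab-separated SAM alignment lines
#'   (no header lines).
#' @return A data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual` and `tags`
#'   (the optional fields tab-joined, `""` when absent). `flag`, `pos`,
#'   `mapq` and `tlen` are integer.
#' @export
parse_sam_lines <- function(lines) {
  if (length(lines) == 0L) return(empty_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 11L)
  if (length(bad) > 0L) {
    stop_parse("malformed SAM record at line ", bad[1L], ": expected >= 11 ",
               "tab-separated columns, found ", nf[bad[1L]])
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  tags <- vapply(parts, function(p) {
    if (length(p) > 11L) paste(p[-seq_len(11L)], collapse = "\t") else ""
  }, character(1))
  df <- data.frame(
    qname = col(1L),
    flag  = as.integer(col(2L)),
    rname = col(3L),
    pos   = as.integer(col(4L)),
    mapq  = as.integer(col(5L)),
    cigar = col(6L),
    rnext = col(7L),
    pnext = as.integer(col(8L)),
    tlen  = as.integer(col(9L)),
    seq   = col(10L),
    qual  = col(11L),
    tags  = tags,
    stringsAsFactors = FALSE
  )
  if (anyNA(df$flag) || anyNA(df$pos) || anyNA(df$tlen)) {
    stop_parse("malformed SAM record: non-numeric FLAG, POS or TLEN")
  }
  df
}

#' Serialize a record data frame back to SAM text lines
#'
#' @param records Record data.frame as produced by [parse_sam_lines()].
#' @return Character vector, one SAM line per record.
#' @export
format_sam_lines <- function(records) {
  if (nrow(records) == 0L) return(character(0))
  core <- do.call(paste, c(unname(as.list(records[SAM_COLUMNS])), sep = "\t"))
  ifelse(records$tags == "", core, paste(core, records$tags, sep = "\t"))
}

empty_records <- function() {
  data.frame(
    qname = character(0), flag = integer(0), rname = character(0),
    pos = integer(0), mapq = integer(0), cigar = character(0),
    rnext = character(0), pnext = integer(0), tlen = integer(0),
    seq = character(0), qual = character(0), tags = character(0),
    stringsAsFactors = FALSE
  )
}

# TRUE where a record carries an optional tag with the given two-letter name.
has_tag <- function(records, tag) {
  grepl(paste0("(^|\t)", tag, ":"), records$tags)
}
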