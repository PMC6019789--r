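#' Construct a filter specification
#'
#' A `filter_spec` bundles every per-record criterion of a filter job. Each
#' criterion is optional; an absent criterion never excludes a record, so
#' the empty spec is the identity filter. Criteria are combined with AND.
#'
#' Template-length bounds apply to the magnitude `|TLEN|`, so the leftmost
#' and rightmost mate of a pair (which carry opposite TLEN signs) receive
#' the same verdict. `seq_pattern` is a plain, case-insensitive nucleotide
#' substring (not a regex). `cigar_regex` must match the *entire* CIGAR
#' string (it is anchored at both ends), so `"[0-9]+M"` means a single
#' full-length match segment and nothing else. `tag_regex` is matched
#' against the optional fields serialized exactly as SAM columns
#' (`TAG:TYPE:VALUE`, tab-joined, original order). Records with CIGAR `"*"`
#' or the unmapped bit set fail any CIGAR or region criterion but remain
#' eligible under flag-only filters.
#'
#' @param mapq_min Minimum mapping quality (inclusive), or `NULL`.
#' @param flag_required Integer bitmask; every set bit must be present in
#'   the record flag. Accepts decimal or `"0x"` hex notation.
#' @param flag_excluded Integer bitmask; no set bit may be present. Must be
#'   disjoint from `flag_required`.
#' @param tlen_min,tlen_max Bounds (inclusive, base pairs) on `|TLEN|`.
#' @param seq_pattern Nucleotide pattern over `{A,C,G,T,N}` that SEQ must
#'   contain as a substring (case-insensitive).
#' @param cigar_regex Regular expression the CIGAR string must fully match.
#' @param tag_regex Regular expression matched against the serialized
#'   optional-tag block.
#' @param regions Region constraint: a data.frame with columns `chrom`,
#'   `start`, `end` (1-based, inclusive), or a character vector of
#'   `"chrom:start-end"` strings, or `NULL` / empty for whole genome.
#' @param samples Character vector of individual IDs to restrict the job
#'   to, or `NULL` for all.
#' @param populations Character vector of population or superpopulation
#'   codes (resolved against the job manifest; a `"nonX"` code selects the
#'   complement of `"X"`), or `NULL` for all.
#' @return An object of class `filter_spec`.
#' @examples
#' filter_spec(flag_required = 83, regions = "1:1-1000000",
#'             seq_pattern = "ACGT")
#' @seealso [matches_filter()], [in_regions()]
#' @export
filter_spec <- function(mapq_min = NULL, flag_required = NULL,
                        flag_excluded = NULL, tlen_min = NULL,
                        tlen_max = NULL, seq_pattern = NULL,
                        cigar_regex = NULL, tag_regex = NULL,
                        regions = NULL, samples = NULL,
                        populations = NULL) {
  chk_int <- function(x, what, min = NULL) {
    if (is.null(x)) return(NULL)
    x <- if (is.character(x)) parse_flag_value(x) else x
    if (length(x) != 1L || is.na(x) || x != trunc(x)) {
      stop_validation(what, " must be a single integer")
    }
    if (!is.null(min) && x < min) {
      stop_validation(what, " must be >= ", min)
    }
    as.integer(x)
  }
  chk_regex <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != 1L || is.na(x)) stop_validation(what, " must be a string")
    ok <- tryCatch({ grepl(x, ""); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_validation("malformed regular expression in ", what, ": ", x)
    as.character(x)
  }

  mapq_min <- chk_int(mapq_min, "mapq_min", min = 0L)
  flag_required <- if (is.null(flag_required)) NULL else parse_flag_value(flag_required)
  flag_excluded <- if (is.null(flag_excluded)) NULL else parse_flag_value(flag_excluded)
  if (!is.null(flag_required) && !is.null(flag_excluded) &&
      bitwAnd(flag_required, flag_excluded) != 0L) {
    stop_validation("flag_required and flag_excluded share set bits: ",
                    bitwAnd(flag_required, flag_excluded))
  }
  tlen_min <- chk_int(tlen_min, "tlen_min")
  tlen_max <- chk_int(tlen_max, "tlen_max")
  if (!is.null(tlen_min) && !is.null(tlen_max) && tlen_min > tlen_max) {
    stop_validation("tlen_min (", tlen_min, ") exceeds tlen_max (", tlen_max, ")")
  }
  if (!is.null(seq_pattern)) {
    seq_pattern <- toupper(as.character(seq_pattern))
    if (length(seq_pattern) != 1L || !grepl("^[ACGTN]+$", seq_pattern)) {
      stop_validation("seq_pattern must be a nonempty string over A,C,G,T,N")
    }
  }
  cigar_regex <- chk_regex(cigar_regex, "cigar_regex")
  tag_regex <- chk_regex(tag_regex, "tag_regex")
  regions <- as_regions(regions)
  if (!is.null(samples)) samples <- unique(as.character(samples))
  if (!is.null(populations)) populations <- unique(as.character(populations))

  structure(
    list(mapq_min = mapq_min, flag_required = flag_required,
         flag_excluded = flag_excluded, tlen_min = tlen_min,
         tlen_max = tlen_max, seq_pattern = seq_pattern,
         cigar_regex = cigar_regex, tag_regex = tag_regex,
         regions = regions, samples = samples, populations = populations),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    if (nm == "regions") {
      cat("  regions:", paste(format_region(v), collapse = ", "), "\n")
    } else {
      cat("  ", nm, ": ", paste(v, collapse = ","), "\n", sep = "")
    }
  }
  invisible(x)
}

# Normalize the accepted region notations to a validated data.frame
# (chrom, start, end), or NULL when unconstrained.
as_regions <- function(regions) {
  if (is.null(regions) || length(regions) == 0L) return(NULL)
  if (is.character(regions)) regions <- parse_region(regions)
  if (!is.data.frame(regions) ||
      !all(c("chrom", "start", "end") %in% names(regions))) {
    stop_validation("regions must be a chrom/start/end data.frame or ",
                    "\"chrom:start-end\" strings")
  }
  regions <- data.frame(chrom = as.character(regions$chrom),
                        start = as.numeric(regions$start),
                        end = as.numeric(regions$end),
                        stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(NULL)
  if (anyNA(regions$start) || anyNA(regions$end) ||
      any(regions$start < 1) || any(regions$start > regions$end)) {
    stop_validation("every region needs 1 <= start <= end")
  }
  regions
}

#' Parse "chrom:start-end" region strings
#'
#' @param x Character vector like `"1:1-1000000"`. Commas in numbers are
#'   allowed and ignored.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop_validation("malformed region string: ", x[bad][1L],
                    " (expected chrom:start-end)")
  }
  data.frame(
    chrom = vapply(m, `[[`, character(1), 2L),
    start = as.numeric(gsub(",", "", vapply(m, `[[`, character(1), 3L))),
    end   = as.numeric(gsub(",", "", vapply(m, `[[`, character(1), 4L))),
    stringsAsFactors = FALSE
  )
}

format_region <- function(regions) {
  sprintf("%s:%d-%d", regions$chrom, as.integer(regions$start),
          as.integer(regions$end))
}

#' Test records against a region constraint
#'
#' A record belongs to a region iff its leftmost position (POS) lies inside
#' the 1-based inclusive interval on the matching chromosome
#' (start-containment, not read-overlap). An empty constraint admits every
#' record; unmapped records (unmapped bit set or POS 0) fail any non-empty
#' constraint.
#'
#' @param records Record data.frame (see [parse_sam_lines()]).
#' @param regions Regions in any form accepted by [filter_spec()].
#' @return Logical vector, one verdict per record.
#' @export
in_regions <- function(records, regions) {
  regions <- as_regions(regions)
  if (is.null(regions)) return(rep(TRUE, nrow(records)))
  ok <- rep(FALSE, nrow(records))
  mapped <- !flag_has_bit(records$flag, 0x4L) & records$pos > 0L
  for (i in seq_len(nrow(regions))) {
    ok <- ok | (mapped &
                records$rname == regions$chrom[i] &
                records$pos >= regions$start[i] &
                records$pos <= regions$end[i])
  }
  ok
}

#' Evaluate a filter specification against alignment records
#'
#' Applies every present criterion of `spec` (see [filter_spec()]) to each
#' record; a record matches iff all present criteria hold. Sample and
#' population subsetting are file-level criteria resolved by the engine and
#' are not evaluated here.
#'
#' @param records Record data.frame.
#' @param spec A [filter_spec()].
#' @return Logical vector, one verdict per record.
#' @export
matches_filter <- function(records, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- nrow(records)
  keep <- rep(TRUE, n)
  if (n == 0L) return(keep)
  unmapped <- flag_has_bit(records$flag, 0x4L)

  if (!is.null(spec$mapq_min)) {
    keep <- keep & records$mapq >= spec$mapq_min
  }
  if (!is.null(spec$flag_required)) {
    keep <- keep & bitwAnd(records$flag, spec$flag_required) == spec$flag_required
  }
  if (!is.null(spec$flag_excluded)) {
    keep <- keep & bitwAnd(records$flag, spec$flag_excluded) == 0L
  }
  if (!is.null(spec$tlen_min)) {
    keep <- keep & abs(records$tlen) >= spec$tlen_min
  }
  if (!is.null(spec$tlen_max)) {
    keep <- keep & abs(records$tlen) <= spec$tlen_max
  }
  if (!is.null(spec$seq_pattern)) {
    keep <- keep & grepl(spec$seq_pattern, toupper(records$seq), fixed = TRUE)
  }
  if (!is.null(spec$cigar_regex)) {
    full <- paste0("^(?:", spec$cigar_regex, ")$")
    keep <- keep & !unmapped & records$cigar != "*" &
      grepl(full, records$cigar, perl = TRUE)
  }
  if (!is.null(spec$tag_regex)) {
    keep <- keep & grepl(spec$tag_regex, records$tags, perl = TRUE)
  }
  if (!is.null(spec$regions)) {
    keep <- keep & in_regions(records, spec$regions)
  }
  keep
}

#' Read / write a filter specification as a flat config mapping
#'
#' The config is a flat YAML mapping whose keys mirror the [filter_spec()]
#' arguments (`regions` as a list of `"chrom:start-end"` strings; `samples`
#' and `populations` as lists). The same keys are exposed as CLI flags.
#'
#' @param path Config file path.
#' @return `read_filter_spec()` returns a `filter_spec`;
#'   `write_filter_spec()` returns `path` invisibly.
#' @export
read_filter_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("mapq_min", "flag_required", "flag_excluded", "tlen_min",
             "tlen_max", "seq_pattern", "cigar_regex", "tag_regex",
             "regions", "samples", "populations")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop_validation("unknown filter config key(s): ",
                    paste(extra, collapse = ", "))
  }
  cfg <- cfg[intersect(known, names(cfg))]
  if (!is.null(cfg$regions)) cfg$regions <- unlist(cfg$regions)
  do.call(filter_spec, cfg)
}

#' @rdname read_filter_spec
#' @param spec A `filter_spec` to serialize.
#' @export
write_filter_spec <- function(spec, path) {
  stopifnot(inherits(spec, "filter_spec"))
  out <- spec[!vapply(spec, is.null, logical(1))]
  if (!is.null(out$regions)) out$regions <- format_region(out$regions)
  yaml::write_yaml(lapply(unclass(out), function(v)
    if (is.numeric(v)) unname(v) else as.character(v)), path)
  invisible(path)
}
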