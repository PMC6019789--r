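# BAM decoding and encoding go through htslib: `samtools view` for decoding
# (the only route that surfaces *every* optional tag verbatim, which the
# tag predicates and round-trip guarantees need) and Rsamtools::asBam for
# SAM -> coordinate-sorted, indexed BAM.

samtools_path <- function() {
  p <- Sys.which("samtools")
  if (!nzchar(p)) stop_io("samtools not found on PATH", retryable = FALSE)
  unname(p)
}

run_samtools <- function(args) {
  out <- suppressWarnings(
    system2(samtools_path(), args, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    msg <- paste(out, collapse = "; ")
    if (grepl("fail to open|failed to open|No such file|Could not|not found|unable",
              msg, ignore.case = TRUE)) {
      stop_io("cannot read alignment source: ", msg)
    }
    stop_parse("samtools failed (", status, "): ", msg)
  }
  as.character(out)
}

#' Describe a pluggable alignment data source
#'
#' A data source is a local path, an HTTP(S) URL or an FTP URL pointing at a
#' BAM file. Random access (region queries) requires a reachable index; for
#' local files the `.bai` sidecar is detected automatically, for URLs the
#' index is fetched by htslib on demand. Region requests against a source
#' without an index are rejected, never silently degraded to a full scan.
#'
#' @param locator Path or URL of the BAM file.
#' @param kind One of `"local-path"`, `"http-url"`, `"ftp-url"`; inferred
#'   from `locator` when omitted.
#' @return An object of class `data_source`.
#' @export
data_source <- function(locator, kind = NULL) {
  if (length(locator) != 1L || !nzchar(locator)) {
    stop_validation("data source locator must be a nonempty string")
  }
  if (is.null(kind)) {
    kind <- if (grepl("^https?://", locator)) "http-url"
            else if (grepl("^ftp://", locator)) "ftp-url"
            else "local-path"
  }
  kind <- match.arg(kind, c("local-path", "http-url", "ftp-url"))
  ra <- if (kind == "local-path") {
    file.exists(paste0(locator, ".bai")) ||
      file.exists(sub("\\.bam$", ".bai", locator))
  } else {
    NA  # resolved on demand by htslib
  }
  structure(list(kind = kind, locator = locator,
                 supports_random_access = ra),
            class = "data_source")
}

as_data_source <- function(x) {
  if (inherits(x, "data_source")) x else data_source(x)
}

#' @export
print.data_source <- function(x, ...) {
  cat("<data_source ", x$kind, "> ", x$locator,
      if (isTRUE(x$supports_random_access)) " [indexed]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Stream alignment records from a data source
#'
#' Decodes the BAM file behind `source` into a record data.frame, either
#' whole-file (in file order) or restricted to regions. Region fetches use
#' the BAM index and are post-filtered to start-containment semantics (a
#' record belongs to a region iff its POS lies inside it; see
#' [in_regions()]), so the result equals a full scan filtered by
#' `in_regions()`. A record whose POS lies in several requested regions is
#' yielded once, for the first such region.
#'
#' @param source A [data_source()], or a path/URL coerced to one.
#' @param regions Regions in any form accepted by [filter_spec()]; `NULL`
#'   for the whole file.
#' @return Record data.frame; attribute `bytes_streamed` carries the number
#'   of bytes pulled from the source (compressed file size for a whole-file
#'   local stream, decoded text size otherwise).
#' @export
stream_alignments <- function(source, regions = NULL) {
  source <- as_data_source(source)
  regions <- as_regions(regions)
  if (is.null(regions)) {
    lines <- run_samtools(c("view", source$locator))
    recs <- parse_sam_lines(lines)
    bytes <- if (source$kind == "local-path") file.size(source$locator)
             else sum(nchar(lines, type = "bytes")) + length(lines)
    attr(recs, "bytes_streamed") <- as.numeric(bytes)
    return(recs)
  }
  if (isFALSE(source$supports_random_access)) {
    stop_validation("region query against non-indexed source: ",
                    source$locator)
  }
  chunks <- vector("list", nrow(regions))
  bytes <- 0
  for (i in seq_len(nrow(regions))) {
    lines <- run_samtools(c("view", source$locator, format_region(regions[i, ])))
    bytes <- bytes + sum(nchar(lines, type = "bytes")) + length(lines)
    recs <- parse_sam_lines(lines)
    keep <- in_regions(recs, regions[i, , drop = FALSE])
    if (i > 1L) {
      # yield each record for the first region containing its start only
      keep <- keep & !in_regions(recs, regions[seq_len(i - 1L), , drop = FALSE])
    }
    chunks[[i]] <- recs[keep, , drop = FALSE]
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  attr(out, "bytes_streamed") <- bytes
  out
}

#' Read the header of a BAM source
#'
#' @param source A [data_source()] or path/URL.
#' @return Character vector of header lines (`@`-prefixed).
#' @export
read_bam_header <- function(source) {
  source <- as_data_source(source)
  run_samtools(c("view", "-H", source$locator))
}

sq_header_lines <- function(seqlengths) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
}

#' Write alignment records to a coordinate-sorted, indexed BAM file
#'
#' @param records Record data.frame.
#' @param header Either a character vector of SAM header lines (as from
#'   [read_bam_header()]) or a named vector of chromosome lengths from
#'   which a minimal header is built.
#' @param destination Output BAM path (`.bam`); a `.bam.bai` index is
#'   written alongside.
#' @return Number of records written, invisibly.
#' @export
write_bam <- function(records, header, destination) {
  if (!is.character(header) || !any(startsWith(header, "@"))) {
    header <- sq_header_lines(header)
  }
  sq <- sub("\tLN:.*$", "", sub("^@SQ\tSN:", "", grep("^@SQ\t", header, value = TRUE)))
  sq <- sub("\t.*$", "", sq)
  mapped <- records$rname != "*"
  unknown <- setdiff(unique(records$rname[mapped]), sq)
  if (length(unknown) > 0L) {
    stop_validation("record references chromosome(s) absent from header: ",
                    paste(unknown, collapse = ", "))
  }
  tmp_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(tmp_sam), add = TRUE)
  writeLines(c(header, format_sam_lines(records)), tmp_sam)
  dest_prefix <- sub("\\.bam$", "", destination)
  Rsamtools::asBam(tmp_sam, dest_prefix, overwrite = TRUE,
                   indexDestination = TRUE)
  invisible(nrow(records))
}

#' Write records in individual alignment format (IAF)
#'
#' IAF is a header-free variant of SAM text in which every line is a
#' self-contained unit: the individual ID and region label lead, followed
#' by the 11 mandatory SAM columns and any optional tags, all tab-joined.
#'
#' @param records Record data.frame.
#' @param individual_id Individual the records belong to.
#' @param region_label Region string for the job (e.g. `"1:1-30000"`), or
#'   `"all"` when the job had no region constraint.
#' @param destination Output file path.
#' @return Number of records written. On a write failure the partial output
#'   file is removed.
#' @export
write_iaf <- function(records, individual_id, region_label, destination) {
  stopifnot(length(individual_id) == 1L, length(region_label) == 1L)
  lines <- if (nrow(records) == 0L) character(0) else
    paste(individual_id, region_label, format_sam_lines(records), sep = "\t")
  ok <- FALSE
  tryCatch({
    con <- file(destination, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con, sep = "\n")
    ok <- TRUE
  }, error = function(e) {
    stop_io("failed writing IAF to ", destination, ": ", conditionMessage(e))
  }, finally = {
    if (!ok && file.exists(destination)) unlink(destination)
  })
  nrow(records)
}

#' Read an individual-alignment-format file
#'
#' Inverse of [write_iaf()]: parsing then re-serializing reproduces the
#' input bytes, and `read_iaf(write_iaf(x))` recovers every field of `x`.
#'
#' @param source IAF file path, or a character vector of IAF lines.
#' @return Record data.frame with leading `individual_id` and
#'   `region_label` columns followed by the SAM record columns.
#' @export
read_iaf <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else as.character(source)
  if (length(lines) == 0L) {
    out <- cbind(data.frame(individual_id = character(0),
                            region_label = character(0),
                            stringsAsFactors = FALSE),
                 empty_records())
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 13L)
  if (length(bad) > 0L) {
    stop_parse("malformed IAF line ", bad[1L], ": expected >= 13 columns, ",
               "found ", nf[bad[1L]])
  }
  sam_lines <- vapply(parts, function(p)
    paste(p[-(1:2)], collapse = "\t"), character(1))
  recs <- parse_sam_lines(sam_lines)
  cbind(data.frame(individual_id = vapply(parts, `[[`, character(1), 1L),
                   region_label = vapply(parts, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE),
        recs)
}

#' Read / write a cohort sample manifest
#'
#' The manifest is a tab-separated table with columns `file`, `individual`,
#' `population`, `superpopulation`, one row per BAM file. Relative `file`
#' paths are resolved against the manifest's directory on read.
#'
#' @param path Manifest path.
#' @return `read_manifest()` returns the manifest data.frame (with resolved
#'   `file` paths); `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  need <- c("file", "individual", "population", "superpopulation")
  if (!all(need %in% names(m))) {
    stop_parse("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$individual)) {
    stop_validation("manifest individual IDs must be unique")
  }
  rel <- !grepl("^(/|[A-Za-z]+://)", m$file)
  m$file[rel] <- file.path(dirname(normalizePath(path)), m$file[rel])
  m
}

#' @rdname read_manifest
#' @param manifest Manifest data.frame to serialize.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
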