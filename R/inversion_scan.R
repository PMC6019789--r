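# Structural-variation scan over TLEN-reduced alignments. An inversion
# breakpoint flips one read of a pair, so both mates align to the same
# strand and the apparent template length is inflated by roughly the
# inverted span. The scan keeps same-strand pairs, discards impure
# alignments (CIGAR not a single full match, or with alternative-alignment
# XA tags), requires each alignment's (chromosome, kb-start, kb-TLEN) bin
# to be supported by at least `min_support` distinct individuals, and then
# summarizes the survivors as per-chromosome frequency matrices at Mb x
# 10 kb display resolution.

#' Same-strand read-pair predicate (inversion signature)
#'
#' A paired record whose own strand bit (0x10) equals its mate's strand bit
#' (0x20) — both forward or both reverse — is a candidate inversion
#' signature. Unpaired records are excluded (FALSE), not an error.
#'
#' @param records Record data.frame (or an integer vector of flags).
#' @return Logical vector.
#' @export
same_strand_pair <- function(records) {
  flag <- if (is.data.frame(records)) records$flag else as.integer(records)
  paired <- flag_has_bit(flag, 0x1L)
  paired & (flag_has_bit(flag, 0x10L) == flag_has_bit(flag, 0x20L))
}

#' Alignment-purity predicate
#'
#' TRUE for records whose CIGAR is a single full-length match segment
#' (digits followed by `M`, e.g. `"100M"`) and that carry no XA
#' (alternative alignment) tag.
#'
#' @param records Record data.frame.
#' @return Logical vector.
#' @export
is_clean_alignment <- function(records) {
  grepl("^[0-9]+M$", records$cigar) & !has_tag(records, "XA")
}

bin_key_of <- function(records, start_scale, tlen_scale) {
  if (start_scale <= 0 || tlen_scale <= 0) {
    stop_validation("bin scales must be positive")
  }
  # SAM POS is 1-based; bins are floor division on the 0-based coordinate.
  data.frame(
    chromosome = records$rname,
    start_bin = floor((records$pos - 1) / start_scale),
    tlen_bin = floor(abs(records$tlen) / tlen_scale),
    stringsAsFactors = FALSE
  )
}

#' Tabulate distinct-individual support per genomic bin
#'
#' Projects each record's start position and |TLEN| down to the given
#' scales and counts, per (chromosome, start bin, TLEN bin), the number of
#' distinct individuals with at least one record in the bin. Multiple
#' records of one individual in one bin count once.
#'
#' @param records IAF record data.frame (needs `individual_id`).
#' @param start_scale,tlen_scale Bin widths in base pairs (default 1 kb).
#' @return An object of class `support_table`: a data.frame with columns
#'   `chromosome`, `start_bin`, `tlen_bin`, `support` and a list column
#'   `individuals`.
#' @export
bin_alignments <- function(records, start_scale = 1000, tlen_scale = 1000) {
  key <- bin_key_of(records, start_scale, tlen_scale)
  if (nrow(records) == 0L) {
    tab <- cbind(key, data.frame(support = integer(0)))
    tab$individuals <- list()
  } else {
    id <- paste(key$chromosome, key$start_bin, key$tlen_bin, sep = "\r")
    inds <- split(records$individual_id, id)
    inds <- lapply(inds, unique)
    first <- !duplicated(id)
    tab <- key[first, , drop = FALSE]
    ord <- paste(tab$chromosome, tab$start_bin, tab$tlen_bin, sep = "\r")
    tab$support <- lengths(inds)[ord]
    tab$individuals <- inds[ord]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("support_table", "data.frame"),
            start_scale = start_scale, tlen_scale = tlen_scale)
}

#' Keep records whose bin has enough distinct-individual support
#'
#' A record survives iff its (chromosome, start, |TLEN|) bin — at the
#' support table's scales — holds records from at least `min_support`
#' distinct individuals. Survivors pass through unchanged.
#'
#' @param records IAF record data.frame.
#' @param table A [bin_alignments()] support table built from the same
#'   record set; rebuilt here when omitted.
#' @param min_support Minimum distinct-individual count (default 20).
#' @return The surviving subset of `records`.
#' @export
support_filter <- function(records, table = NULL, min_support = 20) {
  if (length(min_support) != 1L || is.na(min_support) || min_support < 1) {
    stop_validation("min_support must be >= 1")
  }
  if (is.null(table)) table <- bin_alignments(records)
  key <- bin_key_of(records, attr(table, "start_scale"),
                    attr(table, "tlen_scale"))
  id <- paste(key$chromosome, key$start_bin, key$tlen_bin, sep = "\r")
  tid <- paste(table$chromosome, table$start_bin, table$tlen_bin, sep = "\r")
  support <- table$support[match(id, tid)]
  support[is.na(support)] <- 0L
  records[support >= min_support, , drop = FALSE]
}

#' Per-chromosome frequency matrix of distinct individuals per bin
#'
#' @param records IAF record data.frame restricted to one chromosome.
#' @param chromosome Chromosome name.
#' @param cohort_size Denominator: the number of individuals in the cohort
#'   (or population) the frequency refers to.
#' @param start_scale Display start-position bin width (default 1 Mb).
#' @param tlen_scale Display |TLEN| bin width (default 10 kb).
#' @return An object of class `frequency_matrix`: a list with the dense
#'   `matrix` (rows = start bins from 0, columns = TLEN bins from 0, cells
#'   = fraction of cohort individuals with >= 1 record in the bin),
#'   `chromosome`, `start_scale`, `tlen_scale`, `cohort_size`.
#' @export
frequency_matrix <- function(records, chromosome, cohort_size,
                             start_scale = 1e6, tlen_scale = 1e4) {
  if (cohort_size < 1) stop_validation("cohort_size must be >= 1")
  records <- records[records$rname == chromosome, , drop = FALSE]
  tab <- bin_alignments(records, start_scale, tlen_scale)
  nr <- if (nrow(tab) == 0L) 1L else max(tab$start_bin) + 1L
  nc <- if (nrow(tab) == 0L) 1L else max(tab$tlen_bin) + 1L
  m <- matrix(0, nrow = nr, ncol = nc,
              dimnames = list(start_bin = as.character(seq_len(nr) - 1L),
                              tlen_bin = as.character(seq_len(nc) - 1L)))
  if (nrow(tab) > 0L) {
    m[cbind(tab$start_bin + 1L, tab$tlen_bin + 1L)] <- tab$support / cohort_size
  }
  structure(list(matrix = m, chromosome = chromosome,
                 start_scale = start_scale, tlen_scale = tlen_scale,
                 cohort_size = cohort_size),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  nz <- sum(x$matrix > 0)
  cat("<frequency_matrix chr ", x$chromosome, "> ",
      nrow(x$matrix), " x ", ncol(x$matrix), " bins (",
      format(x$start_scale, scientific = FALSE), " bp x ",
      format(x$tlen_scale, scientific = FALSE), " bp), ",
      nz, " nonzero cell(s), denominator ", x$cohort_size, "\n", sep = "")
  invisible(x)
}

#' Resolve a population selector against a manifest
#'
#' A code matches the manifest's `population` or `superpopulation` column;
#' a `"nonX"` code selects the complement of `"X"` (individuals matching
#' neither column). Several codes union their selections.
#'
#' @param manifest Manifest data.frame (see [read_manifest()]).
#' @param codes Character vector of population codes.
#' @return Character vector of individual IDs.
#' @export
resolve_population <- function(manifest, codes) {
  pick <- rep(FALSE, nrow(manifest))
  known <- unique(c(manifest$population, manifest$superpopulation))
  for (code in codes) {
    if (grepl("^non", code) && sub("^non", "", code) %in% known) {
      base <- sub("^non", "", code)
      pick <- pick | (manifest$population != base &
                      manifest$superpopulation != base)
    } else if (code %in% known) {
      pick <- pick | manifest$population == code |
        manifest$superpopulation == code
    } else {
      stop_validation("unknown population code: ", code)
    }
  }
  manifest$individual[pick]
}

#' Run the inversion scan
#'
#' Full analysis over TLEN-reduced IAF records: keep same-strand pairs
#' ([same_strand_pair()]), discard impure alignments
#' ([is_clean_alignment()]), require `min_support` distinct individuals per
#' kb-scale bin ([support_filter()]), and summarize survivors as
#' per-chromosome [frequency_matrix()] objects at display scales. The
#' upstream template-length reduction (|TLEN| >= 600 bp by default) is a
#' filter-job concern and is not re-applied here.
#'
#' The support filter always runs on the full input record set; when a
#' `population` selector is given, only the frequency summary (records and
#' denominator) is restricted to that population.
#'
#' @param iaf IAF input: a file path, a character vector of paths
#'   (concatenated), or a data.frame from [read_iaf()].
#' @param manifest Manifest data.frame or path; every individual present in
#'   the records must appear in it.
#' @param min_support Distinct-individual support threshold (default 20).
#' @param support_scale Support bin width, bp (default 1 kb for both axes).
#' @param start_scale,tlen_scale Display bin widths (default 1 Mb, 10 kb).
#' @param population Optional population selector (see
#'   [resolve_population()]).
#' @return Named list of `frequency_matrix`, one per chromosome observed
#'   among the surviving records (empty list if none survive).
#' @export
run_scan <- function(iaf, manifest, min_support = 20, support_scale = 1000,
                     start_scale = 1e6, tlen_scale = 1e4,
                     population = NULL) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- read_manifest(manifest)
  }
  records <- if (is.data.frame(iaf)) iaf else
    do.call(rbind, lapply(iaf, read_iaf))
  unknown <- setdiff(unique(records$individual_id), manifest$individual)
  if (length(unknown) > 0L) {
    stop_validation("individual(s) in records but absent from manifest: ",
                    paste(unknown, collapse = ", "))
  }
  keep <- same_strand_pair(records) & is_clean_alignment(records)
  records <- records[keep, , drop = FALSE]
  table <- bin_alignments(records, support_scale, support_scale)
  records <- support_filter(records, table, min_support)

  cohort <- manifest$individual
  if (!is.null(population)) {
    cohort <- resolve_population(manifest, population)
    records <- records[records$individual_id %in% cohort, , drop = FALSE]
  }
  chroms <- unique(records$rname)
  out <- lapply(chroms, function(ch)
    frequency_matrix(records, ch, length(cohort), start_scale, tlen_scale))
  names(out) <- chroms
  out
}

#' Contrast within-population frequencies of two matrices
#'
#' Cellwise `A - B` of two frequency matrices built over the same
#' chromosome and scales, each with its own population size as denominator;
#' positive values indicate higher within-population frequency in `A`.
#' Matrices are padded with zero bins to a common extent first.
#'
#' @param matrix_a,matrix_b [frequency_matrix()] objects.
#' @return A `frequency_matrix`-like object of class
#'   `c("population_contrast", "frequency_matrix")` with cells in
#'   `[-1, 1]`; `cohort_size` holds both denominators.
#' @export
population_difference <- function(matrix_a, matrix_b) {
  stopifnot(inherits(matrix_a, "frequency_matrix"),
            inherits(matrix_b, "frequency_matrix"))
  if (!identical(matrix_a$chromosome, matrix_b$chromosome) ||
      matrix_a$start_scale != matrix_b$start_scale ||
      matrix_a$tlen_scale != matrix_b$tlen_scale) {
    stop_validation("matrices must share chromosome and bin scales")
  }
  nr <- max(nrow(matrix_a$matrix), nrow(matrix_b$matrix))
  nc <- max(ncol(matrix_a$matrix), ncol(matrix_b$matrix))
  pad <- function(m) {
    out <- matrix(0, nr, nc,
                  dimnames = list(start_bin = as.character(seq_len(nr) - 1L),
                                  tlen_bin = as.character(seq_len(nc) - 1L)))
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  structure(list(matrix = pad(matrix_a$matrix) - pad(matrix_b$matrix),
                 chromosome = matrix_a$chromosome,
                 start_scale = matrix_a$start_scale,
                 tlen_scale = matrix_a$tlen_scale,
                 cohort_size = c(a = matrix_a$cohort_size,
                                 b = matrix_b$cohort_size)),
            class = c("population_contrast", "frequency_matrix"))
}

#' Write a frequency matrix as a tab-separated table
#'
#' Rows are start bins, columns TLEN bins, both labelled by bin index.
#'
#' @param fm A [frequency_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "frequency_matrix"))
  utils::write.table(fm$matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Render a frequency matrix as a heat map
#'
#' Start-position bins on the y axis, |TLEN| bins on the x axis, cell
#' intensity the per-bin frequency. With `log_scale = TRUE` intensity is
#' `log10(frequency)` and zero cells are masked to the background colour
#' (log of zero is undefined). A population contrast (which can hold
#' negative cells) is always rendered on a linear diverging scale.
#'
#' @param fm A [frequency_matrix()] or [population_difference()] result.
#' @param path Output PNG path.
#' @param log_scale Use a logarithmic colour scale (default TRUE).
#' @param annotate Draw axes and title (default TRUE). With
#'   `annotate = FALSE` the PNG is a bare raster with exactly one pixel per
#'   matrix cell (row 1 of the image = highest start bin).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(fm, path, log_scale = TRUE, annotate = TRUE) {
  stopifnot(inherits(fm, "frequency_matrix"))
  m <- fm$matrix
  contrast <- inherits(fm, "population_contrast") || any(m < 0)
  if (contrast) {
    z <- m
    lim <- max(abs(z), 1e-12)
    zlim <- c(-lim, lim)
    pal <- grDevices::hcl.colors(101, "Blue-Red 3")
  } else {
    z <- if (log_scale) { out <- log10(m); out[!is.finite(out)] <- NA; out }
         else { out <- m; out[out == 0] <- NA; out }
    zlim <- if (all(is.na(z))) c(0, 1) else range(z, na.rm = TRUE)
    if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
    pal <- grDevices::hcl.colors(101, "YlOrRd", rev = TRUE)
  }
  # image() draws z[i,j] at (x[i], y[j]); transpose so x = TLEN bins
  zt <- t(z)
  x <- seq_len(nrow(zt)) - 1L  # tlen bins
  y <- seq_len(ncol(zt)) - 1L  # start bins
  if (annotate) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(x, y, zt, zlim = zlim, col = pal, useRaster = FALSE,
                    xlab = sprintf("template length bin (%s bp)",
                                   format(fm$tlen_scale, scientific = FALSE)),
                    ylab = sprintf("start position bin (%s bp)",
                                   format(fm$start_scale, scientific = FALSE)),
                    main = paste0("chromosome ", fm$chromosome,
                                  if (contrast) " (population contrast)"
                                  else if (log_scale) " (log10 frequency)"
                                  else " (frequency)"))
  } else {
    grDevices::png(path, width = nrow(zt), height = ncol(zt))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::image(x, y, zt, zlim = zlim, col = pal, useRaster = TRUE,
                    axes = FALSE, xlab = "", ylab = "")
  }
  invisible(path)
}
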