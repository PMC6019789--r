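# Synthetic multi-individual paired-end cohorts with planted structural
# variation. Reads are fabricated alignments: the pipeline consumes
# alignment geometry (flags, positions, TLEN, CIGAR, tags), not base
# content, so SEQ is random A/C/G/T of read length (literal motifs can be
# planted where sequence-pattern filters are under test). All randomness is
# driven by the cohort seed, so a spec run twice yields identical cohorts.

#' Describe a synthetic cohort
#'
#' @param n_individuals Number of individuals (one BAM each).
#' @param populations Optional data.frame with columns `individual`,
#'   `population`, `superpopulation`; generated (`IND0001`..., populations
#'   `POP1`/`POP2` under superpopulations `SUPA`/`SUPB`, split evenly) when
#'   omitted.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Insert-size model: normal, truncated below
#'   at `read_length` (and above at 1 kb so a planted event's kb-scale
#'   TLEN bin is determined by its span alone).
#' @param background_pairs Proper read pairs per individual.
#' @param seed Seed fixing every output byte.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals, populations = NULL,
                        chrom_lengths = c("1" = 40e6),
                        read_length = 100, insert_mean = 400,
                        insert_sd = 50, background_pairs = 30,
                        seed = 1L) {
  if (n_individuals < 1) stop_validation("n_individuals must be >= 1")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths < 1)) {
    stop_validation("chrom_lengths must be a named vector of positive lengths")
  }
  if (insert_mean <= read_length) {
    stop_validation("insert_mean must exceed read_length")
  }
  if (is.null(populations)) {
    ind <- sprintf("IND%04d", seq_len(n_individuals))
    half <- ceiling(n_individuals / 2)
    populations <- data.frame(
      individual = ind,
      population = ifelse(seq_len(n_individuals) <= half, "POP1", "POP2"),
      superpopulation = ifelse(seq_len(n_individuals) <= half,
                               "SUPA", "SUPB"),
      stringsAsFactors = FALSE)
  }
  if (nrow(populations) != n_individuals ||
      anyDuplicated(populations$individual)) {
    stop_validation("populations must assign each individual exactly once")
  }
  structure(list(n_individuals = n_individuals, populations = populations,
                 chrom_lengths = chrom_lengths, read_length = read_length,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 background_pairs = background_pairs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Describe a planted structural-variation event
#'
#' An inversion plants same-strand read pairs (strand and mate-strand bits
#' equal) whose |TLEN| is inflated to roughly `span` plus one insert; a
#' deletion plants pairs keeping the usual forward/reverse orientation with
#' the same |TLEN| inflation. Carrier left-read starts jitter within 200 bp
#' of `locus`, so all planted records of one event share kb-scale bins.
#'
#' @param kind `"inversion"` or `"deletion"`.
#' @param chromosome Chromosome name (must exist in the cohort spec).
#' @param locus 1-based left breakpoint position.
#' @param span Event span in bp (> 0).
#' @param carriers Character vector of carrier individual IDs.
#' @param pairs_per_carrier Planted read pairs per carrier (default 4).
#' @return An object of class `planted_event`.
#' @export
planted_event <- function(kind = c("inversion", "deletion"), chromosome,
                          locus, span, carriers, pairs_per_carrier = 4L) {
  kind <- match.arg(kind)
  if (span <= 0) stop_validation("span must be positive")
  if (length(carriers) == 0L) stop_validation("event needs >= 1 carrier")
  structure(list(kind = kind, chromosome = as.character(chromosome),
                 locus = as.numeric(locus), span = as.numeric(span),
                 carriers = as.character(carriers),
                 pairs_per_carrier = as.integer(pairs_per_carrier)),
            class = "planted_event")
}

# Insert sizes: normal(mean, sd) truncated to (read_length, 1000).
draw_inserts <- function(n, spec) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(n * 2, spec$insert_mean, spec$insert_sd))
    out <- c(out, x[x > spec$read_length & x < 1000])
  }
  as.integer(out[seq_len(n)])
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Build the two records of one pair. Orientation codes: "proper" (FR with
# proper-pair bit), "del" (FR, discordant), "inv_ff"/"inv_rr" (same
# strand). pos1 is the leftmost read's 1-based start.
pair_records <- function(qname, rname, pos1, tlen, rl, orientation) {
  pos2 <- pos1 + tlen - rl
  flags <- switch(orientation,
    proper = c(0x1 + 0x2 + 0x20 + 0x40, 0x1 + 0x2 + 0x10 + 0x80),  # 99/147
    proper_rev = c(0x1 + 0x2 + 0x10 + 0x40, 0x1 + 0x2 + 0x20 + 0x80), # 83/163
    del = c(0x1 + 0x20 + 0x40, 0x1 + 0x10 + 0x80),                 # 97/145
    inv_ff = c(0x1 + 0x40, 0x1 + 0x80),                            # 65/129
    inv_rr = c(0x1 + 0x10 + 0x20 + 0x40, 0x1 + 0x10 + 0x20 + 0x80) # 113/177
  )
  # proper_rev places the reverse read leftmost in flag terms only; for
  # simplicity the leftmost record is always the first segment here.
  data.frame(
    qname = rep(qname, 2L), flag = as.integer(flags), rname = rname,
    pos = as.integer(c(pos1, pos2)), mapq = 60L,
    cigar = sprintf("%dM", rl), rnext = "=",
    pnext = as.integer(c(pos2, pos1)),
    tlen = as.integer(c(tlen, -tlen)),
    seq = random_seq(2L, rl),
    qual = paste(rep("I", rl), collapse = ""),
    tags = "", stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of per-individual BAM files with planted events
#'
#' Writes one coordinate-sorted, indexed BAM per individual, a manifest
#' (format of [read_manifest()]) and a ground-truth sidecar listing every
#' planted record with its expected kb-scale and display-scale bins.
#' Background pairs are properly oriented with |TLEN| drawn from the insert
#' model; inversion carrier pairs have equal strand/mate-strand bits and
#' |TLEN| = span + insert; deletion carrier pairs keep proper orientation
#' with the same |TLEN| inflation. Non-carriers get no same-strand
#' large-|TLEN| pairs.
#'
#' @param spec A [cohort_spec()].
#' @param events List of [planted_event()]s.
#' @param out_dir Output directory (created).
#' @param noise_softclip,noise_xa Fractions of each BAM's records to
#'   soft-clip / XA-tag via [inject_noise()] after generation (default 0).
#' @return List with `manifest` (path), `sidecar` (path), `bams` (paths),
#'   `truth` (the sidecar data.frame), invisibly usable as ground truth.
#' @export
simulate_cohort <- function(spec, events = list(), out_dir,
                            noise_softclip = 0, noise_xa = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (inherits(events, "planted_event")) events <- list(events)
  for (ev in events) {
    if (!ev$chromosome %in% names(spec$chrom_lengths)) {
      stop_validation("event chromosome not in cohort: ", ev$chromosome)
    }
    if (ev$locus + ev$span > spec$chrom_lengths[[ev$chromosome]]) {
      stop_validation("event exceeds chromosome length")
    }
    if (!all(ev$carriers %in% spec$populations$individual)) {
      stop_validation("event carriers must be cohort individuals")
    }
    if (spec$insert_mean >= ev$span) {
      stop_validation("insert_mean must be below every planted event span")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_io("cannot create output directory: ",
                                    out_dir, retryable = FALSE)
  set.seed(spec$seed)
  rl <- spec$read_length
  chroms <- names(spec$chrom_lengths)
  truth <- list()
  bam_paths <- character(spec$n_individuals)

  for (i in seq_len(spec$n_individuals)) {
    ind <- spec$populations$individual[i]
    chunks <- list()
    # background proper pairs
    nb <- spec$background_pairs
    if (nb > 0L) {
      ch <- sample(chroms, nb, replace = TRUE,
                   prob = spec$chrom_lengths / sum(spec$chrom_lengths))
      ins <- draw_inserts(nb, spec)
      maxpos <- spec$chrom_lengths[ch] - ins - 1
      pos <- floor(stats::runif(nb, min = 1, max = maxpos))
      orient <- sample(c("proper", "proper_rev"), nb, replace = TRUE)
      chunks <- c(chunks, lapply(seq_len(nb), function(j)
        pair_records(sprintf("%s_bg_%05d", ind, j), ch[j], pos[j], ins[j],
                     rl, orient[j])))
    }
    # planted events this individual carries
    for (e in seq_along(events)) {
      ev <- events[[e]]
      if (!ind %in% ev$carriers) next
      np <- ev$pairs_per_carrier
      ins <- draw_inserts(np, spec)
      jitter <- sample(0:199, np, replace = TRUE)
      pos1 <- as.integer(ev$locus + jitter)
      tlen <- as.integer(ev$span + ins)
      orient <- if (ev$kind == "inversion") {
        sample(c("inv_ff", "inv_rr"), np, replace = TRUE)
      } else rep("del", np)
      for (j in seq_len(np)) {
        rec <- pair_records(sprintf("%s_ev%d_%03d", ind, e, j),
                            ev$chromosome, pos1[j], tlen[j], rl, orient[j])
        chunks <- c(chunks, list(rec))
        truth[[length(truth) + 1L]] <- data.frame(
          kind = ev$kind, chromosome = ev$chromosome, locus = ev$locus,
          span = ev$span, carrier = ind, pos = rec$pos, tlen = rec$tlen,
          kb_start_bin = floor((rec$pos - 1) / 1000),
          kb_tlen_bin = floor(abs(rec$tlen) / 1000),
          display_start_bin = floor((rec$pos - 1) / 1e6),
          display_tlen_bin = floor(abs(rec$tlen) / 1e4),
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, chunks)
    bam <- file.path(out_dir, paste0(ind, ".bam"))
    write_bam(records, spec$chrom_lengths, bam)
    bam_paths[i] <- bam
  }

  if (noise_softclip > 0 || noise_xa > 0) {
    for (i in seq_len(spec$n_individuals)) {
      inject_noise(bam_paths[i], noise_softclip, noise_xa,
                   seed = spec$seed + i)
    }
  }

  manifest <- data.frame(file = basename(bam_paths),
                         individual = spec$populations$individual,
                         population = spec$populations$population,
                         superpopulation = spec$populations$superpopulation,
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(kind = character(0), chromosome = character(0),
               locus = numeric(0), span = numeric(0), carrier = character(0),
               pos = integer(0), tlen = integer(0),
               kb_start_bin = numeric(0), kb_tlen_bin = numeric(0),
               display_start_bin = numeric(0), display_tlen_bin = numeric(0),
               stringsAsFactors = FALSE)
  sidecar <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(truth, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = manifest_path, sidecar = sidecar, bams = bam_paths,
       truth = truth)
}

#' Inject alignment noise into a BAM file
#'
#' Rewrites the BAM so that `round(fraction_softclip * n)` records get a
#' soft-clipped CIGAR (`5S...M`, read length preserved) and a further
#' disjoint `round(fraction_xa * n)` records get an alternative-alignment
#' `XA` tag — the two impurity classes the scan's purity filter discards.
#' Sampling is seeded and deterministic.
#'
#' @param bam Path to a BAM file (rewritten in place).
#' @param fraction_softclip,fraction_xa Fractions in `[0, 1]`, summing to
#'   at most 1.
#' @param seed Integer seed.
#' @return Invisibly, a list with the counts of modified records
#'   (`n_softclip`, `n_xa`, `n_total`).
#' @export
inject_noise <- function(bam, fraction_softclip, fraction_xa, seed = 1L) {
  if (fraction_softclip < 0 || fraction_xa < 0 ||
      fraction_softclip > 1 || fraction_xa > 1) {
    stop_validation("noise fractions must lie in [0, 1]")
  }
  if (fraction_softclip + fraction_xa > 1) {
    stop_validation("noise fractions sum to more than 1")
  }
  header <- read_bam_header(bam)
  recs <- stream_alignments(bam)
  n <- nrow(recs)
  n_sc <- as.integer(round(fraction_softclip * n))
  n_xa <- as.integer(round(fraction_xa * n))
  if (n_sc + n_xa > 0L && n > 0L) {
    set.seed(as.integer(seed))
    idx <- sample.int(n, n_sc + n_xa)
    sc <- idx[seq_len(n_sc)]
    xa <- idx[n_sc + seq_len(n_xa)]
    if (n_sc > 0L) {
      len <- nchar(recs$seq[sc])
      recs$cigar[sc] <- sprintf("5S%dM", len - 5L)
    }
    if (n_xa > 0L) {
      xa_tag <- sprintf("XA:Z:%s,+%d,%dM,1;", recs$rname[xa],
                        recs$pos[xa] + 5000L, nchar(recs$seq[xa]))
      recs$tags[xa] <- ifelse(recs$tags[xa] == "", xa_tag,
                              paste(recs$tags[xa], xa_tag, sep = "\t"))
    }
    write_bam(recs, header, bam)
  }
  invisible(list(n_softclip = n_sc, n_xa = n_xa, n_total = n))
}
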