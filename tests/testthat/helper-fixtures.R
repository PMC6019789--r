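# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no stored data files.

CIGAR_POOL <- c("100M", "76M", "50M2I48M", "5S95M", "90M10S", "*")
TAG_POOL <- c("", "NM:i:3", "XA:Z:1,+5000,100M,0;",
              "NM:i:2\tXA:Z:2,-777,76M,1;", "AS:i:55\tNM:i:0")

# Arbitrary records for pure-predicate and IAF tests (not necessarily
# SAM-consistent: cigar may disagree with seq length).
random_records <- function(n) {
  data.frame(
    qname = sprintf("r%05d", seq_len(n)),
    flag = sample(0:4095, n, replace = TRUE),
    rname = sample(c("1", "2", "X"), n, replace = TRUE),
    pos = sample(1:2000000, n, replace = TRUE),
    mapq = sample(0:60, n, replace = TRUE),
    cigar = sample(CIGAR_POOL, n, replace = TRUE),
    rnext = rep("=", n),
    pnext = sample(1:2000000, n, replace = TRUE),
    tlen = sample(c(-1L, 1L), n, replace = TRUE) *
      sample(50:2000, n, replace = TRUE),
    seq = random_dna(n, 20),
    qual = rep(strrep("I", 20), n),
    tags = sample(TAG_POOL, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# SAM-consistent records (cigar consumes exactly the query length, mapped,
# positions inside the declared chromosomes) for BAM round trips.
random_valid_records <- function(n, chrom_lengths = c("1" = 3e6, "2" = 2e6)) {
  len <- 100L
  cigars <- c(sprintf("%dM", len), sprintf("5S%dM", len - 5L),
              sprintf("%dM2I%dM", 50L, len - 52L), sprintf("%dM10S", len - 10L))
  rname <- sample(names(chrom_lengths), n, replace = TRUE)
  flags <- sample(c(99L, 147L, 83L, 163L, 65L, 129L, 97L, 145L, 113L, 177L),
                  n, replace = TRUE)
  data.frame(
    qname = sprintf("q%06d", seq_len(n)),
    flag = flags,
    rname = rname,
    pos = vapply(rname, function(ch)
      sample.int(chrom_lengths[[ch]] - len, 1L), integer(1)),
    mapq = sample(0:60, n, replace = TRUE),
    cigar = sample(cigars, n, replace = TRUE),
    rnext = rep("=", n),
    pnext = sample(1:1000000, n, replace = TRUE),
    tlen = sample(c(-1L, 1L), n, replace = TRUE) *
      sample(150:999999, n, replace = TRUE),
    seq = random_dna(n, len),
    qual = rep(strrep("I", len), n),
    tags = sample(TAG_POOL, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Random filter specification; each criterion present independently.
random_spec <- function() {
  p <- function(prob) stats::runif(1) < prob
  req <- if (p(0.4)) sample(0:255, 1) else NULL
  exc <- if (p(0.4)) {
    e <- sample(0:255, 1)
    if (!is.null(req)) e <- bitwAnd(e, bitwNot(req)) %% 4096
    e
  } else NULL
  tmin <- if (p(0.4)) sample(0:1500, 1) else NULL
  tmax <- if (p(0.3)) (if (is.null(tmin)) sample(0:2000, 1)
                       else tmin + sample(0:1000, 1)) else NULL
  filter_spec(
    mapq_min = if (p(0.4)) sample(0:60, 1) else NULL,
    flag_required = req, flag_excluded = exc,
    tlen_min = tmin, tlen_max = tmax,
    seq_pattern = if (p(0.3)) paste(sample(c("A", "C", "G", "T"),
                                           sample(1:3, 1), replace = TRUE),
                                    collapse = "") else NULL,
    cigar_regex = if (p(0.3)) sample(c("[0-9]+M", "[0-9]+M[0-9]+S",
                                       "100M", ".*"), 1) else NULL,
    tag_regex = if (p(0.3)) sample(c("XA:", "NM:i:[0-9]", "AS:i:"), 1)
                else NULL,
    regions = if (p(0.3)) {
      st <- sample(1:1500000, 1)
      data.frame(chrom = sample(c("1", "2"), 1), start = st,
                 end = st + sample(1000:800000, 1))
    } else NULL
  )
}

# Independent clause-by-clause predicate: evaluates one record against one
# spec with per-bit loops and scalar logic, sharing no code path with
# matches_filter().
oracle_match <- function(rec, spec) {
  bits_of <- function(x) {
    out <- integer(0)
    for (b in 0:15) if (x %/% 2^b %% 2 == 1) out <- c(out, 2^b)
    out
  }
  if (!is.null(spec$mapq_min) && rec$mapq < spec$mapq_min) return(FALSE)
  if (!is.null(spec$flag_required)) {
    for (b in bits_of(spec$flag_required)) {
      if (!(b %in% bits_of(rec$flag))) return(FALSE)
    }
  }
  if (!is.null(spec$flag_excluded)) {
    for (b in bits_of(spec$flag_excluded)) {
      if (b %in% bits_of(rec$flag)) return(FALSE)
    }
  }
  if (!is.null(spec$tlen_min) && abs(rec$tlen) < spec$tlen_min) return(FALSE)
  if (!is.null(spec$tlen_max) && abs(rec$tlen) > spec$tlen_max) return(FALSE)
  if (!is.null(spec$seq_pattern)) {
    hay <- toupper(rec$seq); needle <- toupper(spec$seq_pattern)
    found <- FALSE
    if (nchar(needle) <= nchar(hay)) {
      for (i in 1:(nchar(hay) - nchar(needle) + 1)) {
        if (substr(hay, i, i + nchar(needle) - 1) == needle) {
          found <- TRUE; break
        }
      }
    }
    if (!found) return(FALSE)
  }
  if (!is.null(spec$cigar_regex)) {
    unmapped <- rec$flag %/% 4 %% 2 == 1
    if (unmapped || rec$cigar == "*") return(FALSE)
    m <- regmatches(rec$cigar,
                    regexpr(paste0("(?:", spec$cigar_regex, ")"),
                            rec$cigar, perl = TRUE))
    if (length(m) == 0 || m != rec$cigar) return(FALSE)
  }
  if (!is.null(spec$tag_regex) &&
      !grepl(spec$tag_regex, rec$tags, perl = TRUE)) return(FALSE)
  if (!is.null(spec$regions)) {
    unmapped <- rec$flag %/% 4 %% 2 == 1
    if (unmapped || rec$pos == 0) return(FALSE)
    inside <- FALSE
    for (k in seq_len(nrow(spec$regions))) {
      if (rec$rname == spec$regions$chrom[k] &&
          rec$pos >= spec$regions$start[k] &&
          rec$pos <= spec$regions$end[k]) inside <- TRUE
    }
    if (!inside) return(FALSE)
  }
  TRUE
}

# A small cohort on disk, built once per test run and reused.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache) && file.exists(cache$manifest)) return(cache)
    dir <- file.path(tempdir(), "bamsieve-tiny-cohort")
    spec <- cohort_spec(8, chrom_lengths = c("1" = 10e6, "2" = 6e6),
                        background_pairs = 25, seed = 42L)
    inv <- planted_event("inversion", "1", 3000001, 900000,
                         carriers = spec$populations$individual[1:5])
    res <- simulate_cohort(spec, list(inv), dir)
    cache <<- c(res, list(spec = spec, dir = dir))
    cache
  }
})
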