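# Small in-memory IAF fixtures: build records directly, no files needed.
iaf_rec <- function(individual, chrom = "1", pos, tlen, flag = 65L,
                    cigar = "100M", tags = "") {
  data.frame(individual_id = individual, region_label = "all",
             qname = paste0(individual, "_", pos), flag = as.integer(flag),
             rname = chrom, pos = as.integer(pos), mapq = 60L,
             cigar = cigar, rnext = "=", pnext = 1L,
             tlen = as.integer(tlen), seq = "ACGT", qual = "IIII",
             tags = tags, stringsAsFactors = FALSE)
}

mini_manifest <- function(inds, pop = "POP1", superpop = "SUPA") {
  data.frame(file = paste0(inds, ".bam"), individual = inds,
             population = rep_len(pop, length(inds)),
             superpopulation = rep_len(superpop, length(inds)),
             stringsAsFactors = FALSE)
}

test_that("same-strand predicate compares the 0x10 and 0x20 bits", {
  # both reverse
  expect_true(same_strand_pair(0x1 + 0x10 + 0x20))
  # both forward (paired, neither strand bit)
  expect_true(same_strand_pair(0x1))
  # flag 83: read reverse, mate forward
  expect_false(same_strand_pair(83))
  # unpaired records are excluded, not an error
  expect_false(same_strand_pair(0x10 + 0x20))
  expect_identical(same_strand_pair(c(83L, 65L, 113L, 97L)),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("purity predicate requires a single-match CIGAR and no XA tag", {
  r <- rbind(iaf_rec("a", pos = 1, tlen = 1),
             iaf_rec("a", pos = 2, tlen = 1, cigar = "50M2I48M"),
             iaf_rec("a", pos = 3, tlen = 1, cigar = "5S95M"),
             iaf_rec("a", pos = 4, tlen = 1,
                     tags = "XA:Z:1,+100,76M,0;"),
             iaf_rec("a", pos = 5, tlen = 1, tags = "NM:i:0"),
             iaf_rec("a", pos = 6, tlen = 1, cigar = "*"))
  expect_identical(is_clean_alignment(r),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("binning floors 0-based start and |TLEN| at the given scales", {
  r <- rbind(iaf_rec("i1", pos = 30000001, tlen = 900000),
             iaf_rec("i1", pos = 999, tlen = -500),
             iaf_rec("i2", pos = 30000001, tlen = 900000))
  tab <- bin_alignments(r, 1000, 1000)
  expect_s3_class(tab, "support_table")
  row <- tab[tab$start_bin == 30000, ]
  expect_identical(row$tlen_bin, 900)
  expect_identical(row$support, 2L)
  # floor boundary: pos 999 is 0-based 998 -> bin 0; |−500| -> bin 0
  low <- tab[tab$start_bin == 0, ]
  expect_identical(low$tlen_bin, 0)
  expect_identical(low$support, 1L)
  # duplicates of one individual count once
  r2 <- do.call(rbind, replicate(25, iaf_rec("only", pos = 5000, tlen = 700),
                                 simplify = FALSE))
  expect_identical(bin_alignments(r2)$support, 1L)
})

test_that("support filter keeps bins with enough distinct individuals", {
  mk <- function(n, pos) do.call(rbind, lapply(seq_len(n), function(i)
    iaf_rec(sprintf("s%03d", i), pos = pos, tlen = 700000)))
  r <- rbind(mk(19, 1000001), mk(20, 2000001))
  tab <- bin_alignments(r)
  out <- support_filter(r, tab, min_support = 20)
  expect_identical(unique(out$pos), 2000001L)
  expect_identical(nrow(out), 20L)
  # boundary is inclusive at exactly 20; min_support 1 is the identity
  expect_identical(support_filter(r, tab, min_support = 1), r)
  expect_error(support_filter(r, tab, min_support = 0),
               class = "bamsieve_validation_error")
})

test_that("survivors pass through the support filter unchanged", {
  set.seed(13)
  r <- do.call(rbind, lapply(1:30, function(i)
    iaf_rec(sprintf("s%02d", i), pos = 7000001 + (i %% 3), tlen = 650000)))
  out <- support_filter(r, min_support = 20)
  expect_identical(out, r)
})

test_that("orientation and purity filters commute; support does not", {
  set.seed(17)
  r <- do.call(rbind, lapply(1:40, function(i)
    iaf_rec(sprintf("s%02d", i), pos = sample(1:5e6, 1),
            tlen = sample(600000:900000, 1),
            flag = sample(c(65L, 83L, 97L, 113L), 1),
            cigar = sample(c("100M", "5S95M"), 1),
            tags = sample(c("", "XA:Z:1,+1,100M,0;"), 1))))
  ab <- r[same_strand_pair(r), ][is_clean_alignment(r[same_strand_pair(r), ]), ]
  ba <- r[is_clean_alignment(r), ][same_strand_pair(r[is_clean_alignment(r), ]), ]
  expect_identical(ab, ba)
  # support_filter depends on the surviving set: filtering a subset first
  # can drop bins below threshold
  pair <- rbind(iaf_rec("s01", pos = 1000001, tlen = 700000),
                iaf_rec("s02", pos = 1000002, tlen = 700000))
  expect_identical(nrow(support_filter(pair, min_support = 2)), 2L)
  expect_identical(nrow(support_filter(pair[1, ], min_support = 2)), 0L)
})

test_that("frequency matrices count distinct individuals over the cohort", {
  inds <- sprintf("i%02d", 1:10)
  r <- do.call(rbind, lapply(inds[1:3], function(i)
    iaf_rec(i, pos = 30000001, tlen = 900000)))
  fm <- frequency_matrix(r, "1", cohort_size = 10)
  expect_identical(dim(fm$matrix), c(31L, 91L))
  expect_identical(fm$matrix["30", "90"], 0.3)
  expect_identical(sum(fm$matrix > 0), 1L)
  expect_true(all(fm$matrix >= 0 & fm$matrix <= 1))
})

test_that("the scan pipeline recovers planted signatures only", {
  inds <- sprintf("i%02d", 1:25)
  manifest <- mini_manifest(inds)
  # inversion signature from 22 individuals, deletion-like from all 25,
  # and an XA-contaminated same-strand batch from 25
  inv <- do.call(rbind, lapply(inds[1:22], function(i)
    iaf_rec(i, pos = 3000001, tlen = 900000, flag = 65L)))
  del <- do.call(rbind, lapply(inds, function(i)
    iaf_rec(i, pos = 8000001, tlen = 800000, flag = 97L)))
  noisy <- do.call(rbind, lapply(inds, function(i)
    iaf_rec(i, pos = 12000001, tlen = 700000, flag = 65L,
            tags = "XA:Z:1,+9,100M,0;")))
  mats <- run_scan(rbind(inv, del, noisy), manifest, min_support = 20)
  m <- mats[["1"]]$matrix
  expect_identical(sum(m > 0), 1L)
  expect_identical(m["3", "90"], 22 / 25)
  # below-threshold support yields nothing
  mats2 <- run_scan(rbind(inv[1:19, ], del, noisy), manifest,
                    min_support = 20)
  expect_length(mats2, 0L)
  # empty input: no matrices at all
  expect_length(run_scan(inv[0, ], manifest), 0L)
  # unknown individuals are a validation error
  expect_error(run_scan(iaf_rec("ghost", pos = 1, tlen = 1e6),
                        manifest), class = "bamsieve_validation_error")
})

test_that("population contrasts subtract per-population frequencies", {
  a_inds <- sprintf("e%02d", 1:25)
  b_inds <- sprintf("n%03d", 1:100)
  manifest <- rbind(mini_manifest(a_inds, "GBR", "EUR"),
                    mini_manifest(b_inds, "YRI", "AFR"))
  recs <- rbind(
    do.call(rbind, lapply(a_inds[1:5], function(i)
      iaf_rec(i, pos = 43000001, tlen = 600000))),
    do.call(rbind, lapply(b_inds[1:10], function(i)
      iaf_rec(i, pos = 43000001, tlen = 600000))))
  a <- run_scan(recs, manifest, min_support = 10, population = "EUR")
  b <- run_scan(recs, manifest, min_support = 10, population = "nonEUR")
  expect_identical(a[["1"]]$cohort_size, 25L)
  expect_identical(b[["1"]]$cohort_size, 100L)
  d <- population_difference(a[["1"]], b[["1"]])
  # 5/25 − 10/100 = 0.20 − 0.10
  expect_equal(d$matrix["43", "60"], 0.10)
  expect_true(all(d$matrix >= -1 & d$matrix <= 1))
  expect_identical(sum(d$matrix != 0), 1L)
  # identical matrices cancel exactly
  z <- population_difference(a[["1"]], a[["1"]])
  expect_true(all(z$matrix == 0))
  # mismatched scales are rejected
  fm2 <- frequency_matrix(recs, "1", 10, start_scale = 1e5)
  expect_error(population_difference(a[["1"]], fm2),
               class = "bamsieve_validation_error")
})

test_that("unknown population codes are rejected", {
  manifest <- mini_manifest(c("a", "b"))
  expect_error(resolve_population(manifest, "EUR"),
               class = "bamsieve_validation_error")
  expect_identical(resolve_population(manifest, "POP1"), c("a", "b"))
  expect_identical(resolve_population(manifest, "nonPOP1"), character(0))
})

test_that("heat maps place cells where the matrix says", {
  skip_if_not_installed("png")
  inds <- sprintf("i%02d", 1:10)
  r <- do.call(rbind, lapply(inds[1:4], function(i)
    iaf_rec(i, pos = 2500001, tlen = 350000)))
  fm <- frequency_matrix(r, "1", 10)   # 3 x 36 bins; nonzero at (2, 35)
  path <- tempfile(fileext = ".png")
  render_heatmap(fm, path, annotate = FALSE)
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], c(nrow(fm$matrix), ncol(fm$matrix)))
  lum <- img[, , 1] + img[, , 2] + img[, , 3]
  hot <- which(lum != lum[1, 1], arr.ind = TRUE)
  # image row 1 is the top = highest start bin; nonzero cell is start bin 2
  # (bottom row of the image), tlen bin 35 (last column)
  expect_identical(nrow(hot), 1L)
  expect_identical(unname(hot[1, ]), c(1L, 36L))
  # all-zero matrices render as a uniform background
  zero <- frequency_matrix(r[0, ], "1", 10)
  p2 <- tempfile(fileext = ".png")
  render_heatmap(zero, p2, annotate = FALSE)
  img2 <- png::readPNG(p2)
  expect_identical(length(unique(as.vector(img2))), 1L)
  # log vs linear differ in colour only, not geometry
  p3 <- tempfile(fileext = ".png")
  render_heatmap(fm, p3, log_scale = FALSE, annotate = FALSE)
  img3 <- png::readPNG(p3)
  lum3 <- img3[, , 1] + img3[, , 2] + img3[, , 3]
  expect_identical(which(lum3 != lum3[1, 1]), which(lum != lum[1, 1]))
})

test_that("matrices serialize as labelled TSV tables", {
  r <- iaf_rec("i1", pos = 1500001, tlen = 250000)
  fm <- frequency_matrix(r, "1", 4)
  path <- tempfile(fileext = ".tsv")
  write_matrix(fm, path)
  back <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(fm$matrix))
  expect_identical(rownames(back), rownames(fm$matrix))
})
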