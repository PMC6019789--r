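# Engine tests run against a small simulated cohort on disk (8
# individuals, one planted inversion; see helper-fixtures.R).

merged_output <- function(locators) {
  recs <- do.call(rbind, lapply(locators, read_iaf))
  lines <- paste(recs$individual_id, recs$region_label,
                 format_sam_lines(recs), sep = "\t")
  sort(lines)
}

test_that("planning yields exactly one pending task per file", {
  coh <- tiny_cohort()
  job <- bam_job(filter_spec(tlen_min = 600), coh$manifest,
                 output_format = "iaf", sink = tempfile())
  tasks <- plan_job(job)
  expect_length(tasks, 8L)
  expect_setequal(vapply(tasks, `[[`, character(1), "individual_id"),
                  coh$spec$populations$individual)
  expect_true(all(vapply(tasks, `[[`, character(1), "state") == "pending"))
  # stable order and unique ids
  expect_identical(anyDuplicated(vapply(tasks, `[[`, character(1),
                                        "task_id")), 0L)
})

test_that("per-task record counts match a brute-force per-file filter", {
  coh <- tiny_cohort()
  spec <- filter_spec(tlen_min = 600)
  job <- bam_job(spec, coh$manifest, output_format = "iaf",
                 sink = tempfile())
  results <- run_job(job, workers = 1L)
  expect_true(all(vapply(results, `[[`, character(1), "state") == "done"))
  manifest <- read_manifest(coh$manifest)
  for (r in results) {
    f <- manifest$file[manifest$individual == r$individual_id]
    recs <- stream_alignments(f)
    expect_identical(r$records_in, nrow(recs))
    expect_identical(r$records_out, sum(matches_filter(recs, spec)))
  }
  # conservation: sum of records_out equals the merged output size
  total <- sum(vapply(results, `[[`, integer(1), "records_out"))
  expect_length(merged_output(collect_results(job)), total)
})

test_that("merged output is independent of worker count", {
  coh <- tiny_cohort()
  spec <- filter_spec(tlen_min = 600, flag_excluded = 0x400)
  outs <- lapply(c(1L, 2L, 4L), function(w) {
    job <- bam_job(spec, coh$manifest, output_format = "iaf",
                   sink = tempfile(), job_id = paste0("wc", w))
    run_job(job, workers = w)
    merged_output(collect_results(job))
  })
  expect_identical(outs[[2]], outs[[1]])
  expect_identical(outs[[3]], outs[[1]])
})

test_that("a failing task is isolated and reported, not fatal", {
  coh <- tiny_cohort()
  manifest <- read_manifest(coh$manifest)
  manifest$file[3] <- file.path(coh$dir, "missing.bam")
  broken <- tempfile(fileext = ".tsv")
  write_manifest(manifest, broken)
  job <- bam_job(filter_spec(), broken, output_format = "iaf",
                 sink = tempfile())
  results <- run_job(job, workers = 2L)
  states <- vapply(results, `[[`, character(1), "state")
  expect_identical(sum(states == "failed"), 1L)
  expect_identical(sum(states == "done"), 7L)
  expect_match(results[states == "failed"][[1]]$error, "cannot read")
  st <- job_status(job)
  expect_identical(st$counts[["done"]] + st$counts[["failed"]], st$total)
  # failed tasks are absent from collection
  expect_length(collect_results(job), 7L)
})

test_that("status probes and collection respect job lifecycle", {
  coh <- tiny_cohort()
  sink_dir <- tempfile()
  job <- bam_job(filter_spec(mapq_min = 0), coh$manifest,
                 output_format = "iaf", sink = sink_dir)
  st0 <- job_status(job)
  expect_identical(st0$counts[["pending"]], 8L)
  expect_length(collect_results(job), 0L)
  run_job(job, workers = 2L)
  st1 <- job_status(job)
  expect_identical(st1$counts[["done"]], 8L)
  expect_gte(st1$counts[["done"]], st0$counts[["done"]])
  locs <- collect_results(job)
  expect_length(locs, 8L)
  expect_true(all(file.exists(locs)))
  # cross-process path: the summary in the sink answers status/collect too
  entry_gone <- paste0(job$job_id)
  rm(list = entry_gone, envir = bamsieve:::.job_registry)
  st2 <- job_status(job$job_id, sink = sink_dir)
  expect_identical(st2$counts[["done"]], 8L)
  expect_setequal(collect_results(job$job_id, sink = sink_dir), locs)
  expect_error(job_status("no-such-job", sink = sink_dir),
               class = "bamsieve_validation_error")
})

test_that("population and sample subsets restrict the file list", {
  coh <- tiny_cohort()
  inds <- coh$spec$populations$individual
  job <- bam_job(filter_spec(samples = inds[1:3]), coh$manifest,
                 output_format = "iaf", sink = tempfile())
  expect_length(plan_job(job), 3L)
  job2 <- bam_job(filter_spec(populations = "POP1"), coh$manifest,
                  output_format = "iaf", sink = tempfile())
  expect_identical(sort(job2$files$individual),
                   sort(inds[coh$spec$populations$population == "POP1"]))
  job3 <- bam_job(filter_spec(populations = "nonPOP1"), coh$manifest,
                  output_format = "iaf", sink = tempfile())
  expect_identical(sort(c(job2$files$individual, job3$files$individual)),
                   sort(inds))
  expect_error(bam_job(filter_spec(samples = "NOBODY"), coh$manifest,
                       output_format = "iaf", sink = tempfile()),
               class = "bamsieve_validation_error")
})

test_that("BAM output tasks produce re-streamable files", {
  coh <- tiny_cohort()
  spec <- filter_spec(tlen_min = 600)
  job <- bam_job(spec, coh$manifest, output_format = "bam",
                 sink = tempfile())
  results <- run_job(job, workers = 1L)
  expect_true(all(vapply(results, `[[`, character(1), "state") == "done"))
  locs <- collect_results(job)
  counts <- vapply(locs, function(l) nrow(stream_alignments(l)), integer(1))
  expect_identical(unname(counts),
                   vapply(results, `[[`, integer(1), "records_out"))
})

test_that("throughput is total bytes over wall time and linear in bytes", {
  results <- list(list(bytes_streamed = 50e6), list(bytes_streamed = 50e6))
  expect_identical(throughput(results, 10), 10e6)
  expect_identical(throughput(list(), 5), 0)
  doubled <- lapply(results, function(r)
    list(bytes_streamed = 2 * r$bytes_streamed))
  expect_identical(throughput(doubled, 10), 2 * throughput(results, 10))
  expect_error(throughput(results, 0), class = "bamsieve_validation_error")
})

test_that("scaled speedup follows (T1/Tn)/n with mandatory baseline", {
  t <- data.frame(n = c(1, 2, 4), wall_seconds = c(100, 50, 50))
  ss <- scaled_speedup(t)
  expect_identical(unname(ss[["1"]]), 1)
  expect_identical(unname(ss[["2"]]), 1)
  expect_identical(unname(ss[["4"]]), 0.5)
  expect_error(scaled_speedup(data.frame(n = 2, wall_seconds = 10)),
               class = "bamsieve_validation_error")
  expect_error(scaled_speedup(data.frame(n = 1, wall_seconds = 0)),
               class = "bamsieve_validation_error")
  # arbitrary tables follow the closed form
  set.seed(9)
  tt <- data.frame(n = c(1, sample(2:50, 10)),
                   wall_seconds = stats::runif(11, 1, 100))
  ss <- scaled_speedup(tt)
  expect_equal(unname(ss),
               (tt$wall_seconds[1] / tt$wall_seconds) / tt$n)
})
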