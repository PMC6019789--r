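# One filter job = one filter_spec applied to many BAM files; each file
# becomes exactly one task. Tasks are executed by an in-process worker pool
# fed from a single shared queue (workers pull the next pending task as
# they become available), and per-task outputs are consolidated to a
# pluggable sink. An in-memory registry keeps job state for status probes
# and result collection; run_job additionally writes a job summary JSON
# into the sink so separate processes can probe and collect too.

.job_registry <- new.env(parent = emptyenv())

#' Create a local-directory result sink
#'
#' The sink contract is two stateless methods: `put(name, content)` stores
#' a byte stream under a name and returns a locator; `get(locator)` returns
#' the bytes. Content may be a character vector of lines or a raw vector.
#'
#' @param dir Directory to store results in (created if missing).
#' @return An object of class `local_sink`.
#' @export
local_sink <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_io("sink directory unusable: ", dir,
                                retryable = FALSE)
  dir <- normalizePath(dir)
  structure(list(
    dir = dir,
    put = function(name, content) {
      path <- file.path(dir, name)
      if (is.raw(content)) {
        writeBin(content, path)
      } else {
        con <- file(path, open = "wb")
        writeLines(content, con, sep = "\n")
        close(con)
      }
      path
    },
    get = function(locator) {
      if (!file.exists(locator)) stop_io("no such result: ", locator)
      readLines(locator)
    }
  ), class = "local_sink")
}

as_sink <- function(x) {
  if (inherits(x, "local_sink")) x else local_sink(x)
}

#' Define a filter job over a cohort of BAM files
#'
#' A job is a filter condition plus the set of files to apply it to. Files
#' come from a cohort manifest (see [read_manifest()]); sample and
#' population subsets in the spec are resolved here, against the manifest,
#' to the effective file list. A `"nonX"` population code selects every
#' individual whose population and superpopulation both differ from `"X"`.
#'
#' @param spec A [filter_spec()].
#' @param manifest Manifest data.frame or path.
#' @param output_format `"iaf"` (individual alignment format) or `"bam"`.
#' @param sink A [local_sink()] or a directory path.
#' @param job_id Optional job identifier; generated when omitted. Task
#'   outputs are namespaced by job id inside the sink.
#' @return An object of class `bam_job`, registered for [job_status()] and
#'   [collect_results()].
#' @export
bam_job <- function(spec, manifest, output_format = c("iaf", "bam"),
                    sink, job_id = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  output_format <- match.arg(output_format)
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- read_manifest(manifest)
  }
  files <- manifest
  if (!is.null(spec$samples)) {
    files <- files[files$individual %in% spec$samples, , drop = FALSE]
  }
  if (!is.null(spec$populations)) {
    keep <- resolve_population(manifest, spec$populations)
    files <- files[files$individual %in% keep, , drop = FALSE]
  }
  if (nrow(files) == 0L) {
    stop_validation("job has an empty file list after cohort subsetting")
  }
  if (anyDuplicated(files$individual)) {
    stop_validation("individual IDs must be unique within a job")
  }
  if (is.null(job_id)) {
    job_id <- sprintf("job-%s-%04x", format(Sys.time(), "%Y%m%d%H%M%S"),
                      sample.int(65535L, 1L))
  }
  job <- structure(list(
    job_id = job_id, spec = spec, files = files,
    output_format = output_format, sink = as_sink(sink)
  ), class = "bam_job")
  tasks <- plan_job(job)
  assign(job_id, list(job = job, tasks = tasks, results = NULL),
         envir = .job_registry)
  job
}

#' @export
print.bam_job <- function(x, ...) {
  cat("<bam_job ", x$job_id, ">: ", nrow(x$files), " file(s) -> ",
      x$output_format, " in ", x$sink$dir, "\n", sep = "")
  invisible(x)
}

#' Plan a job into per-file tasks
#'
#' Exactly one task per BAM file, in manifest order, all initially pending.
#'
#' @param job A [bam_job()].
#' @return List of task records (`task_id`, `job_id`, `source`,
#'   `individual_id`, `state`).
#' @export
plan_job <- function(job) {
  stopifnot(inherits(job, "bam_job"))
  if (nrow(job$files) == 0L) stop_validation("job file list is empty")
  lapply(seq_len(nrow(job$files)), function(i) {
    list(task_id = sprintf("%s-t%04d", job$job_id, i),
         job_id = job$job_id,
         source = data_source(job$files$file[i]),
         individual_id = job$files$individual[i],
         state = "pending")
  })
}

# Execute one task: stream, filter, push to sink. Retries once on
# retryable I/O errors. Returns a TaskResult list; never signals.
run_task <- function(task, job) {
  t0 <- proc.time()[["elapsed"]]
  result <- list(task_id = task$task_id, job_id = task$job_id,
                 individual_id = task$individual_id, state = "failed",
                 records_in = NA_integer_, records_out = NA_integer_,
                 bytes_streamed = NA_real_, wall_seconds = NA_real_,
                 locator = NA_character_, error = NA_character_)
  attempt <- function() {
    regions <- job$spec$regions
    use_regions <- !is.null(regions) &&
      isTRUE(task$source$supports_random_access)
    recs <- if (use_regions) stream_alignments(task$source, regions)
            else stream_alignments(task$source)
    bytes <- attr(recs, "bytes_streamed")
    keep <- matches_filter(recs, job$spec)
    out <- recs[keep, , drop = FALSE]
    region_label <- if (is.null(regions)) "all"
                    else paste(format_region(regions), collapse = ",")
    name <- paste0(task$job_id, "_", task$individual_id, ".",
                   job$output_format)
    locator <- if (job$output_format == "iaf") {
      lines <- if (nrow(out) == 0L) character(0) else
        paste(task$individual_id, region_label, format_sam_lines(out),
              sep = "\t")
      job$sink$put(name, lines)
    } else {
      tmp <- tempfile(fileext = ".bam")
      on.exit(unlink(c(tmp, paste0(tmp, ".bai"))), add = TRUE)
      write_bam(out, read_bam_header(task$source), tmp)
      job$sink$put(name, readBin(tmp, "raw", file.size(tmp)))
    }
    list(records_in = nrow(recs), records_out = nrow(out),
         bytes_streamed = as.numeric(bytes), locator = locator)
  }
  res <- tryCatch(attempt(), bamsieve_io_error = function(e) {
    if (is_retryable(e)) tryCatch(attempt(), error = function(e2) e2) else e
  }, error = function(e) e)
  if (inherits(res, "condition")) {
    result$error <- conditionMessage(res)
  } else {
    result[names(res)] <- res
    result$state <- "done"
  }
  result$wall_seconds <- proc.time()[["elapsed"]] - t0
  result
}

#' Run a filter job on a worker pool
#'
#' Executes every task of the job on `workers` concurrent workers pulling
#' from a single shared queue (a worker takes the next pending task as soon
#' as it finishes its current one). The merged output is, as a multiset of
#' records, independent of the worker count. A failing task is recorded in
#' its TaskResult — with one automatic retry for retryable I/O errors — and
#' never disturbs sibling tasks.
#'
#' @param job A [bam_job()].
#' @param workers Pool size (>= 1).
#' @return List of TaskResult records (fields `task_id`, `individual_id`,
#'   `state`, `records_in`, `records_out`, `bytes_streamed`,
#'   `wall_seconds`, `locator`, `error`), in task order. Attribute
#'   `wall_seconds_total` carries the job wall time.
#' @export
run_job <- function(job, workers = 1L) {
  stopifnot(inherits(job, "bam_job"))
  if (length(workers) != 1L || is.na(workers) || workers < 1L) {
    stop_validation("workers must be >= 1")
  }
  entry <- get_job_entry(job$job_id)
  tasks <- entry$tasks
  t0 <- proc.time()[["elapsed"]]
  results <- if (workers == 1L) {
    lapply(tasks, run_task, job = job)
  } else {
    # mc.preschedule = FALSE: at most `workers` forks alive, each new task
    # started as a slot frees - the pull-on-availability queue contract.
    parallel::mclapply(tasks, run_task, job = job,
                       mc.cores = as.integer(workers),
                       mc.preschedule = FALSE)
  }
  wall <- proc.time()[["elapsed"]] - t0
  err <- vapply(results, function(r) inherits(r, "try-error") ||
                  inherits(r, "condition"), logical(1))
  if (any(err)) {
    # a fork crashed outside run_task's own tryCatch; record, don't raise
    for (i in which(err)) {
      results[[i]] <- list(task_id = tasks[[i]]$task_id, job_id = job$job_id,
                           individual_id = tasks[[i]]$individual_id,
                           state = "failed", records_in = NA_integer_,
                           records_out = NA_integer_,
                           bytes_streamed = NA_real_, wall_seconds = NA_real_,
                           locator = NA_character_,
                           error = paste(as.character(results[[i]]),
                                         collapse = " "))
    }
  }
  attr(results, "wall_seconds_total") <- wall
  entry$results <- results
  entry$tasks <- lapply(seq_along(tasks), function(i) {
    t <- tasks[[i]]; t$state <- results[[i]]$state; t
  })
  assign(job$job_id, entry, envir = .job_registry)
  write_job_summary(job, results, wall)
  results
}

get_job_entry <- function(job_id) {
  if (!exists(job_id, envir = .job_registry, inherits = FALSE)) {
    stop_validation("unknown job id: ", job_id)
  }
  get(job_id, envir = .job_registry, inherits = FALSE)
}

summary_name <- function(job_id) paste0(job_id, ".status.json")

write_job_summary <- function(job, results, wall) {
  strip <- lapply(results, function(r) r[setdiff(names(r), "job_id")])
  json <- jsonlite::toJSON(
    list(job_id = job$job_id, output_format = job$output_format,
         wall_seconds_total = wall, tasks = strip),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  job$sink$put(summary_name(job$job_id), as.character(json))
}

read_job_summary <- function(sink, job_id) {
  sink <- as_sink(sink)
  path <- file.path(sink$dir, summary_name(job_id))
  if (!file.exists(path)) return(NULL)
  jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                     simplifyDataFrame = FALSE)
}

#' Probe the progress of a job
#'
#' @param job_id Job identifier (or a `bam_job`).
#' @param sink Optional sink to consult when the job is not present in this
#'   process's registry (run in another process); the summary written by
#'   [run_job()] is read instead.
#' @return An object of class `job_status`: counts per state
#'   (`pending`, `running`, `done`, `failed`), total, and a per-task
#'   data.frame. The done count never decreases across successive probes.
#' @export
job_status <- function(job_id, sink = NULL) {
  if (inherits(job_id, "bam_job")) job_id <- job_id$job_id
  in_registry <- exists(job_id, envir = .job_registry, inherits = FALSE)
  if (!in_registry && !is.null(sink)) {
    s <- read_job_summary(sink, job_id)
    if (is.null(s)) stop_validation("unknown job id: ", job_id)
    states <- vapply(s$tasks, `[[`, character(1), "state")
    detail <- data.frame(
      task_id = vapply(s$tasks, `[[`, character(1), "task_id"),
      individual_id = vapply(s$tasks, `[[`, character(1), "individual_id"),
      state = states, stringsAsFactors = FALSE)
  } else {
    entry <- get_job_entry(job_id)
    states <- vapply(entry$tasks, `[[`, character(1), "state")
    detail <- data.frame(
      task_id = vapply(entry$tasks, `[[`, character(1), "task_id"),
      individual_id = vapply(entry$tasks, `[[`, character(1),
                             "individual_id"),
      state = states, stringsAsFactors = FALSE)
  }
  counts <- vapply(c("pending", "running", "done", "failed"),
                   function(s) sum(states == s), integer(1))
  structure(list(job_id = job_id, counts = counts, total = length(states),
                 tasks = detail),
            class = "job_status")
}

#' @export
print.job_status <- function(x, ...) {
  cat("<job ", x$job_id, "> ", x$total, " task(s): ",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Collect result locators of a finished job
#'
#' @param job_id Job identifier (or a `bam_job`).
#' @param sink As in [job_status()].
#' @return Character vector with one locator per *done* task (failed tasks
#'   are absent here and flagged in [job_status()]).
#' @export
collect_results <- function(job_id, sink = NULL) {
  if (inherits(job_id, "bam_job")) job_id <- job_id$job_id
  in_registry <- exists(job_id, envir = .job_registry, inherits = FALSE)
  if (!in_registry && !is.null(sink)) {
    s <- read_job_summary(sink, job_id)
    if (is.null(s)) stop_validation("unknown job id: ", job_id)
    done <- Filter(function(t) identical(t$state, "done"), s$tasks)
    return(vapply(done, `[[`, character(1), "locator"))
  }
  entry <- get_job_entry(job_id)
  if (is.null(entry$results)) return(character(0))
  done <- Filter(function(r) identical(r$state, "done"), entry$results)
  vapply(done, function(r) as.character(r$locator), character(1))
}

#' Aggregate filtering throughput
#'
#' Total bytes streamed across tasks per unit of job wall time (wall time
#' from query deployment to completion of the last task).
#'
#' @param results List of TaskResults from [run_job()].
#' @param wall_seconds_total Job wall time in seconds; defaults to the
#'   attribute recorded by [run_job()].
#' @return Bytes per second.
#' @export
throughput <- function(results,
                       wall_seconds_total = attr(results, "wall_seconds_total")) {
  if (is.null(wall_seconds_total) || length(wall_seconds_total) != 1L ||
      is.na(wall_seconds_total) || wall_seconds_total <= 0) {
    stop_validation("wall_seconds_total must be a positive number")
  }
  if (length(results) == 0L) return(0)
  bytes <- vapply(results, function(r) {
    b <- r$bytes_streamed
    if (is.null(b) || is.na(b)) 0 else as.numeric(b)
  }, numeric(1))
  sum(bytes) / wall_seconds_total
}

#' Scaled speedup across worker counts
#'
#' Speedup at `n` workers is `T_1 / T_n`; scaled speedup divides by `n`, so
#' 1.0 corresponds to linear scaling (the theoretical upper bound for an
#' ideal scheduler, up to remainder effects when tasks do not divide
#' evenly).
#'
#' @param timings data.frame with columns `n` (worker count) and
#'   `wall_seconds` (job wall time at that count); must include `n = 1`.
#' @return Named numeric vector mapping each `n` to `(T_1 / T_n) / n`.
#' @export
scaled_speedup <- function(timings) {
  if (!is.data.frame(timings) ||
      !all(c("n", "wall_seconds") %in% names(timings))) {
    stop_validation("timings must have columns n and wall_seconds")
  }
  if (any(timings$wall_seconds <= 0) || any(timings$n < 1)) {
    stop_validation("need wall_seconds > 0 and n >= 1")
  }
  base <- timings$wall_seconds[timings$n == 1]
  if (length(base) == 0L) {
    stop_validation("timings must include the n = 1 baseline")
  }
  t1 <- base[1L]
  out <- (t1 / timings$wall_seconds) / timings$n
  names(out) <- as.character(timings$n)
  out
}
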