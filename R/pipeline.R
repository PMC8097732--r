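#' Assemble a pipeline run configuration
#'
#' Validates paths and parameters for [run_pipeline()]. Can also be loaded
#' from a YAML file with `run_config_from_yaml()`.
#'
#' @param reference Reference FASTA path.
#' @param locus BED locus descriptor path.
#' @param samples Sample sheet TSV path (`sample_id`, `fastq`, `condition`,
#'   `time_min`, `replicate`).
#' @param out_dir Output directory.
#' @param flank Window flank length (nt).
#' @param adapter Optional 3' adapter to trim (`NULL` disables trimming).
#' @param min_overlap,max_error_rate Adapter-trimming parameters.
#' @param min_len Minimum read length after trimming.
#' @param scoring A [scoring_scheme()].
#' @param thresholds A [filter_thresholds()].
#' @param include_unclassified Include `UNCLASSIFIED` in percentage
#'   denominators?
#' @return A `run_config` list.
#' @export
run_config <- function(reference, locus, samples, out_dir,
                       flank = 50L, adapter = NULL, min_overlap = 3L,
                       max_error_rate = 0.1, min_len = 15L,
                       scoring = scoring_scheme(),
                       thresholds = filter_thresholds(),
                       include_unclassified = FALSE) {
  for (p in c(reference, locus, samples)) {
    if (!file.exists(p))
      abort(paste0("input file does not exist: ", p),
            class = "trfcat_config_error")
  }
  if (!is.null(adapter) &&
      (!is.character(adapter) || nchar(adapter) == 0))
    abort("adapter must be NULL or a non-empty sequence",
          class = "trfcat_config_error")
  structure(list(reference = reference, locus = locus, samples = samples,
                 out_dir = out_dir, flank = as.integer(flank),
                 adapter = adapter, min_overlap = as.integer(min_overlap),
                 max_error_rate = max_error_rate, min_len = as.integer(min_len),
                 scoring = scoring, thresholds = thresholds,
                 include_unclassified = isTRUE(include_unclassified)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields above (`scoring`/`thresholds` as
#'   nested maps).
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("reference", "locus", "samples", "out_dir")
  miss <- setdiff(required, names(y))
  if (length(miss))
    abort(paste0("config missing fields: ", paste(miss, collapse = ", ")),
          class = "trfcat_config_error")
  scoring <- if (!is.null(y$scoring)) do.call(scoring_scheme, y$scoring)
             else scoring_scheme()
  thresholds <- if (!is.null(y$thresholds))
    do.call(filter_thresholds, y$thresholds) else filter_thresholds()
  run_config(reference = y$reference, locus = y$locus, samples = y$samples,
             out_dir = y$out_dir, flank = y$flank %||% 50L,
             adapter = y$adapter, min_overlap = y$min_overlap %||% 3L,
             max_error_rate = y$max_error_rate %||% 0.1,
             min_len = y$min_len %||% 15L, scoring = scoring,
             thresholds = thresholds,
             include_unclassified = y$include_unclassified %||% FALSE)
}

#' Run the full profiling pipeline
#'
#' simulate/trim -> filter -> map -> classify -> profile -> report, with a
#' per-sample run log that accounts for every input read
#' (`input == kept + dropped`; `kept == mapped + antisense + unmapped`;
#' `mapped == sum of category counts`). Identical configuration and inputs
#' produce byte-identical TSV outputs.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisible list with `per_read`, `profiles`, `percentages`,
#'   `timecourse`, `run_log` tibbles and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  genome <- read_reference(config$reference)
  locus <- load_locus(config$reference, config$locus)
  window <- build_window(genome, locus, flank = config$flank)
  sheet <- readr::read_tsv(config$samples, show_col_types = FALSE)
  need <- c("sample_id", "fastq", "condition", "time_min", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    abort(paste0("sample sheet missing columns: ",
                 paste(miss, collapse = ", ")),
          class = "trfcat_config_error")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  per_read <- purrr::map(seq_len(nrow(sheet)), function(i) {
    reads <- read_sequences(sheet$fastq[i])
    if (!is.null(config$adapter) && nrow(reads))
      reads <- trim_adapter(reads, config$adapter,
                            min_overlap = config$min_overlap,
                            max_error_rate = config$max_error_rate)
    classify_sample(reads, window, sample_id = sheet$sample_id[i],
                    min_len = config$min_len, scoring = config$scoring,
                    thresholds = config$thresholds)
  }) %>% bind_rows()

  run_log <- pipeline_log(per_read)
  check_conservation(per_read, run_log)

  labelled <- per_read %>% filter(!is.na(.data$category))
  if (!nrow(labelled))
    abort("no reads were mapped in any sample", class = "trfcat_runtime_error")
  profiles <- count_categories(per_read)
  percentages <- category_percentages(
    profiles, include_unclassified = config$include_unclassified)
  tc <- aggregate_replicates(profiles, sheet)

  out <- config$out_dir
  paths <- list(per_read = file.path(out, "per_read.tsv"),
                profiles = file.path(out, "profiles.tsv"),
                percentages = file.path(out, "percentages.tsv"),
                run_log = file.path(out, "run_log.tsv"))
  readr::write_tsv(per_read %>% select(-"ops"), paths$per_read)
  readr::write_tsv(tidy(profiles), paths$profiles)
  readr::write_tsv(percentages, paths$percentages)
  readr::write_tsv(run_log, paths$run_log)
  report_files <- report_timecourse(tc, out)
  invisible(list(per_read = per_read, profiles = profiles,
                 percentages = percentages, timecourse = tc,
                 run_log = run_log, window = window,
                 files = c(unlist(paths), report_files)))
}

#' Per-sample read accounting
#'
#' @param per_read Per-read tibble from [classify_sample()] (any number of
#'   samples).
#' @return Tibble with per-sample input/kept/dropped/mapped/antisense/
#'   unmapped/classified counts.
#' @export
pipeline_log <- function(per_read) {
  per_read %>%
    group_by(.data$sample_id) %>%
    summarise(
      input = dplyr::n(),
      dropped = sum(.data$status == "dropped"),
      kept = sum(.data$status != "dropped"),
      mapped = sum(.data$status == "mapped"),
      antisense = sum(.data$status == "antisense"),
      unmapped = sum(.data$status == "unmapped"),
      classified = sum(!is.na(.data$category)),
      .groups = "drop")
}

#' Assert read-count conservation across pipeline stages
#'
#' Errors (class `trfcat_conservation_error`) unless, for every sample,
#' `input == kept + dropped`, `kept == mapped + antisense + unmapped` and
#' `mapped == classified` (category counts partition the mapped total).
#'
#' @param per_read Per-read tibble.
#' @param log Optional precomputed [pipeline_log()].
#' @return `TRUE` invisibly on success.
#' @export
check_conservation <- function(per_read, log = NULL) {
  if (is.null(log)) log <- pipeline_log(per_read)
  ok <- with(log, all(input == kept + dropped) &&
               all(kept == mapped + antisense + unmapped) &&
               all(mapped == classified))
  if (!ok)
    abort("read-count conservation violated across pipeline stages",
          class = "trfcat_conservation_error")
  invisible(TRUE)
}
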