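#' Count category labels per sample
#'
#' Tallies per-read category labels into a per-sample profile over the full
#' category grid (zero-filled). Only mapped reads carry labels; the counts
#' therefore partition each sample's mapped total exactly.
#'
#' @param classified Per-read tibble with `sample_id` and `category`
#'   (e.g. from [classify_sample()]); rows with `NA` category (dropped,
#'   unmapped, antisense reads) are ignored.
#' @return Tibble `sample_id`, `category`, `count` plus one
#'   `total_mapped` value per sample, class `trf_profile`.
#' @export
count_categories <- function(classified) {
  stopifnot(all(c("sample_id", "category") %in% names(classified)))
  labelled <- classified %>% filter(!is.na(.data$category))
  prof <- labelled %>%
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS)) %>%
    count(.data$sample_id, .data$category, name = "count") %>%
    tidyr::complete(sample_id = unique(labelled$sample_id),
                    category = factor(CATEGORY_LEVELS,
                                      levels = CATEGORY_LEVELS),
                    fill = list(count = 0L)) %>%
    group_by(.data$sample_id) %>%
    mutate(total_mapped = sum(.data$count)) %>%
    ungroup() %>%
    arrange(.data$sample_id, .data$category)
  class(prof) <- c("trf_profile", class(prof))
  prof
}

#' Category percentages of a profile
#'
#' Percentages are computed over the classified total; `UNCLASSIFIED` reads
#' are excluded from the denominator by default (and reported separately),
#' matching how published category percentages span only the nine
#' categories. With several samples and `pool = TRUE`, counts are summed
#' across samples before dividing, so the pooled percentage equals the
#' count-weighted mean of per-sample percentages.
#'
#' @param profile A `trf_profile` (one or more samples).
#' @param pool Sum counts across samples before computing percentages?
#' @param include_unclassified Keep `UNCLASSIFIED` in the denominator?
#' @return Tibble `sample_id` (or `"pooled"`), `category`, `count`,
#'   `percent`.
#' @export
category_percentages <- function(profile, pool = FALSE,
                                 include_unclassified = FALSE) {
  x <- profile
  if (pool) {
    x <- x %>% group_by(.data$category) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      mutate(sample_id = "pooled")
  }
  x <- x %>%
    mutate(in_denom = include_unclassified |
             .data$category != "UNCLASSIFIED") %>%
    group_by(.data$sample_id) %>%
    mutate(denom = sum(.data$count[.data$in_denom])) %>%
    ungroup()
  if (any(x$denom == 0))
    abort("cannot compute percentages: classified total is zero",
          class = "trfcat_zero_total")
  x %>%
    mutate(percent = ifelse(.data$in_denom, 100 * .data$count / .data$denom,
                            NA_real_)) %>%
    select("sample_id", "category", "count", "percent")
}

#' Aggregate replicate profiles into a time course
#'
#' Joins profiles to a sample sheet and computes, per (condition, time,
#' category), the arithmetic mean of counts across replicates, the standard
#' error of the mean (sample SD, n-1 denominator, divided by sqrt(n)), and
#' the replicate number. With a single replicate the SEM is reported as
#' `NA`, not 0.
#'
#' @param profile A `trf_profile` covering all samples.
#' @param sample_sheet Tibble `sample_id`, `condition`, `time_min`,
#'   `replicate`.
#' @return Tibble `condition`, `time_min`, `category`, `n`, `mean_count`,
#'   `sd_count`, `sem`, class `trf_timecourse`.
#' @export
aggregate_replicates <- function(profile, sample_sheet) {
  missing <- setdiff(unique(profile$sample_id), sample_sheet$sample_id)
  if (length(missing))
    abort(paste0("sample(s) not in sample sheet: ",
                 paste(missing, collapse = ", ")),
          class = "trfcat_config_error")
  tc <- profile %>%
    inner_join(sample_sheet, by = "sample_id") %>%
    group_by(.data$condition, .data$time_min, .data$category) %>%
    summarise(n = dplyr::n(),
              mean_count = mean(.data$count),
              sd_count = if (dplyr::n() > 1) sd(.data$count) else NA_real_,
              .groups = "drop") %>%
    mutate(sem = .data$sd_count / sqrt(.data$n)) %>%
    arrange(.data$condition, .data$time_min, .data$category)
  class(tc) <- c("trf_timecourse", class(tc))
  tc
}

#' @method tidy trf_timecourse
#' @export
tidy.trf_timecourse <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @method glance trf_timecourse
#' @export
glance.trf_timecourse <- function(x, ...) {
  tibble(n_conditions = dplyr::n_distinct(x$condition),
         n_timepoints = dplyr::n_distinct(x$time_min),
         n_categories = dplyr::n_distinct(x$category),
         max_replicates = max(x$n),
         total_mean_reads = sum(x$mean_count))
}

#' @method tidy trf_profile
#' @export
tidy.trf_profile <- function(x, ...) as_tibble(unclass_tbl(x))

#' @method glance trf_profile
#' @export
glance.trf_profile <- function(x, ...) {
  x %>% group_by(.data$sample_id) %>%
    summarise(total_mapped = sum(.data$count),
              n_categories_seen = sum(.data$count > 0), .groups = "drop")
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("trf_profile", "trf_timecourse"))
  x
}

#' Write time-course report tables and trend plots
#'
#' Emits a tidy TSV, a wide TSV (one row per category, mean and SEM columns
#' per condition x time), and one per-category trend plot (mean count vs
#' time, one series per condition, SEM error bars). Output is byte-stable
#' across reruns on identical input.
#'
#' @param tc A `trf_timecourse`.
#' @param out_dir Output directory (created if needed).
#' @param plot_format Device for plots, `"png"` or `"pdf"`.
#' @return Invisible character vector of files written.
#' @export
report_timecourse <- function(tc, out_dir, plot_format = c("png", "pdf")) {
  plot_format <- match.arg(plot_format)
  if (!nrow(tc)) abort("empty time course", class = "trfcat_config_error")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(paste0("cannot create output directory ", out_dir),
          class = "trfcat_io_error")
  files <- character(0)
  tidy_path <- file.path(out_dir, "timecourse.tsv")
  readr::write_tsv(tidy(tc), tidy_path)
  wide <- tc %>%
    mutate(series = paste0(.data$condition, "_T", .data$time_min)) %>%
    select("category", "series", "mean_count", "sem") %>%
    tidyr::pivot_wider(names_from = "series",
                       values_from = c("mean_count", "sem"))
  wide_path <- file.path(out_dir, "timecourse_wide.tsv")
  readr::write_tsv(wide, wide_path)
  files <- c(tidy_path, wide_path)
  plot_dir <- file.path(out_dir, "plots")
  dir.create(plot_dir, showWarnings = FALSE)
  for (cat_i in unique(as.character(tc$category))) {
    p <- plot_category_trend(tc, cat_i)
    f <- file.path(plot_dir, paste0("category_", cat_i, ".", plot_format))
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 150)
    files <- c(files, f)
  }
  invisible(files)
}

#' Summarise a mapped-read accounting table
#'
#' Convenience over a per-run accounting table (columns `condition`,
#' `time_min`, `mapped_reads`): total mapped reads, and per-(condition,
#' time) replicate means.
#'
#' @param tbl Tibble as returned by [study_mapped_reads()].
#' @return List with `total_mapped` and a `per_timepoint` tibble.
#' @export
mapped_read_summary <- function(tbl) {
  per <- tbl %>%
    group_by(.data$condition, .data$time_min) %>%
    summarise(n = dplyr::n(), mean_mapped = mean(.data$mapped_reads),
              .groups = "drop")
  list(total_mapped = sum(tbl$mapped_reads), per_timepoint = per)
}

#' Packaged per-run read accounting for the GSE81238 tRNA-Cys analysis
#'
#' Per-run total and tRNA-Cys-mapped read counts for the 14 public small-RNA
#' sequencing runs (GEO accession GSE81238; dormant spores at T0 and
#' outgrowth at 30/60/90 min with and without 1.2 M NaCl, two replicates
#' each).
#'
#' @return Tibble `run`, `condition`, `time_min`, `replicate`,
#'   `total_reads`, `mapped_reads`.
#' @export
study_mapped_reads <- function() {
  path <- system.file("extdata", "gse81238_trnacys_mapped_reads.tsv",
                      package = "trfcat", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
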