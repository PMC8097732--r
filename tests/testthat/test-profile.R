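make_classified <- function(sample_id, cats) {
  tibble::tibble(sample_id = sample_id, category = cats)
}

test_that("category counting fills the full grid and records totals", {
  cl <- make_classified("s1", c("III", "III", "VII", "VII"))
  prof <- count_categories(cl)
  expect_equal(nrow(prof), length(trf_categories()))
  expect_equal(prof$count[prof$category == "III"], 2L)
  expect_equal(prof$count[prof$category == "VII"], 2L)
  expect_equal(sum(prof$count), 4L)
  expect_equal(unique(prof$total_mapped), 4L)
  # NA categories (unmapped/dropped reads) are ignored
  cl2 <- dplyr::bind_rows(cl, make_classified("s1", c(NA, NA)))
  expect_equal(sum(count_categories(cl2)$count), 4L)
})

test_that("percentages divide by the classified total, pooling sums counts", {
  prof <- count_categories(make_classified("s1", c("III", "III", "VII", "VII")))
  pct <- category_percentages(prof)
  expect_equal(pct$percent[pct$category == "III"], 50)
  expect_equal(pct$percent[pct$category == "VII"], 50)
  expect_equal(sum(pct$percent, na.rm = TRUE), 100, tolerance = 1e-9)

  # pooled percentage = summed counts: {III:1, of 4} + {III:3, of 4} -> 50%
  two <- dplyr::bind_rows(
    make_classified("a", c("III", "VII", "VII", "VII")),
    make_classified("b", c("III", "III", "III", "VII")))
  pooled <- category_percentages(count_categories(two), pool = TRUE)
  expect_equal(pooled$percent[pooled$category == "III"], 50)

  # zero classified total errors out
  empty <- count_categories(make_classified("s", "UNCLASSIFIED"))
  expect_error(category_percentages(empty), class = "trfcat_zero_total")
})

test_that("pooled percentages equal count-weighted means of replicates", {
  withr::with_seed(61, {
    for (k in 1:10) {
      cats <- sample(trf_categories()[1:9], 60, TRUE)
      cl <- tibble::tibble(sample_id = sample(c("r1", "r2", "r3"), 60, TRUE),
                           category = cats)
      prof <- count_categories(cl)
      per <- category_percentages(prof)
      pooled <- category_percentages(prof, pool = TRUE)
      totals <- prof %>% dplyr::group_by(sample_id) %>%
        dplyr::summarise(t = sum(count))
      joined <- per %>% dplyr::left_join(totals, by = "sample_id") %>%
        dplyr::group_by(category) %>%
        dplyr::summarise(wmean = sum(percent * t) / sum(t))
      cmp <- dplyr::left_join(pooled, joined, by = "category")
      expect_equal(cmp$percent, cmp$wmean, tolerance = 1e-9)
    }
  })
})

test_that("replicate aggregation computes means and SEM as sd/sqrt(n)", {
  sheet <- tibble::tibble(sample_id = c("a", "b"), condition = "dormant",
                          time_min = 0, replicate = 1:2)
  # replicate totals 243 and 349 average to 296
  cl <- dplyr::bind_rows(
    make_classified("a", rep("III", 243)),
    make_classified("b", rep("III", 349)))
  tc <- aggregate_replicates(count_categories(cl), sheet)
  row <- tc %>% dplyr::filter(category == "III")
  expect_equal(row$mean_count, 296)
  expect_equal(row$n, 2L)
  # counts 93 and 95 -> mean 94, SEM sd/sqrt(2) = 1
  cl2 <- dplyr::bind_rows(make_classified("a", rep("V", 93)),
                          make_classified("b", rep("V", 95)))
  tc2 <- aggregate_replicates(count_categories(cl2), sheet)
  row2 <- tc2 %>% dplyr::filter(category == "V")
  expect_equal(row2$mean_count, 94)
  expect_equal(row2$sem, 1)
  # equal counts -> SEM exactly 0
  expect_equal((tc2 %>% dplyr::filter(category == "III"))$sem, 0)
})

test_that("single replicates report SEM as NA and aggregation is order-invariant", {
  sheet <- tibble::tibble(sample_id = c("solo", "x", "y"),
                          condition = c("dormant", "nacl", "nacl"),
                          time_min = c(0, 30, 30), replicate = c(1, 1, 2))
  cl <- dplyr::bind_rows(make_classified("solo", rep("III", 5)),
                         make_classified("x", rep("III", 4)),
                         make_classified("y", rep("III", 8)))
  prof <- count_categories(cl)
  tc <- aggregate_replicates(prof, sheet)
  solo <- tc %>% dplyr::filter(condition == "dormant", category == "III")
  expect_true(is.na(solo$sem))
  expect_equal(solo$n, 1L)
  # permutation invariance in replicate order
  perm <- prof[rev(seq_len(nrow(prof))), ]
  tc_perm <- aggregate_replicates(perm, sheet)
  expect_equal(tidy(tc), tidy(tc_perm))
  # unknown sample id is a config error
  expect_error(aggregate_replicates(prof, sheet[-1, ]),
               class = "trfcat_config_error")
})

test_that("report writes deterministic tables and one plot per category", {
  sheet <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                          condition = c("no_nacl", "no_nacl", "nacl", "nacl"),
                          time_min = c(30, 60, 30, 60), replicate = 1L)
  cl <- dplyr::bind_rows(
    make_classified("a", c("III", "VII")), make_classified("b", "III"),
    make_classified("c", c("I", "I", "VII")), make_classified("d", "IX"))
  tc <- aggregate_replicates(count_categories(cl), sheet)
  out1 <- tempfile()
  out2 <- tempfile()
  f1 <- report_timecourse(tc, out1)
  f2 <- report_timecourse(tc, out2)
  expect_identical(readLines(file.path(out1, "timecourse.tsv")),
                   readLines(file.path(out2, "timecourse.tsv")))
  expect_identical(readLines(file.path(out1, "timecourse_wide.tsv")),
                   readLines(file.path(out2, "timecourse_wide.tsv")))
  wide <- readr::read_tsv(file.path(out1, "timecourse_wide.tsv"),
                          show_col_types = FALSE)
  # 2 conditions x 2 times -> 4 mean + 4 sem columns per category row
  expect_equal(ncol(wide), 1 + 8)
  expect_equal(nrow(wide), length(trf_categories()))
  expect_true(all(file.exists(
    file.path(out1, "plots", paste0("category_", trf_categories(), ".png")))))
  # dormant-only (single-timepoint) input renders without error
  sheet0 <- tibble::tibble(sample_id = "s", condition = "dormant",
                           time_min = 0, replicate = 1L)
  tc0 <- aggregate_replicates(
    count_categories(make_classified("s", c("III", "VII"))), sheet0)
  expect_no_error(report_timecourse(tc0, tempfile()))
})

test_that("tidy/glance/autoplot methods behave like broom/ggplot idioms", {
  sheet <- tibble::tibble(sample_id = c("a", "b"), condition = "nacl",
                          time_min = c(30, 60), replicate = 1L)
  prof <- count_categories(dplyr::bind_rows(
    make_classified("a", c("III", "VII")), make_classified("b", "I")))
  tc <- aggregate_replicates(prof, sheet)
  td <- tidy(tc)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "trf_timecourse"))
  gl <- glance(tc)
  expect_equal(gl$n_conditions, 1L)
  expect_equal(gl$n_timepoints, 2L)
  expect_s3_class(autoplot(tc), "ggplot")
  expect_s3_class(autoplot(prof), "ggplot")
  expect_equal(nrow(glance(prof)), 2L)
})

test_that("study accounting table sums and averages correctly", {
  tbl <- study_mapped_reads()
  expect_equal(nrow(tbl), 14L)
  s <- mapped_read_summary(tbl)
  expect_equal(s$total_mapped, 9163L)
  t0 <- s$per_timepoint %>% dplyr::filter(condition == "dormant")
  expect_equal(t0$mean_mapped, 296)
})
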