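#' Decompose mapped reads into gene coverage and end extensions
#'
#' For each sense-mapped read, walks the alignment columns to find the
#' covered gene interval, the read bases preceding/following it
#' (`five_extra` / `three_extra`), and how much of each extension is
#' genomically encoded. Bases *aligned* within the flank regions count
#' toward the genomic extension length; soft-clipped bases extend it only by
#' contiguous exact match against the flank sequence. The residual
#' post-transcriptional tail is `three_extra` with its genomic prefix
#' removed.
#'
#' @param mapped Output of [map_reads()] (sense rows are annotated; antisense
#'   and unmapped rows pass through with `NA` annotation columns).
#' @param window A `reference_window`.
#' @return `mapped` with columns appended: `gene_covered`, `gene_start`,
#'   `gene_end`, `five_extra`, `three_extra`, `five_genomic_len`,
#'   `three_genomic_len`, `tail`, `ambiguous_flank_c`.
#' @export
annotate_ends <- function(mapped, window) {
  empty <- list(gene_covered = FALSE, gene_start = NA_integer_,
                gene_end = NA_integer_, five_extra = NA_character_,
                three_extra = NA_character_, five_genomic_len = NA_integer_,
                three_genomic_len = NA_integer_, tail = NA_character_,
                ambiguous_flank_c = FALSE)
  ann <- purrr::pmap(
    mapped[c("status", "seq", "ops", "window_start", "window_end",
             "read_start", "read_end", "left_clip", "right_clip")],
    function(status, seq, ops, window_start, window_end, read_start,
             read_end, left_clip, right_clip) {
      if (status != "mapped") return(empty)
      annotate_one(seq, ops, window_start, window_end, read_start, read_end,
                   left_clip, right_clip, window)
    })
  bind_cols(mapped, bind_rows(ann))
}

annotate_one <- function(seq, ops, window_start, window_end, read_start,
                         read_end, left_clip, right_clip, window) {
  v <- strsplit(ops, "")[[1]]
  wseq <- window$window_seq
  g1 <- window$gene_offset + 1L
  g2 <- window$gene_offset + window$gene_length
  # per-column window position (NA for I) and read position (NA for D)
  consumes_w <- v != "I"
  consumes_r <- v != "D"
  wpos <- ifelse(consumes_w, window_start - 1L + cumsum(consumes_w),
                 NA_integer_)
  rpos <- ifelse(consumes_r, read_start - 1L + cumsum(consumes_r),
                 NA_integer_)
  gene_cols <- which(v %in% c("=", "X") & !is.na(wpos) & wpos >= g1 &
                       wpos <= g2)
  if (!length(gene_cols)) {
    return(list(gene_covered = FALSE, gene_start = NA_integer_,
                gene_end = NA_integer_, five_extra = NA_character_,
                three_extra = NA_character_, five_genomic_len = NA_integer_,
                three_genomic_len = NA_integer_, tail = NA_character_,
                ambiguous_flank_c = FALSE))
  }
  first_g <- min(gene_cols)
  last_g <- max(gene_cols)
  gene_start <- wpos[first_g] - window$gene_offset
  gene_end <- wpos[last_g] - window$gene_offset
  read_chars <- strsplit(seq, "")[[1]]

  # --- 5' side -------------------------------------------------------------
  pre_cols <- if (first_g > 1L) seq_len(first_g - 1L) else integer(0)
  pre_r <- rpos[pre_cols]
  five_aln <- paste(read_chars[pre_r[!is.na(pre_r)]], collapse = "")
  five_extra <- paste0(left_clip, five_aln)
  five_genomic <- 0L
  reached_start <- TRUE
  for (k in rev(pre_cols)) {
    if (v[k] %in% c("=", "X")) {
      five_genomic <- five_genomic + 1L
    } else if (v[k] == "I") {
      reached_start <- FALSE
      break
    } # D: window-only column, contiguity in the flank continues
  }
  if (reached_start && nchar(left_clip) > 0L) {
    wp <- window_start - 1L
    for (i in rev(seq_len(nchar(left_clip)))) {
      if (wp < 1L) break
      if (substr(left_clip, i, i) == substr(wseq, wp, wp)) {
        five_genomic <- five_genomic + 1L
        wp <- wp - 1L
      } else break
    }
  }

  # --- 3' side -------------------------------------------------------------
  n_cols <- length(v)
  post_cols <- if (last_g < n_cols) seq.int(last_g + 1L, n_cols) else integer(0)
  post_r <- rpos[post_cols]
  three_aln <- paste(read_chars[post_r[!is.na(post_r)]], collapse = "")
  three_extra <- paste0(three_aln, right_clip)
  three_genomic <- 0L
  reached_end <- TRUE
  for (k in post_cols) {
    if (v[k] %in% c("=", "X")) {
      three_genomic <- three_genomic + 1L
    } else if (v[k] == "I") {
      reached_end <- FALSE
      break
    }
  }
  if (reached_end && nchar(right_clip) > 0L) {
    wp <- window_end + 1L
    for (i in seq_len(nchar(right_clip))) {
      if (wp > nchar(wseq)) break
      if (substr(right_clip, i, i) == substr(wseq, wp, wp)) {
        three_genomic <- three_genomic + 1L
        wp <- wp + 1L
      } else break
    }
  }
  tail_str <- substr(three_extra, three_genomic + 1L, nchar(three_extra))
  flank_first <- if (g2 + 1L <= nchar(wseq)) substr(wseq, g2 + 1L, g2 + 1L)
                 else ""
  list(gene_covered = TRUE, gene_start = as.integer(gene_start),
       gene_end = as.integer(gene_end), five_extra = five_extra,
       three_extra = three_extra, five_genomic_len = as.integer(five_genomic),
       three_genomic_len = as.integer(three_genomic), tail = tail_str,
       ambiguous_flank_c = identical(flank_first, "C") &&
         nchar(three_extra) > 0L)
}

#' Assign maturation/fragmentation categories
#'
#' Applies the category decision rules, in precedence order, to annotated
#' reads (see [annotate_ends()]):
#' 1. any genomic 5' or 3' extension -> `I` (precursor);
#' 2. full-length (gene positions 1..L): empty tail -> `II`, `CCA` -> `III`,
#'    `CC` -> `IV`, anything else -> `VIII`;
#' 3. 3'-tRF (start >= 2, end == L, non-empty tail): `CCA` -> `V`,
#'    `CC` -> `VI`, anything else -> `IX`;
#' 4. everything else (end < L, or start >= 2 with empty tail) -> `VII`
#'    (5'-tRF / internal fragment; `trf_n = L - gene_end`).
#'
#' Tail vocabulary is matched verbatim: a sequencing error inside a CCA tail
#' lands in `VIII`/`IX` by design. Reads covering no gene position are
#' `UNCLASSIFIED`; antisense/unmapped reads keep `NA`.
#'
#' @param annotated Output of [annotate_ends()].
#' @param gene_length Encoded gene length (71 for the tRNA-Cys model).
#' @return Input with `category` (factor over [trf_categories()]), `trf_n`
#'   and `flags` (comma-separated) appended.
#' @export
classify_reads <- function(annotated, gene_length = 71L) {
  res <- purrr::pmap(
    annotated[c("status", "gene_covered", "gene_start", "gene_end",
                "five_extra", "five_genomic_len", "three_genomic_len",
                "tail")],
    classify_one, gene_length = as.integer(gene_length))
  bind_cols(annotated, bind_rows(res)) %>%
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS))
}

classify_one <- function(status, gene_covered, gene_start, gene_end,
                         five_extra, five_genomic_len, three_genomic_len,
                         tail, gene_length = 71L) {
  if (is.na(status) || status != "mapped") {
    return(list(category = NA_character_, trf_n = NA_integer_,
                flags = NA_character_))
  }
  if (!isTRUE(gene_covered)) {
    return(list(category = "UNCLASSIFIED", trf_n = NA_integer_,
                flags = "flank_only"))
  }
  flags <- character(0)
  if (nchar(five_extra) > five_genomic_len) flags <- c(flags, "nongenomic_5prime")
  full <- gene_start == 1L && gene_end == gene_length
  cat <- if (five_genomic_len >= 1L || three_genomic_len >= 1L) {
    "I"
  } else if (full) {
    switch(tail, "CCA" = "III", "CC" = "IV",
           if (tail == "") "II" else "VIII")
  } else if (gene_start >= 2L && gene_end == gene_length && tail != "") {
    switch(tail, "CCA" = "V", "CC" = "VI", "IX")
  } else {
    "VII"
  }
  if (cat == "VII") {
    if (gene_start >= 2L && gene_end == gene_length && tail == "")
      flags <- c(flags, "three_trf_no_tail")
    if (gene_end < gene_length && tail != "")
      flags <- c(flags, "tail_before_71")
    if (gene_start == 1L && gene_end < gene_length)
      flags <- c(flags, "five_trf")
    if (gene_start >= 2L && gene_end < gene_length)
      flags <- c(flags, "internal")
  }
  if (cat %in% c("VIII", "IX") && tail == "C") flags <- c(flags, "single_c_tail")
  list(category = cat,
       trf_n = as.integer(gene_length - gene_end),
       flags = if (length(flags)) paste(flags, collapse = ",")
               else NA_character_)
}

#' End-to-end per-read classification for one sample
#'
#' Convenience chain: quality filtering, mapping, end annotation and category
#' assignment for one sample's reads. Adapter trimming, if wanted, is done
#' beforehand with [trim_adapter()].
#'
#' @param reads Tibble from [read_sequences()] (or the simulator).
#' @param window A `reference_window`.
#' @param sample_id Sample label added to the output.
#' @param min_len Minimum read length (see [filter_reads()]).
#' @param scoring,thresholds Alignment parameters.
#' @return Tibble with one row per *input* read: dropped reads keep their
#'   `drop_reason`, surviving reads carry mapping status, end annotation and
#'   `category`.
#' @export
classify_sample <- function(reads, window, sample_id = "sample",
                            min_len = 15L, scoring = scoring_scheme(),
                            thresholds = filter_thresholds()) {
  filt <- filter_reads(reads, min_len = min_len)
  kept <- kept_reads(filt)
  dropped <- filt %>% filter(!.data$keep) %>%
    transmute(.data$read_id, .data$seq, read_len = nchar(.data$seq),
              status = "dropped", fail_reason = .data$drop_reason)
  out <- if (nrow(kept)) {
    map_reads(kept[c("read_id", "seq")], window, scoring, thresholds) %>%
      annotate_ends(window) %>%
      classify_reads(gene_length = window$gene_length)
  } else tibble()
  bind_rows(out, dropped) %>%
    mutate(sample_id = sample_id) %>%
    select("sample_id", everything())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
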