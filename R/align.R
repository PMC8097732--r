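#' Alignment scoring scheme
#'
#' Default local-alignment scoring: match +2, mismatch -3, gap open -5,
#' gap extend -2 (a gap of length L costs `gap_open + (L-1) * gap_extend`).
#'
#' @param match Positive match score.
#' @param mismatch,gap_open,gap_extend Non-positive penalties.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Mapping filter thresholds
#'
#' Alignments must cover at least `min_length_fraction` of the read, show at
#' least `min_similarity_fraction` identical columns over all alignment
#' columns (gap columns included), and contain at most `max_mismatches`
#' substituted columns and `max_indels` gap *events* (insertion/deletion
#' runs, not gapped bases).
#'
#' @param min_length_fraction,min_similarity_fraction Fractions in (0, 1].
#' @param max_mismatches,max_indels Non-negative integer budgets.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_length_fraction = 0.8,
                              min_similarity_fraction = 0.8,
                              max_mismatches = 2L, max_indels = 3L) {
  stopifnot(min_length_fraction > 0, min_length_fraction <= 1,
            min_similarity_fraction > 0, min_similarity_fraction <= 1,
            max_mismatches >= 0, max_indels >= 0)
  structure(list(min_length_fraction = min_length_fraction,
                 min_similarity_fraction = min_similarity_fraction,
                 max_mismatches = as.integer(max_mismatches),
                 max_indels = as.integer(max_indels)),
            class = "filter_thresholds")
}

#' Best local alignment of one read against the window
#'
#' Smith-Waterman with affine gaps. Ties are resolved deterministically
#' (leftmost window end coordinate, then leftmost read coordinate, diagonal-
#' preferring traceback). A zero/negative best score yields an unaligned
#' result (`aligned = FALSE`).
#'
#' @param read_seq Read sequence.
#' @param window_seq Window (reference) sequence.
#' @param scoring A [scoring_scheme()].
#' @return One-row tibble: `score`, `read_start`, `read_end`, `window_start`,
#'   `window_end`, `ops` (per-column string over `=XID`), `cigar`
#'   (run-length-compressed ops), per-category counts, `n_gap_events`,
#'   `left_clip`, `right_clip`, `aligned`.
#' @export
smith_waterman <- function(read_seq, window_seq, scoring = scoring_scheme()) {
  stopifnot(nchar(read_seq) > 0, nchar(window_seq) > 0)
  res <- sw_align_cpp(toupper(read_seq), toupper(window_seq),
                      scoring$match, scoring$mismatch, scoring$gap_open,
                      scoring$gap_extend)
  ops <- res$ops
  counts <- count_ops(ops)
  aligned <- res$score > 0
  tibble(
    score = res$score,
    read_start = res$read_start, read_end = res$read_end,
    window_start = res$ref_start, window_end = res$ref_end,
    ops = ops, cigar = compress_ops(ops),
    n_match = counts[["match"]], n_mismatch = counts[["mismatch"]],
    n_ins_bases = counts[["ins"]], n_del_bases = counts[["del"]],
    n_gap_events = counts[["gap_events"]],
    left_clip = if (aligned) substr(read_seq, 1L, res$read_start - 1L) else "",
    right_clip = if (aligned) substr(read_seq, res$read_end + 1L,
                                     nchar(read_seq)) else read_seq,
    aligned = aligned)
}

count_ops <- function(ops) {
  if (!nchar(ops)) {
    return(c(match = 0L, mismatch = 0L, ins = 0L, del = 0L, gap_events = 0L))
  }
  v <- strsplit(ops, "")[[1]]
  r <- rle(v)
  c(match = sum(v == "="), mismatch = sum(v == "X"),
    ins = sum(v == "I"), del = sum(v == "D"),
    gap_events = sum(r$values %in% c("I", "D")))
}

compress_ops <- function(ops) {
  if (!nchar(ops)) return("")
  r <- rle(strsplit(ops, "")[[1]])
  paste0(r$lengths, r$values, collapse = "")
}

#' Apply the mapping filters to alignments
#'
#' Pass iff aligned read bases / read length >= `min_length_fraction`, AND
#' matches / alignment columns >= `min_similarity_fraction`, AND mismatches
#' <= `max_mismatches`, AND gap events <= `max_indels`. The first failing
#' check (in that order) is recorded as the reason.
#'
#' @param aln Tibble with columns `n_match`, `n_mismatch`, `n_ins_bases`,
#'   `n_del_bases`, `n_gap_events`, `read_len` and `aligned` (rows as from
#'   [smith_waterman()] plus a `read_len` column).
#' @param thresholds A [filter_thresholds()].
#' @return `aln` with logical `pass` and character `fail_reason` appended.
#' @export
passes_filters <- function(aln, thresholds = filter_thresholds()) {
  aligned_bases <- aln$n_match + aln$n_mismatch + aln$n_ins_bases
  columns <- aligned_bases + aln$n_del_bases
  length_frac <- aligned_bases / aln$read_len
  sim_frac <- ifelse(columns > 0, aln$n_match / columns, 0)
  reason <- dplyr::case_when(
    !aln$aligned ~ "no_local_alignment",
    length_frac < thresholds$min_length_fraction ~ "length_fraction",
    sim_frac < thresholds$min_similarity_fraction ~ "similarity_fraction",
    aln$n_mismatch > thresholds$max_mismatches ~ "mismatches",
    aln$n_gap_events > thresholds$max_indels ~ "indels",
    TRUE ~ NA_character_)
  aln %>% mutate(length_fraction = length_frac, similarity_fraction = sim_frac,
                 fail_reason = reason, pass = is.na(reason))
}

#' Map reads to the reference window
#'
#' Aligns each read in sense and antisense (reverse-complement) orientation,
#' applies the mapping filters to both, and keeps the better passing
#' alignment (higher score; sense wins ties). Antisense survivors are
#' reported with `status = "antisense"` and are excluded from end
#' classification downstream; reads with no passing alignment get
#' `status = "unmapped"` with the sense-strand failure reason.
#'
#' @param reads Tibble with `read_id`, `seq` (post [filter_reads()]).
#' @param window A `reference_window`.
#' @param scoring A [scoring_scheme()].
#' @param thresholds A [filter_thresholds()].
#' @return Tibble, one row per read: `read_id`, `read_len`, `status`
#'   (`mapped`/`antisense`/`unmapped`), `fail_reason`, and the alignment
#'   columns of [smith_waterman()] for the chosen orientation.
#' @export
map_reads <- function(reads, window, scoring = scoring_scheme(),
                      thresholds = filter_thresholds()) {
  wseq <- window$window_seq
  if (!nrow(reads)) {
    return(tibble(read_id = character(), seq = character(),
                  read_len = integer(), status = character(),
                  fail_reason = character()))
  }
  sense <- align_batch(reads$seq, wseq, scoring) %>%
    mutate(read_len = nchar(reads$seq)) %>% passes_filters(thresholds)
  anti <- align_batch(revcomp(reads$seq), wseq, scoring) %>%
    mutate(read_len = nchar(reads$seq)) %>% passes_filters(thresholds)
  use_sense <- sense$pass & (!anti$pass | sense$score >= anti$score)
  use_anti <- !use_sense & anti$pass
  out <- sense
  if (any(use_anti)) out[use_anti, ] <- anti[use_anti, ]
  out %>%
    mutate(read_id = reads$read_id, seq = reads$seq,
           status = dplyr::case_when(use_sense ~ "mapped",
                                     use_anti ~ "antisense",
                                     TRUE ~ "unmapped")) %>%
    select("read_id", "seq", "read_len", "status", "fail_reason", everything(),
           -"aligned", -"pass")
}

# vectorized smith_waterman over many reads against one window
align_batch <- function(seqs, wseq, scoring) {
  res <- lapply(toupper(seqs), function(s) {
    if (!nchar(s)) {
      list(score = 0, read_start = 0L, read_end = 0L, ref_start = 0L,
           ref_end = 0L, ops = "")
    } else {
      sw_align_cpp(s, wseq, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
    }
  })
  ops <- vapply(res, `[[`, character(1), "ops")
  op_chars <- strsplit(ops, "")
  rles <- lapply(op_chars, rle)
  score <- vapply(res, `[[`, numeric(1), "score")
  read_start <- vapply(res, function(r) as.integer(r$read_start), integer(1))
  read_end <- vapply(res, function(r) as.integer(r$read_end), integer(1))
  aligned <- score > 0
  tibble(
    score = score,
    read_start = read_start, read_end = read_end,
    window_start = vapply(res, function(r) as.integer(r$ref_start),
                          integer(1)),
    window_end = vapply(res, function(r) as.integer(r$ref_end), integer(1)),
    ops = ops,
    cigar = vapply(rles, function(r) {
      if (!length(r$values)) "" else paste0(r$lengths, r$values, collapse = "")
    }, character(1)),
    n_match = vapply(op_chars, function(v) sum(v == "="), integer(1)),
    n_mismatch = vapply(op_chars, function(v) sum(v == "X"), integer(1)),
    n_ins_bases = vapply(op_chars, function(v) sum(v == "I"), integer(1)),
    n_del_bases = vapply(op_chars, function(v) sum(v == "D"), integer(1)),
    n_gap_events = vapply(rles, function(r)
      sum(r$values %in% c("I", "D")), integer(1)),
    left_clip = ifelse(aligned, substr(seqs, 1L, read_start - 1L), ""),
    right_clip = ifelse(aligned, substr(seqs, read_end + 1L, nchar(seqs)),
                        seqs),
    aligned = aligned)
}

#' Write mapped reads as SAM against the window
#'
#' Minimal single-reference SAM export: soft-clips encoded as `S`, aligned
#' columns as `M`, with `NM` (edit distance) tags. Antisense reads are
#' written with flag 16 and reverse-complemented sequence; unmapped reads
#' with flag 4.
#'
#' @param mapped Output of [map_reads()] joined with read sequences
#'   (columns `read_id`, `seq` required).
#' @param window A `reference_window`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mapped, window, path) {
  stopifnot("seq" %in% names(mapped))
  ref_name <- window$locus$name
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, nchar(window$window_seq)))
  body <- purrr::pmap_chr(
    mapped[c("read_id", "seq", "status", "window_start", "ops",
             "left_clip", "right_clip", "n_mismatch", "n_ins_bases",
             "n_del_bases")],
    function(read_id, seq, status, window_start, ops, left_clip, right_clip,
             n_mismatch, n_ins_bases, n_del_bases) {
      if (status == "unmapped") {
        return(paste(read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, seq, "*",
                     sep = "\t"))
      }
      flag <- if (status == "antisense") 16L else 0L
      out_seq <- if (status == "antisense") revcomp(seq) else seq
      cig <- sam_cigar(ops, nchar(left_clip), nchar(right_clip))
      nm <- n_mismatch + n_ins_bases + n_del_bases
      paste(read_id, flag, ref_name, window_start, 255L, cig, "*", 0L, 0L,
            out_seq, "*", paste0("NM:i:", nm), sep = "\t")
    })
  writeLines(c(header, body), path)
  invisible(path)
}

sam_cigar <- function(ops, left_clip_len, right_clip_len) {
  ops_sam <- chartr("=X", "MM", ops)
  r <- rle(strsplit(ops_sam, "")[[1]])
  core <- paste0(r$lengths, r$values, collapse = "")
  paste0(if (left_clip_len > 0) paste0(left_clip_len, "S") else "",
         core,
         if (right_clip_len > 0) paste0(right_clip_len, "S") else "")
}
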