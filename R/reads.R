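#' Read small-RNA sequences from FASTQ or FASTA
#'
#' Streams all records of a (optionally gzipped) FASTQ or FASTA file into a
#' tibble, preserving file order. Quality strings are kept for FASTQ input
#' and `NA` for FASTA.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fastq"` or `"fasta"`.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_sequences <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    tryCatch({
      set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE)
      seqs <- unname(toupper(as.character(set)))
      qual <- unname(as.character(S4Vectors::mcols(set)$qualities))
      bad <- which(nchar(qual) != nchar(seqs))
      if (length(bad))
        stop("record ", bad[1], " ('", names(set)[bad[1]],
             "') has mismatched sequence/quality lengths")
      tibble(read_id = as.character(names(set)), seq = seqs, qual = qual)
    }, error = function(e) abort(
      paste0("failed to parse FASTQ '", path, "': ", conditionMessage(e)),
      class = "trfcat_parse_error"))
  } else {
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) abort(
        paste0("failed to parse FASTA '", path, "': ", conditionMessage(e)),
        class = "trfcat_parse_error"))
    tibble(read_id = as.character(names(set)),
           seq = unname(toupper(as.character(set))), qual = NA_character_)
  }
}

#' Trim a 3' sequencing adapter
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at most `floor(max_error_rate * overlap)` substitutions, provided the
#' overlap is at least `min_overlap`. Reads without a qualifying match are
#' returned untouched; a read equal to the adapter trims to length zero (to
#' be dropped by [filter_reads()]). Quality strings are trimmed in step.
#'
#' @param reads Tibble from [read_sequences()].
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum read/adapter overlap to trim (default 3).
#' @param max_error_rate Maximum substitution rate in the overlap (default 0.1).
#' @return The input tibble with `seq`/`qual` trimmed and an integer column
#'   `trimmed_bases` appended.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L,
                         max_error_rate = 0.1) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nchar(adapter) >= 1L)
  adapter <- toupper(adapter)
  a_chars <- strsplit(adapter, "")[[1]]
  new_len <- vapply(reads$seq, function(s) {
    trim_position(s, a_chars, min_overlap, max_error_rate)
  }, integer(1), USE.NAMES = FALSE)
  reads %>%
    mutate(trimmed_bases = nchar(.data$seq) - new_len,
           qual = ifelse(is.na(.data$qual), .data$qual,
                         substr(.data$qual, 1L, new_len)),
           seq = substr(.data$seq, 1L, new_len))
}

# returns length of read after trimming; prefers the longest (leftmost) match
trim_position <- function(seq, a_chars, min_overlap, max_error_rate) {
  n <- nchar(seq)
  if (n == 0L) return(0L)
  s_chars <- strsplit(seq, "")[[1]]
  alen <- length(a_chars)
  for (i in seq_len(n)) {
    L <- n - i + 1L
    if (L < min_overlap) break
    if (L > alen) next  # a suffix longer than the adapter cannot be its prefix
    mism <- sum(s_chars[i:n] != a_chars[seq_len(L)])
    if (mism <= floor(max_error_rate * L)) return(i - 1L)
  }
  n
}

#' Apply basic read-quality rules
#'
#' Drops reads containing any base outside `{A,C,G,T}` (ambiguous) and reads
#' shorter than `min_len` after trimming. Both the keep/drop decision and the
#' reason are recorded so a run log can account for every input read.
#'
#' @param reads Tibble with a `seq` column.
#' @param min_len Minimum retained length (default 15).
#' @return Input tibble with logical `keep` and character `drop_reason`
#'   (`NA` for kept reads) columns appended.
#' @export
filter_reads <- function(reads, min_len = 15L) {
  reads %>%
    mutate(
      drop_reason = dplyr::case_when(
        grepl("[^ACGT]", .data$seq) ~ "ambiguous",
        nchar(.data$seq) < min_len ~ "too_short",
        TRUE ~ NA_character_),
      keep = is.na(.data$drop_reason))
}

#' Keep only reads passing [filter_reads()]
#'
#' @param reads Tibble with `keep` column.
#' @return Filtered tibble without the bookkeeping columns.
#' @export
kept_reads <- function(reads) {
  reads %>% filter(.data$keep) %>% select(-"keep", -"drop_reason")
}

#' Write reads as a 4-line-per-record FASTQ file
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` (missing qualities are
#'   written as constant `"I"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- ifelse(is.na(reads$qual), strrep("I", nchar(reads$seq)), reads$qual)
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
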