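#' Read a reference FASTA into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning upper-case
#' plain character sequences named by the first whitespace-delimited token of
#' each FASTA header (the convention BED files refer to).
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_reference <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(
      paste0("failed to parse FASTA '", path, "': ", conditionMessage(e)),
      class = "trfcat_parse_error")
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Load a gene locus from a BED descriptor
#'
#' Reads a BED6 (or BED3/4) locus descriptor, converts the half-open 0-based
#' BED interval to 1-based inclusive coordinates, and validates it against the
#' reference. Internal gene coordinates are 1-based: position 1 is the first
#' encoded base, `gene_length` the last; a post-transcriptional CCA is never
#' part of the encoded gene for loci with `encodes_cca = FALSE`.
#'
#' @param reference_fasta Path to the reference FASTA.
#' @param locus_bed Path to a BED file whose first record describes the locus.
#' @param encodes_cca Does the gene encode its own 3' CCA? `FALSE` for the
#'   packaged tRNA-Cys model.
#' @return An object of class `gene_locus`: a list with `chrom_id`, `strand`,
#'   `start`, `end`, `gene_length`, `name`, `encodes_cca`.
#' @export
load_locus <- function(reference_fasta, locus_bed, encodes_cca = FALSE) {
  seqs <- read_reference(reference_fasta)
  bed <- utils::read.table(locus_bed, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(bed) < 1 || ncol(bed) < 3)
    abort("locus BED must have at least one record with 3 columns",
          class = "trfcat_malformed_locus")
  rec <- bed[1, ]
  chrom <- as.character(rec[[1]])
  start0 <- as.numeric(rec[[2]])
  end0 <- as.numeric(rec[[3]])
  name <- if (ncol(bed) >= 4) as.character(rec[[4]]) else "locus"
  strand <- if (ncol(bed) >= 6) as.character(rec[[6]]) else "+"
  if (!strand %in% c("+", "-")) strand <- "+"
  if (!chrom %in% names(seqs))
    abort(paste0("locus chrom '", chrom, "' not found in reference (has: ",
                 paste(names(seqs), collapse = ", "), ")"),
          class = "trfcat_reference_mismatch")
  if (is.na(start0) || is.na(end0) || end0 - start0 < 1)
    abort("locus interval must have positive length",
          class = "trfcat_malformed_locus")
  start <- as.integer(start0) + 1L
  end <- as.integer(end0)
  if (start < 1L || end > nchar(seqs[[chrom]]))
    abort("locus interval outside reference sequence bounds",
          class = "trfcat_malformed_locus")
  new_gene_locus(chrom_id = chrom, strand = strand, start = start, end = end,
                 name = name, encodes_cca = encodes_cca)
}

new_gene_locus <- function(chrom_id, strand, start, end, name = "locus",
                           encodes_cca = FALSE) {
  gene_length <- end - start + 1L
  stopifnot(gene_length >= 1L, strand %in% c("+", "-"))
  structure(
    list(chrom_id = chrom_id, strand = strand, start = as.integer(start),
         end = as.integer(end), gene_length = as.integer(gene_length),
         name = name, encodes_cca = isTRUE(encodes_cca)),
    class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s %s:%d-%d(%s) length %d nt, encodes_cca=%s\n",
              x$name, x$chrom_id, x$start, x$end, x$strand, x$gene_length,
              x$encodes_cca))
  invisible(x)
}

#' Build the gene-sense alignment window around a locus
#'
#' Extracts the gene plus up to `flank` nt of genomic context on each side
#' (truncated at the chromosome ends) and orients the window in gene sense
#' (reverse-complemented for minus-strand loci). The flanks are what make
#' genomically encoded precursor leaders/trailers detectable downstream.
#'
#' @param genome_seq Either the named character vector from
#'   [read_reference()] or a single character sequence for the locus' chrom.
#' @param locus A `gene_locus`.
#' @param flank Flank length in nt on each side (default 50).
#' @return An object of class `reference_window`: list with `window_seq`,
#'   `left_flank_len`, `right_flank_len`, `gene_offset` (0-based index of gene
#'   position 1 within `window_seq`), `gene_length`, `locus`.
#' @export
build_window <- function(genome_seq, locus, flank = 50L) {
  stopifnot(inherits(locus, "gene_locus"), flank >= 0)
  flank <- as.integer(flank)
  chrom_seq <- if (length(genome_seq) > 1L || !is.null(names(genome_seq))) {
    if (!locus$chrom_id %in% names(genome_seq))
      abort(paste0("chrom '", locus$chrom_id, "' not in supplied sequences"),
            class = "trfcat_reference_mismatch")
    genome_seq[[locus$chrom_id]]
  } else genome_seq
  chrom_seq <- toupper(chrom_seq)
  L <- nchar(chrom_seq)
  if (locus$end > L)
    abort("locus extends past end of sequence", class = "trfcat_malformed_locus")
  lo <- max(1L, locus$start - flank)
  hi <- min(L, locus$end + flank)
  seq <- substr(chrom_seq, lo, hi)
  up_len <- locus$start - lo      # genomic upstream flank actually captured
  down_len <- hi - locus$end
  if (locus$strand == "-") {
    seq <- revcomp(seq)
    left_flank <- down_len        # gene-sense left = genomic downstream
    right_flank <- up_len
  } else {
    left_flank <- up_len
    right_flank <- down_len
  }
  new_reference_window(seq, left_flank, right_flank, locus)
}

new_reference_window <- function(window_seq, left_flank_len, right_flank_len,
                                 locus) {
  stopifnot(nchar(window_seq) ==
              left_flank_len + locus$gene_length + right_flank_len)
  if (grepl("[^ACGT]", window_seq))
    abort("window sequence contains non-ACGT characters",
          class = "trfcat_reference_mismatch")
  structure(
    list(window_seq = window_seq,
         left_flank_len = as.integer(left_flank_len),
         right_flank_len = as.integer(right_flank_len),
         gene_offset = as.integer(left_flank_len),
         gene_length = locus$gene_length,
         locus = locus),
    class = "reference_window")
}

#' @export
print.reference_window <- function(x, ...) {
  cat(sprintf(
    "<reference_window> %d nt (%d flank | %d gene | %d flank), gene_offset=%d\n",
    nchar(x$window_seq), x$left_flank_len, x$gene_length, x$right_flank_len,
    x$gene_offset))
  invisible(x)
}

#' Window/gene coordinate conversions
#'
#' `gene_to_window()` maps a 1-based gene position to its 1-based window
#' position; `window_to_gene()` inverts it, returning `NA` for window
#' positions in the flanks.
#'
#' @param window A `reference_window`.
#' @param pos Integer vector of positions.
#' @return Integer vector of converted positions.
#' @export
gene_to_window <- function(window, pos) {
  stopifnot(all(pos >= 1 & pos <= window$gene_length))
  as.integer(window$gene_offset + pos)
}

#' @rdname gene_to_window
#' @export
window_to_gene <- function(window, pos) {
  g <- as.integer(pos - window$gene_offset)
  g[g < 1L | g > window$gene_length] <- NA_integer_
  g
}

#' Gene and flank sequences of a window
#'
#' @param window A `reference_window`.
#' @return Character scalar.
#' @export
gene_seq <- function(window) {
  substr(window$window_seq, window$gene_offset + 1L,
         window$gene_offset + window$gene_length)
}

#' @rdname gene_seq
#' @export
upstream_flank <- function(window) {
  if (window$left_flank_len == 0L) return("")
  substr(window$window_seq, 1L, window$left_flank_len)
}

#' @rdname gene_seq
#' @export
downstream_flank <- function(window) {
  if (window$right_flank_len == 0L) return("")
  substr(window$window_seq, window$gene_offset + window$gene_length + 1L,
         nchar(window$window_seq))
}

#' Export / re-import a window as FASTA
#'
#' The header records flank lengths so that `read_window_fasta()` restores an
#' identical `reference_window`; `build_window()` on the exported sequence
#' with a locus spanning the gene interval is idempotent.
#'
#' @param window A `reference_window`.
#' @param path Output/input FASTA path.
#' @return `write_window_fasta()` returns `path` invisibly;
#'   `read_window_fasta()` returns a `reference_window`.
#' @export
write_window_fasta <- function(window, path) {
  header <- sprintf(">%s left_flank=%d right_flank=%d gene_length=%d strand=%s",
                    window$locus$name, window$left_flank_len,
                    window$right_flank_len, window$gene_length,
                    window$locus$strand)
  writeLines(c(header, window$window_seq), path)
  invisible(path)
}

#' @rdname write_window_fasta
#' @export
read_window_fasta <- function(path) {
  lines <- readLines(path)
  header <- lines[[1]]
  seq <- paste(lines[-1], collapse = "")
  get_field <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, "=[-+0-9A-Za-z]+"), header))
    if (!length(m)) abort("window FASTA header missing metadata",
                          class = "trfcat_parse_error")
    sub(paste0(key, "="), "", m)
  }
  lf <- as.integer(get_field("left_flank"))
  rf <- as.integer(get_field("right_flank"))
  gl <- as.integer(get_field("gene_length"))
  name <- sub("^>", "", strsplit(header, " ")[[1]][1])
  locus <- new_gene_locus(chrom_id = name, strand = get_field("strand"),
                          start = lf + 1L, end = lf + gl, name = name)
  new_reference_window(toupper(seq), lf, rf, locus)
}

# fast in-package reverse complement (tests cross-check against Biostrings)
revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", stringi::stri_reverse(s))
}
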