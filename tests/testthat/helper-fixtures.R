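# Programmatic fixtures: a tiny deterministic reference + locus pair, and
# FASTA/FASTQ writers into tempfiles.

fixture_chrom <- function(len = 500, seed = 101) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

write_fixture_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(purrr::imap(as.list(seqs), function(s, n) c(paste0(">", n), s)))
  writeLines(lines, path)
  path
}

write_fixture_bed <- function(chrom, start0, end0, name = "trnD-Cys",
                              strand = "+", path = tempfile(fileext = ".bed")) {
  writeLines(paste(chrom, start0, end0, name, ".", strand, sep = "\t"), path)
  path
}

write_fixture_fastq <- function(records, path = tempfile(fileext = ".fastq")) {
  # records: list of c(id, seq, qual)
  lines <- unlist(purrr::map(records, function(r) {
    c(paste0("@", r[[1]]), r[[2]], "+", r[[3]])
  }))
  writeLines(lines, path)
  path
}

# default test window: deterministic 500 nt chrom, gene at 1-based 100..170
fixture_window <- function(strand = "+", flank = 50) {
  chrom <- fixture_chrom()
  fa <- write_fixture_fasta(c(chr1 = chrom))
  bed <- write_fixture_bed("chr1", 99, 170, strand = strand)
  locus <- load_locus(fa, bed)
  build_window(read_reference(fa), locus, flank = flank)
}
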