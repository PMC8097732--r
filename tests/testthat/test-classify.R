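# helper: run one constructed read through map -> annotate -> classify
classify_one_read <- function(seq, w) {
  m <- map_reads(tibble::tibble(read_id = "r", seq = seq), w)
  classify_reads(annotate_ends(m, w), gene_length = w$gene_length)
}

test_that("end annotation separates genomic trailers from added tails", {
  w <- fixture_window()
  g <- gene_seq(w)
  down <- downstream_flank(w)
  up <- upstream_flank(w)

  # soft-clipped CCA that does not match the flank -> pure tail
  if (substr(down, 1, 1) != "C") {
    ann <- annotate_ends(map_reads(tibble::tibble(read_id = "r",
                                                  seq = paste0(g, "CCA")), w), w)
    expect_equal(ann$three_genomic_len, 0L)
    expect_equal(ann$tail, "CCA")
  }

  # six genomically encoded downstream bases -> precursor trailer, empty tail
  ann2 <- annotate_ends(map_reads(tibble::tibble(
    read_id = "r", seq = paste0(g, substr(down, 1, 6))), w), w)
  expect_equal(ann2$three_genomic_len, 6L)
  expect_equal(ann2$tail, "")

  # genomic leader on the 5' side
  ann3 <- annotate_ends(map_reads(tibble::tibble(
    read_id = "r", seq = paste0(substr(up, 43, 50), g)), w), w)
  expect_equal(ann3$five_genomic_len, 8L)
  expect_equal(ann3$gene_start, 1L)
})

test_that("clip-versus-flank extension matches brute-force prefix matching", {
  # engineered window whose downstream flank starts "CAT...": a clipped "CA"
  # is genomic (2 bases), a clipped "CCA" stops at the second base
  gene <- withr::with_seed(21, paste(sample(c("A", "C", "G", "T"), 71, TRUE),
                                     collapse = ""))
  up <- withr::with_seed(22, paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                                   collapse = ""))
  down <- paste0("CAT", withr::with_seed(23, paste(
    sample(c("G", "T"), 47, TRUE), collapse = "")))
  chrom <- paste0(up, gene, down)
  fa <- write_fixture_fasta(c(chr = chrom))
  locus <- load_locus(fa, write_fixture_bed("chr", 50, 121))
  w <- build_window(read_reference(fa), locus, flank = 50)

  for (extra in c("CA", "CCA", "CAT", "C", "CATAA")) {
    ann <- annotate_ends(map_reads(tibble::tibble(
      read_id = "r", seq = paste0(gene, extra)), w), w)
    expected <- oracle_prefix_match(extra, down)
    # aligner may absorb matching flank bases into the alignment itself;
    # genomic length must equal the brute-force contiguous match either way
    expect_equal(ann$three_genomic_len, expected, info = extra)
    expect_equal(ann$tail, substr(extra, expected + 1, nchar(extra)),
                 info = extra)
  }
})

test_that("category rules assign the nine maturation/fragmentation labels", {
  w <- fixture_window()
  g <- gene_seq(w)
  up <- upstream_flank(w)
  down <- downstream_flank(w)
  cases <- list(
    list(seq = paste0(g, "CCA"), cat = "III"),               # mature
    list(seq = g, cat = "II"),                                # immature
    list(seq = paste0(g, "CC"), cat = "IV"),                  # CC-ended
    list(seq = paste0(substr(g, 10, 71), "CCA"), cat = "V"),  # 3'-tRF CCA
    list(seq = paste0(substr(g, 10, 71), "CC"), cat = "VI"),  # 3'-tRF CC
    list(seq = substr(g, 1, 55), cat = "VII"),                # 5'-tRF n=16
    list(seq = substr(g, 5, 68), cat = "VII"),                # internal
    list(seq = paste0(g, "CCACCA"), cat = "VIII"),            # double CCA
    list(seq = paste0(substr(g, 12, 71), "CCAAAAA"), cat = "IX"),
    list(seq = paste0(substr(up, 48, 50), g), cat = "I"),     # genomic leader
    list(seq = paste0(g, substr(down, 1, 4)), cat = "I"))     # genomic trailer
  for (cs in cases) {
    out <- classify_one_read(cs$seq, w)
    expect_equal(as.character(out$category), cs$cat, info = cs$seq)
  }
  # 5'-tRF n bookkeeping: 71 - 55 = 16
  out <- classify_one_read(substr(g, 1, 55), w)
  expect_equal(out$trf_n, 16L)
  expect_match(out$flags, "five_trf")
  out2 <- classify_one_read(substr(g, 5, 68), w)
  expect_match(out2$flags, "internal")
})

test_that("precedence: genomic extension dominates every other label", {
  w <- fixture_window()
  g <- gene_seq(w)
  down <- downstream_flank(w)
  up <- upstream_flank(w)
  # every template ending at the encoded 3' end gains a genomic trailer -> I
  templates <- c(g, paste0(g, "CCA"), paste0(g, "CC"),
                 paste0(substr(g, 10, 71), "CCA"),
                 paste0(g, "CCACCA"))
  for (tpl in templates) {
    if (endsWith(tpl, substr(g, 69, 71))) {
      aug <- paste0(tpl, substr(down, 1, 3))
      out <- classify_one_read(aug, w)
      expect_equal(as.character(out$category), "I", info = tpl)
    }
    # templates starting at gene position 1 gain a genomic leader -> I
    if (startsWith(tpl, substr(g, 1, 3))) {
      aug5 <- paste0(substr(up, 47, 50), tpl)
      out5 <- classify_one_read(aug5, w)
      expect_equal(as.character(out5$category), "I", info = tpl)
    }
  }
})

test_that("edge cases: tail-less 3' fragments and odd tails are flagged", {
  w <- fixture_window()
  g <- gene_seq(w)
  # 3' fragment ending exactly at 71 with no tail -> VII with subtype flag
  out <- classify_one_read(substr(g, 10, 71), w)
  expect_equal(as.character(out$category), "VII")
  expect_match(out$flags, "three_trf_no_tail")
  expect_equal(out$trf_n, 0L)
  # full-length single-C tail -> VIII flagged
  out2 <- classify_one_read(paste0(g, "C"), w)
  if (substr(downstream_flank(w), 1, 1) != "C") {
    expect_equal(as.character(out2$category), "VIII")
    expect_match(out2$flags, "single_c_tail")
  }
})

test_that("classification is deterministic and total over mapped reads", {
  w <- fixture_window()
  mx <- category_mixture(n_reads = 400, error_rate = 0.01)
  reads <- simulate_sample(w, mx, seed = 55)
  run <- function() classify_sample(reads[c("read_id", "seq", "qual")], w)
  a <- run()
  b <- run()
  expect_identical(as.character(a$category), as.character(b$category))
  mapped <- a %>% dplyr::filter(status == "mapped")
  expect_true(all(!is.na(mapped$category)))
  expect_true(all(as.character(mapped$category) %in% trf_categories()))
})

test_that("truth recovery is exact on an unambiguous error-free corpus", {
  w <- generate_reference(91)
  mx <- category_mixture(n_reads = 1000, error_rate = 0)
  reads <- simulate_sample(w, mx, seed = 92)
  cl <- classify_sample(reads[c("read_id", "seq", "qual")], w)
  joined <- dplyr::left_join(cl, reads[c("read_id", "true_category")],
                             by = "read_id")
  classified <- joined %>% dplyr::filter(!is.na(category))
  expect_equal(mean(as.character(classified$category) ==
                      classified$true_category), 1)
  # the only reads not reaching the classifier are long-tailed fragments
  # rejected by the length-fraction mapping filter
  lost <- joined %>% dplyr::filter(is.na(category))
  if (nrow(lost)) {
    expect_true(all(lost$fail_reason == "length_fraction"))
    expect_true(all(lost$true_category %in% c("VIII", "IX")))
  }
})

test_that("at 1% error mature reads degrade along the expected routes", {
  w <- generate_reference(7)
  mx <- category_mixture(proportions = c(III = 1), n_reads = 1500,
                         error_rate = 0.01)
  reads <- simulate_sample(w, mx, seed = 70)
  cl <- classify_sample(reads[c("read_id", "seq", "qual")], w)
  classified <- cl %>% dplyr::filter(!is.na(category))
  cats <- as.character(classified$category)
  expect_gt(mean(cats == "III"), 0.9)
  # substitutions can only reroute via: start trimming (V), end trimming
  # (VII), a corrupted tail (VIII), or a tail base coinciding with the
  # first flank base (single-base apparent trailer -> I)
  expect_true(all(cats %in% c("III", "V", "VII", "VIII", "I")))
  apparent_I <- classified %>% dplyr::filter(as.character(category) == "I")
  if (nrow(apparent_I)) {
    expect_true(all(apparent_I$three_genomic_len == 1L &
                      apparent_I$five_genomic_len == 0L))
  }
})
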