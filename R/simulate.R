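#' Dormant-spore-like category proportions
#'
#' The published dormant-spore (T0) category percentages, with the pooled
#' V+VI and VIII+IX figures split as configured here (V/VI evenly; VIII/IX
#' 7.0/5.27), normalised to sum to 1. These are the simulator's default
#' mixture for a realistic dormant-spore sample.
#'
#' @return Named numeric vector over categories I..IX summing to 1.
#' @export
dormant_proportions <- function() {
  p <- c(I = 0.0101, II = 0.0034, III = 0.2285, IV = 0.0947,
         V = 0.11595, VI = 0.11595, VII = 0.3046, VIII = 0.07, IX = 0.0527)
  p / sum(p)
}

#' Outgrowth-like category proportions
#'
#' Illustrative default mixture for outgrowth timepoints: precursor-heavy
#' (transcription resumes), with depleted CC-ended species and 3'-tRFs.
#'
#' @return Named numeric vector over categories I..IX summing to 1.
#' @export
outgrowth_proportions <- function() {
  p <- c(I = 0.50, II = 0.012, III = 0.24, IV = 0.02, V = 0.03, VI = 0.008,
         VII = 0.13, VIII = 0.045, IX = 0.015)
  p / sum(p)
}

#' Default incorrect-tail repertoire
#'
#' Tails observed on incorrectly tailed species: CCA plus extra C/CA, a
#' second CCA terminus, CCA-primed poly(A) tails, and bare C/CA
#' intermediates. `CCApolyA` draws `CCA` followed by 1-6 A's at simulation
#' time. None of `""`, `"CC"`, `"CCA"` are allowed (those define categories
#' II-VI).
#'
#' @return Character vector of tail templates.
#' @export
default_tail_repertoire <- function() {
  c("CCAC", "CCACA", "CCACCA", "CCApolyA", "C", "CA")
}

#' Define a read mixture for simulation
#'
#' @param proportions Named numeric over categories I..IX (must sum to 1
#'   within 1e-9; zero entries allowed; missing categories are zero).
#' @param n_reads Number of reads to draw.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param leader_p,trailer_p Geometric(p) success parameters for precursor
#'   leader/trailer lengths (length = 1 + Geometric(p), truncated at the
#'   flank).
#' @param frag_min_len Minimum fragment length (matches the read filter so
#'   simulated fragments survive preprocessing).
#' @param tail_repertoire,tail_weights Incorrect-tail templates and weights.
#' @return A `trf_mixture` list.
#' @export
category_mixture <- function(proportions = dormant_proportions(),
                             n_reads = 1000L, error_rate = 0,
                             leader_p = 0.3, trailer_p = 0.3,
                             frag_min_len = 15L,
                             tail_repertoire = default_tail_repertoire(),
                             tail_weights = NULL) {
  cats <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")
  p <- setNames(rep(0, length(cats)), cats)
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% cats))
    abort("proportions must be named with categories I..IX",
          class = "trfcat_config_error")
  p[names(proportions)] <- proportions
  if (abs(sum(p) - 1) > 1e-9)
    abort("mixture proportions must sum to 1", class = "trfcat_config_error")
  if (error_rate < 0 || error_rate >= 1)
    abort("error_rate must be in [0, 1)", class = "trfcat_config_error")
  bad <- intersect(tail_repertoire, c("", "CC", "CCA"))
  if (length(bad))
    abort("tail repertoire may not contain '', 'CC' or 'CCA'",
          class = "trfcat_config_error")
  if (is.null(tail_weights)) tail_weights <- rep(1, length(tail_repertoire))
  stopifnot(length(tail_weights) == length(tail_repertoire))
  structure(list(proportions = p, n_reads = as.integer(n_reads),
                 error_rate = error_rate, leader_p = leader_p,
                 trailer_p = trailer_p, frag_min_len = as.integer(frag_min_len),
                 tail_repertoire = tail_repertoire,
                 tail_weights = tail_weights),
            class = "trf_mixture")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference window
#'
#' Builds a random gene of `gene_length` nt inside random flanks and returns
#' the gene-sense window (via [build_window()], so the reference plumbing is
#' exercised too). The first 10 downstream-flank bases are drawn from
#' `{G, T}` only: the downstream flank then cannot begin with `C`, contains
#' no `CCA` among its first bases, and cannot absorb any C/A-alphabet
#' post-transcriptional tail, which keeps tail-versus-trailer disambiguation
#' exact for truth-recovery tests.
#'
#' @param seed Integer seed (mandatory; the generator is deterministic).
#' @param gene_length Gene length in nt (default 71).
#' @param flank Flank length on each side (>= 50; default 60).
#' @param fasta Optional path: write the synthetic chromosome as FASTA and a
#'   matching BED locus next to it.
#' @return A `reference_window`. When `fasta` is given, paths to the FASTA
#'   and BED files are attached as attributes `fasta` and `bed`.
#' @export
generate_reference <- function(seed, gene_length = 71L, flank = 60L,
                               fasta = NULL) {
  stopifnot(flank >= 50L)
  with_seed_restore(seed, {
    up <- random_dna(flank)
    gene <- random_dna(gene_length)
    down <- paste0(random_dna(10L, alphabet = c("G", "T")),
                   random_dna(flank - 10L))
    chrom <- paste0(up, gene, down)
    locus <- new_gene_locus(chrom_id = "synthetic_chrom", strand = "+",
                            start = flank + 1L, end = flank + gene_length,
                            name = "synthetic_trna")
    window <- build_window(setNames(chrom, "synthetic_chrom"), locus,
                           flank = flank)
    if (!is.null(fasta)) {
      writeLines(c(">synthetic_chrom", chrom), fasta)
      bed <- sub("\\.fa(sta)?$", ".bed", fasta)
      if (identical(bed, fasta)) bed <- paste0(fasta, ".bed")
      writeLines(paste("synthetic_chrom", flank, flank + gene_length,
                       "synthetic_trna", ".", "+", sep = "\t"), bed)
      attr(window, "fasta") <- fasta
      attr(window, "bed") <- bed
    }
    window
  })
}

# run code under a seed without disturbing the caller's RNG state
with_seed_restore <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

trunc_geom <- function(n, p, max_len) {
  pmin(1L + rgeom(n, p), max_len)
}

# uniform draw from a:b that is safe when a == b (sample() would otherwise
# treat a lone scalar as 1:a)
sample_range <- function(a, b) {
  a + sample.int(b - a + 1L, 1L) - 1L
}

draw_tail <- function(mixture) {
  t <- sample(mixture$tail_repertoire, 1L, prob = mixture$tail_weights)
  if (t == "CCApolyA") t <- paste0("CCA", strrep("A", sample_range(1L, 6L)))
  t
}

#' Simulate one labelled sample
#'
#' Draws `n_reads` categories from the mixture, constructs each read from
#' the window sequence according to its category's definition, applies iid
#' substitution errors, and returns reads together with their ground-truth
#' records. Construction rules: I = full gene plus genomic leader and/or
#' trailer taken from the flanks; II = gene 1..L; III/IV = gene + CCA/CC;
#' V/VI = gene s..L + CCA/CC (s uniform in 2..(L - frag_min_len)); VII =
#' 5'-tRF gene 1..e (e uniform in frag_min_len..L-1) or internal fragment
#' s..e of length >= frag_min_len; VIII/IX = full-length/3'-tRF plus an
#' incorrect tail from the repertoire.
#'
#' @param window A `reference_window` (typically [generate_reference()]).
#' @param mixture A [category_mixture()].
#' @param seed Integer seed (mandatory).
#' @param sample_id Sample label used in read ids.
#' @return Tibble with `read_id`, `seq`, `qual` and truth columns
#'   `true_category`, `true_gene_start`, `true_gene_end`, `true_tail`,
#'   `leader_len`, `trailer_len`, `n_errors`.
#' @export
simulate_sample <- function(window, mixture, seed, sample_id = "sample") {
  stopifnot(inherits(mixture, "trf_mixture"))
  L <- window$gene_length
  smin <- mixture$frag_min_len
  if (smin >= L)
    abort("frag_min_len must be smaller than the gene length",
          class = "trfcat_config_error")
  gene <- gene_seq(window)
  up <- upstream_flank(window)
  down <- downstream_flank(window)
  with_seed_restore(seed, {
    n <- mixture$n_reads
    if (n == 0L) {
      return(tibble(read_id = character(), seq = character(),
                    qual = character(), true_category = character(),
                    true_gene_start = integer(), true_gene_end = integer(),
                    true_tail = character(), leader_len = integer(),
                    trailer_len = integer(), n_errors = integer()))
    }
    cats <- sample(names(mixture$proportions), n, replace = TRUE,
                   prob = mixture$proportions)
    rows <- purrr::map(seq_len(n), function(i) {
      cat_i <- cats[[i]]
      leader <- 0L
      trailer <- 0L
      gs <- 1L
      ge <- L
      tail <- ""
      if (cat_i == "I") {
        side <- runif(1)
        if (side < 0.4) {
          leader <- trunc_geom(1L, mixture$leader_p, nchar(up))
        } else if (side < 0.8) {
          trailer <- trunc_geom(1L, mixture$trailer_p, nchar(down))
        } else {
          leader <- trunc_geom(1L, mixture$leader_p, nchar(up))
          trailer <- trunc_geom(1L, mixture$trailer_p, nchar(down))
        }
      } else if (cat_i == "III") {
        tail <- "CCA"
      } else if (cat_i == "IV") {
        tail <- "CC"
      } else if (cat_i %in% c("V", "VI")) {
        gs <- sample_range(2L, L - smin)
        tail <- if (cat_i == "V") "CCA" else "CC"
      } else if (cat_i == "VII") {
        if (runif(1) < 0.5) {           # 5'-tRF
          ge <- sample_range(smin, L - 1L)
        } else {                        # internal fragment
          gs <- sample_range(2L, L - smin)
          ge <- sample_range(gs + smin - 1L, L - 1L)
        }
      } else if (cat_i == "VIII") {
        tail <- draw_tail(mixture)
      } else if (cat_i == "IX") {
        gs <- sample_range(2L, L - smin)
        tail <- draw_tail(mixture)
      }
      body <- substr(gene, gs, ge)
      seq <- paste0(
        if (leader > 0L) substr(up, nchar(up) - leader + 1L, nchar(up)) else "",
        body,
        if (trailer > 0L) substr(down, 1L, trailer) else "",
        tail)
      list(cat = cat_i, gs = gs, ge = ge, tail = tail, leader = leader,
           trailer = trailer, seq = seq)
    })
    seqs <- vapply(rows, `[[`, character(1), "seq")
    err <- apply_substitutions(seqs, mixture$error_rate)
    tibble(
      read_id = sprintf("%s_r%05d_%s", sample_id, seq_len(n), cats),
      seq = err$seq,
      qual = strrep("I", nchar(err$seq)),
      true_category = cats,
      true_gene_start = vapply(rows, function(r) as.integer(r$gs), integer(1)),
      true_gene_end = vapply(rows, function(r) as.integer(r$ge), integer(1)),
      true_tail = vapply(rows, `[[`, character(1), "tail"),
      leader_len = vapply(rows, function(r) as.integer(r$leader), integer(1)),
      trailer_len = vapply(rows, function(r) as.integer(r$trailer), integer(1)),
      n_errors = err$n_errors)
  })
}

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate == 0) {
    return(list(seq = seqs, n_errors = rep(0L, length(seqs))))
  }
  bases <- c("A", "C", "G", "T")
  n_errors <- integer(length(seqs))
  out <- vapply(seq_along(seqs), function(i) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    hit <- which(runif(length(ch)) < error_rate)
    for (k in hit) {
      ch[k] <- sample(setdiff(bases, ch[k]), 1L)
    }
    n_errors[i] <<- length(hit)
    paste(ch, collapse = "")
  }, character(1))
  list(seq = out, n_errors = n_errors)
}

#' Default 14-sample study design
#'
#' Two dormant-spore replicates (T0) plus two conditions x three outgrowth
#' timepoints x two replicates, with per-sample read depths taken from the
#' published per-run mapped-read accounting ([study_mapped_reads()]), and
#' the dormant/outgrowth default mixtures.
#'
#' @param n_reads Optional integer vector (length 14) overriding per-sample
#'   read counts.
#' @return Tibble `sample_id`, `condition`, `time_min`, `replicate`,
#'   `n_reads`, `mixture` (`"dormant"`/`"outgrowth"`).
#' @export
study_design <- function(n_reads = NULL) {
  tbl <- study_mapped_reads() %>%
    mutate(sample_id = sprintf("%s_T%d_rep%d", .data$condition,
                               .data$time_min, .data$replicate),
           mixture = ifelse(.data$condition == "dormant", "dormant",
                            "outgrowth"),
           n_reads = .data$mapped_reads) %>%
    select("sample_id", "condition", "time_min", "replicate", "n_reads",
           "mixture")
  if (!is.null(n_reads)) {
    stopifnot(length(n_reads) == nrow(tbl))
    tbl$n_reads <- as.integer(n_reads)
  }
  tbl
}

#' Simulate a full multi-sample study
#'
#' Emits one FASTQ + truth TSV per design row plus a sample sheet,
#' reproducing the shape of a two-condition outgrowth time course with
#' duplicate sequencing. Deterministic given `seed` (per-sample seeds are
#' derived as `seed + row index`).
#'
#' @param out_dir Output directory.
#' @param seed Integer base seed (mandatory).
#' @param design Study design tibble, see [study_design()].
#' @param window A `reference_window`; default regenerates the packaged
#'   synthetic reference from `seed`.
#' @param mixtures Named list mapping the design's `mixture` names to
#'   [category_mixture()] *templates* (their `n_reads` is overridden per
#'   sample).
#' @param error_rate Per-base substitution rate applied to every sample.
#' @return Sample sheet tibble with `fastq` and `truth` paths appended;
#'   the window used is attached as attribute `window`.
#' @export
simulate_study <- function(out_dir, seed, design = study_design(),
                           window = NULL,
                           mixtures = list(
                             dormant = category_mixture(dormant_proportions()),
                             outgrowth = category_mixture(outgrowth_proportions())),
                           error_rate = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(window))
    window <- generate_reference(seed, fasta = file.path(out_dir, "reference.fa"))
  missing <- setdiff(unique(design$mixture), names(mixtures))
  if (length(missing))
    abort(paste0("no mixture defined for: ", paste(missing, collapse = ", ")),
          class = "trfcat_config_error")
  sheet <- design %>%
    mutate(fastq = file.path(out_dir, paste0(.data$sample_id, ".fastq")),
           truth = file.path(out_dir, paste0(.data$sample_id, ".truth.tsv")))
  for (i in seq_len(nrow(sheet))) {
    mx <- mixtures[[sheet$mixture[i]]]
    mx$n_reads <- as.integer(sheet$n_reads[i])
    mx$error_rate <- error_rate
    reads <- simulate_sample(window, mx, seed = seed + i,
                             sample_id = sheet$sample_id[i])
    write_fastq(reads, sheet$fastq[i])
    readr::write_tsv(reads %>% select(-"seq", -"qual"), sheet$truth[i])
  }
  readr::write_tsv(sheet %>% select(-"mixture"),
                   file.path(out_dir, "sample_sheet.tsv"))
  attr(sheet, "window") <- window
  sheet
}
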