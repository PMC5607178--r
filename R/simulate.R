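#' Simulation settings for divergent RNA-seq reads
#'
#' The simulation emulates the read sets used to benchmark alignment-based
#' read assignment: uniform coverage over every gene's longest transcript,
#' with a single per-base substitution rate standing in for the combined
#' effect of sequencing error, polymorphism and inter-species divergence.
#'
#' @param read_length Read length in bases. The benchmark length classes are
#'   100, 150, 200 and 350.
#' @param divergence Per-base substitution probability in `[0, 1]`; the
#'   benchmark levels are 0, 0.05, 0.15 and 0.30.
#' @param coverage Target per-gene coverage depth (default 10).
#' @param seed Integer seed; every gene derives its own reproducible
#'   sub-stream from this seed and its `gene_id`, so gene sets can be
#'   simulated incrementally.
#' @param tiling `"even"` (deterministic, evenly spaced starts; default) or
#'   `"random"` (uniform random starts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(read_length = 100L, divergence = 0, coverage = 10,
                       seed = 1L, tiling = c("even", "random")) {
  tiling <- match.arg(tiling)
  stopifnot(read_length >= 1, divergence >= 0, divergence <= 1, coverage > 0)
  structure(
    list(read_length = as.integer(read_length), divergence = divergence,
         coverage = coverage, seed = as.integer(seed), tiling = tiling),
    class = "sim_config"
  )
}

# Stable 31-bit string hash so each gene gets its own RNG sub-stream that does
# not depend on catalog order or on R's internal string hashing.
gene_stream_seed <- function(seed, gene_id) {
  h <- 0
  for (c in utf8ToInt(gene_id)) h <- (h * 31 + c) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483629)
}

#' Tile reads over one transcript at fixed coverage
#'
#' Emits `n = ceiling(coverage * L / r_eff)` reads with `r_eff =
#' min(read_length, L)`; full-length reads have evenly spaced starts spanning
#' `[0, L - r_eff]` (or uniform random starts under `tiling = "random"`).
#' Transcripts shorter than the read length yield whole-transcript copies.
#' All reads carry constant Phred 40 qualities so that quality filtering is a
#' no-op on simulated data and assignment behaviour is measured in isolation.
#'
#' @param gene_id,sequence The source transcript.
#' @param cfg A [sim_config()].
#' @return Tibble of reads with 0-based `start` and `origin_gene_id`.
#' @export
tile_reads <- function(gene_id, sequence, cfg) {
  L <- nchar(sequence)
  stopifnot(L >= 1)
  r_eff <- min(cfg$read_length, L)
  n <- ceiling(cfg$coverage * L / r_eff)
  set.seed(gene_stream_seed(cfg$seed, gene_id))
  if (cfg$tiling == "even") {
    starts <- if (n == 1) 0L else as.integer(round(seq(0, L - r_eff, length.out = n)))
  } else {
    starts <- sample.int(L - r_eff + 1L, n, replace = TRUE) - 1L
  }
  seqs <- substring(sequence, starts + 1L, starts + r_eff)
  if (cfg$divergence > 0) seqs <- inject_divergence(seqs, cfg$divergence)
  tibble(
    read_id = sprintf("%s_r%04d", gene_id, seq_len(n)),
    sequence = seqs,
    quality = strrep("I", r_eff),  # Phred 40
    mate = "single",
    origin_gene_id = gene_id,
    start = starts,
    strand = "+"
  )
}

#' Substitute bases at a fixed per-base rate
#'
#' Each position is independently replaced with probability `divergence`,
#' the replacement drawn uniformly from the three other bases; length is
#' preserved and no indels are introduced. `N` positions are left untouched.
#' Draws come from the current RNG state.
#'
#' @param sequences Character vector of DNA sequences.
#' @param divergence Substitution probability in `[0, 1]`.
#' @return Character vector of mutated sequences.
#' @export
inject_divergence <- function(sequences, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  if (divergence == 0) return(sequences)
  bases <- c("A", "C", "G", "T")
  vapply(sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < divergence & ch %in% bases)
    if (length(hit) > 0) {
      # uniform over the three non-identical bases via a cyclic offset
      off <- sample.int(3L, length(hit), replace = TRUE)
      ch[hit] <- bases[(match(ch[hit], bases) - 1L + off) %% 4L + 1L]
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a full read dataset from a gene catalog
#'
#' Runs [tile_reads()] for every catalog gene under per-gene seeded RNG
#' sub-streams, producing a read table and its truth table (read to origin
#' gene). Deterministic for a fixed seed: the same catalog and configuration
#' always produce byte-identical FASTQ output.
#'
#' @param catalog Gene catalog from [build_gene_catalog()] or
#'   [synthesize_catalog()].
#' @param cfg A [sim_config()].
#' @param fastq_path,truth_path Optional output paths; when given, the reads
#'   are written as Phred+33 FASTQ and the truth table as TSV.
#' @return A list with `reads` (read tibble) and `truth` (tibble `read_id`,
#'   `origin_gene_id`, `start`, `strand`), invisibly when files are written.
#' @export
simulate_dataset <- function(catalog, cfg, fastq_path = NULL, truth_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ord <- order(catalog$gene_id)
  reads <- purrr::map(ord, function(i) {
    tile_reads(catalog$gene_id[i], catalog$sequence[i], cfg)
  }) %>% purrr::list_rbind()
  truth <- dplyr::select(reads, "read_id", "origin_gene_id", "start", "strand")
  out <- list(reads = dplyr::select(reads, -"start", -"strand"), truth = truth)
  if (!is.null(fastq_path)) write_reads_fastq(out$reads, fastq_path)
  if (!is.null(truth_path)) readr::write_tsv(truth, truth_path, progress = FALSE)
  if (is.null(fastq_path) && is.null(truth_path)) out else invisible(out)
}

#' Synthesize a gene catalog of non-homologous transcripts
#'
#' Generates random transcripts constructed so that no two genes share any
#' `word_size`-mer on either strand: under such a catalog every read seeds
#' only on its own gene, which makes the zero-divergence ideal case exactly
#' attainable. Sequences are built as random walks in the order-`word_size`
#' De Bruijn graph that avoid every word (or its reverse complement) already
#' used by another gene — plain rejection sampling cannot reach the word
#' densities a realistic catalog occupies. Optionally plants paralog pairs
#' (a copy of an existing gene mutated at `paralog_divergence`) to study
#' multigene score ties.
#'
#' @param n_genes Number of (non-paralog) genes.
#' @param gene_length Transcript length in bases, or a vector of lengths
#'   recycled across genes.
#' @param n_paralog_pairs Number of planted paralog pairs (default 0). Each
#'   pair adds one extra gene whose sequence is a mutated copy of one of the
#'   base genes; paralogs are exempt from the k-mer screen against their
#'   template.
#' @param paralog_divergence Substitution rate used to create paralog copies.
#' @param word_size Seed word size used for the homology screen (default 9).
#' @param seed Integer seed.
#' @param species_tag Label stored in the catalog's `species_tag` column.
#' @return A gene catalog tibble (`gene_id`, `transcript_id`, `sequence`,
#'   `length`, `species_tag`).
#' @export
synthesize_catalog <- function(n_genes, gene_length = 1000L,
                               n_paralog_pairs = 0L, paralog_divergence = 0.05,
                               word_size = 9L, seed = 1L,
                               species_tag = "synthetic") {
  set.seed(seed)
  k <- as.integer(word_size)
  lens <- rep_len(as.integer(gene_length), n_genes)
  if (any(lens < k)) abort("gene_length must be at least word_size")
  n_words <- 4L^k
  if (sum(lens) * 2 > 0.8 * n_words) {
    abort("catalog occupies too much of the word space to stay word-disjoint")
  }
  bases <- c("A", "C", "G", "T")
  # reverse-complement code for every k-mer code, vectorised once
  codes <- 0:(n_words - 1L)
  rc_table <- integer(n_words)
  tmp <- codes
  for (pos in seq_len(k)) {
    rc_table <- rc_table * 4L + (3L - tmp %% 4L)
    tmp <- tmp %/% 4L
  }
  rc_table <- rc_table + 1L
  used <- logical(n_words)
  suffix_mod <- n_words %/% 4L  # 4^(k-1)

  walk_sequence <- function(len) {
    for (attempt in 1:50) {
      b <- integer(len)
      local_codes <- integer(len)
      code <- 0L
      ok <- TRUE
      for (i in seq_len(len)) {
        cand <- sample.int(4L) - 1L
        placed <- FALSE
        for (nb in cand) {
          if (i < k) { b[i] <- nb; code <- code * 4L + nb; placed <- TRUE; break }
          nc <- (code %% suffix_mod) * 4L + nb
          if (!used[nc + 1L] && !used[rc_table[nc + 1L]]) {
            b[i] <- nb
            code <- nc
            local_codes[i] <- nc + 1L
            used[nc + 1L] <<- TRUE  # also blocks within-walk reuse
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      lc <- local_codes[local_codes > 0L]
      if (ok) {
        # keep the walk's own words marked: they now belong to this gene
        return(paste(bases[b + 1L], collapse = ""))
      }
      used[lc] <<- FALSE  # dead end: release and restart this gene
    }
    abort("failed to build a word-disjoint sequence; lower n_genes or gene_length")
  }
  seqs <- vapply(lens, walk_sequence, character(1))
  cat <- tibble(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    transcript_id = sprintf("tx%03d", seq_len(n_genes)),
    sequence = seqs,
    length = nchar(seqs),
    species_tag = species_tag
  )
  if (n_paralog_pairs > 0) {
    stopifnot(n_paralog_pairs <= n_genes)
    par <- cat[seq_len(n_paralog_pairs), ]
    par$gene_id <- paste0(par$gene_id, "p")
    par$transcript_id <- paste0(par$transcript_id, "p")
    par$sequence <- inject_divergence(par$sequence, paralog_divergence)
    par$length <- nchar(par$sequence)
    cat <- dplyr::arrange(dplyr::bind_rows(cat, par), .data$gene_id)
  }
  cat
}
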