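#' Alignment parameters
#'
#' Word size 9 is the seeding length used for read-to-gene assignment; the
#' scoring scheme is the classic nucleotide-BLAST default (+2 match, -3
#' mismatch, gap open 5, gap extend 2), under which a length-`L` gap costs
#' `5 + 2L`. `x_drop` bounds the ungapped seed extension; `band` is the
#' half-width (in diagonals) of the banded gapped extension around the seed
#' diagonals.
#'
#' @param word_size Exact-match seed length (>= 4; default 9).
#' @param match,mismatch Match/mismatch scores (default +2 / -3).
#' @param gap_open,gap_extend Affine gap penalties (default 5 / 2).
#' @param x_drop Ungapped extension drop-off (default 20).
#' @param band Diagonal half-band for gapped extension (default 5).
#' @return A list of class `align_params`.
#' @export
align_params <- function(word_size = 9L, match = 2L, mismatch = -3L,
                         gap_open = 5L, gap_extend = 2L, x_drop = 20L,
                         band = 5L) {
  stopifnot(word_size >= 4, match > 0, mismatch < 0, gap_open >= 0,
            gap_extend >= 0, x_drop > 0, band >= 1)
  structure(
    list(word_size = as.integer(word_size), match = as.integer(match),
         mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend), x_drop = as.integer(x_drop),
         band = as.integer(band)),
    class = "align_params"
  )
}

#' Build a seed index over subject sequences
#'
#' Indexes every `word_size`-mer over `{A,C,G,T}` (words containing `N` are
#' skipped) to its subject and position. Only the plus strand is indexed;
#' minus-strand hits are found by aligning the reverse-complemented query, so
#' subject coordinates are always reported on the subject plus strand.
#'
#' @param subjects Tibble with columns `seq_id` and `sequence` (a gene
#'   catalog works directly: its `gene_id` is used as `seq_id`).
#' @param params An [align_params()].
#' @return An object of class `tx_seed_index`.
#' @export
seed_index <- function(subjects, params = align_params()) {
  if (!"seq_id" %in% names(subjects) && "gene_id" %in% names(subjects)) {
    subjects$seq_id <- subjects$gene_id
  }
  if (nrow(subjects) == 0) abort("cannot index an empty subject collection")
  ptr <- cpp_build_index(subjects$seq_id, subjects$sequence, params$word_size)
  structure(
    list(ptr = ptr, seq_ids = subjects$seq_id,
         lengths = stats::setNames(nchar(subjects$sequence), subjects$seq_id),
         word_size = params$word_size),
    class = "tx_seed_index"
  )
}

#' Number of indexed words in a seed index
#' @param index A `tx_seed_index`.
#' @return Integer posting count.
#' @export
index_n_kmers <- function(index) cpp_index_n_kmers(index$ptr)

#' Seed-and-extend local alignment of one query
#'
#' Finds high-scoring pairs (HSPs) of the query against every indexed
#' subject, on both strands. Seed hits are clustered by diagonal, extended
#' ungapped under an x-drop rule, then refined by banded gapped extension;
#' overlapping HSPs in the same subject/strand region are collapsed to the
#' highest-scoring one. Output is deterministic and sorted by descending
#' score. A query shorter than the word size, or one sharing no word with
#' any subject, yields zero rows.
#'
#' @param query DNA string.
#' @param index A [seed_index()].
#' @param params An [align_params()] (must match the index word size).
#' @return Tibble of HSPs: `subject_id`, `strand`, 0-based half-open
#'   `query_start`/`query_end` and `subject_start`/`subject_end` (subject
#'   plus strand), `alignment_length`, `identities`, `score`,
#'   `identity_fraction`, `query_coverage`.
#' @export
local_align <- function(query, index, params = align_params()) {
  stopifnot(inherits(index, "tx_seed_index"))
  empty <- tibble(
    subject_id = character(), strand = character(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), subject_end = integer(),
    alignment_length = integer(), identities = integer(), score = integer(),
    identity_fraction = double(), query_coverage = double()
  )
  if (nchar(query) < index$word_size) return(empty)
  df <- cpp_local_align(query, index$ptr, params$match, params$mismatch,
                        params$gap_open, params$gap_extend, params$x_drop,
                        params$band)
  if (nrow(df) == 0) return(empty)
  tibble(
    subject_id = df$subject_id, strand = df$strand,
    query_start = df$qs, query_end = df$qe,
    subject_start = df$ss, subject_end = df$se,
    alignment_length = df$alignment_length, identities = df$identities,
    score = df$score,
    identity_fraction = df$identities / df$alignment_length,
    query_coverage = (df$qe - df$qs) / nchar(query)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$subject_id, .data$strand,
                   .data$subject_start)
}

#' Exact Smith-Waterman score (verification cross-check)
#'
#' Exhaustive local alignment with affine gaps under the same scoring as
#' [local_align()], delegated to `Biostrings::pairwiseAlignment()`. Used in
#' tests as the independent upper bound and best-hit oracle for the
#' seed-and-extend heuristic; a quadratic-cost guard rejects sequences over
#' 2,000 bases. Scores are clipped at 0 (the empty local alignment).
#'
#' @param query,subject DNA strings (plus strand; align the reverse
#'   complement yourself to query the minus strand).
#' @param params An [align_params()].
#' @return List with `score`, `query_interval`, `subject_interval` (0-based
#'   half-open).
#' @export
sw_oracle <- function(query, subject, params = align_params()) {
  if (nchar(query) > 2000 || nchar(subject) > 2000) {
    abort("sw_oracle is quadratic; sequences must be <= 2,000 bases")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, scoreOnly = FALSE
  )
  score <- Biostrings::score(aln)
  if (score <= 0) {
    return(list(score = 0L, query_interval = c(0L, 0L),
                subject_interval = c(0L, 0L)))
  }
  qr <- aln@pattern@range
  sr <- aln@subject@range
  list(
    score = as.integer(score),
    query_interval = c(BiocGenerics::start(qr) - 1L, BiocGenerics::end(qr)),
    subject_interval = c(BiocGenerics::start(sr) - 1L, BiocGenerics::end(sr))
  )
}

#' Best Smith-Waterman score over both strands
#'
#' Convenience wrapper around [sw_oracle()] that also tries the
#' reverse-complemented query and reports the better strand.
#'
#' @inheritParams sw_oracle
#' @return List with `score` and `strand` (`"plus"` or `"minus"`).
#' @export
sw_oracle_best <- function(query, subject, params = align_params()) {
  plus <- sw_oracle(query, subject, params)$score
  minus <- sw_oracle(revcomp(query), subject, params)$score
  if (minus > plus) list(score = minus, strand = "minus")
  else list(score = plus, strand = "plus")
}
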