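#' Quality-control settings
#'
#' Defaults follow the standard pre-assignment filter: end-trimming to
#' Phred >= 13 (error rate < 0.05), then rejection of any read with a single
#' base below Phred 5, more than 10% of bases below Phred 13, a mean Phred
#' below 20, or a trimmed length under 30 bases. All boundaries are strict:
#' a read with exactly 10% weak bases, mean exactly 20, or length exactly 30
#' survives. Rejected mates of a pair are replaced by a 50-base all-N
#' placeholder so R1/R2 files keep record-for-record parity.
#'
#' @param trim_min_phred Ends are trimmed until a base with at least this
#'   Phred score is met (default 13).
#' @param reject_any_below Reject when any base is below this score (5).
#' @param reject_frac_threshold Reject when more than this fraction of bases
#'   (default 0.10) is below `reject_frac_phred`.
#' @param reject_frac_phred Score used by the fraction rule (13).
#' @param reject_mean_below Reject when the mean Phred is below this (20).
#' @param min_length Reject when the trimmed read is shorter than this (30).
#' @param placeholder_length Length of the all-N replacement read (50).
#' @param merge_min_overlap Minimum read-through overlap for pair merging (8).
#' @param merge_min_identity Minimum identity over the merge overlap (0.90).
#' @param dedupe_cap Optional cap on identical-sequence copies for the
#'   over-representation filter; `NULL` (default) disables it.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(trim_min_phred = 13L, reject_any_below = 5L,
                      reject_frac_threshold = 0.10, reject_frac_phred = 13L,
                      reject_mean_below = 20, min_length = 30L,
                      placeholder_length = 50L, merge_min_overlap = 8L,
                      merge_min_identity = 0.90, dedupe_cap = NULL) {
  stopifnot(min_length >= 1, trim_min_phred >= 0, merge_min_overlap >= 1)
  structure(
    list(trim_min_phred = trim_min_phred, reject_any_below = reject_any_below,
         reject_frac_threshold = reject_frac_threshold,
         reject_frac_phred = reject_frac_phred,
         reject_mean_below = reject_mean_below, min_length = min_length,
         placeholder_length = placeholder_length,
         merge_min_overlap = merge_min_overlap,
         merge_min_identity = merge_min_identity, dedupe_cap = dedupe_cap),
    class = "qc_config"
  )
}

#' Trim read ends on quality
#'
#' Removes leading and trailing bases until a base with Phred score at least
#' `trim_min_phred` is encountered, trimming sequence and qualities in
#' lockstep. A read may trim to length zero.
#'
#' @param reads Read tibble.
#' @param cfg A [qc_config()].
#' @return The read tibble with trimmed `sequence` and `quality`.
#' @export
trim_reads <- function(reads, cfg = qc_config()) {
  if (nrow(reads) == 0) return(reads)
  trimmed <- purrr::map2(reads$sequence, reads$quality, function(s, q) {
    sc <- utf8ToInt(q) - 33L
    keep <- which(sc >= cfg$trim_min_phred)
    if (length(keep) == 0) return(c("", ""))
    c(substr(s, keep[1], keep[length(keep)]), substr(q, keep[1], keep[length(keep)]))
  })
  reads$sequence <- vapply(trimmed, `[`, character(1), 1)
  reads$quality <- vapply(trimmed, `[`, character(1), 2)
  reads
}

#' Flag reads failing the rejection rules
#'
#' Applied to already-trimmed reads. A read is rejected iff it has one base
#' below Phred 5, more than 10% of bases below Phred 13, a mean Phred below
#' 20, or fewer than 30 bases (defaults; all strict inequalities).
#'
#' @param reads Read tibble (trimmed).
#' @param cfg A [qc_config()].
#' @return Logical vector, `TRUE` = reject.
#' @export
reject_reads <- function(reads, cfg = qc_config()) {
  vapply(reads$quality, function(q) {
    sc <- utf8ToInt(q) - 33L
    n <- length(sc)
    if (n < cfg$min_length) return(TRUE)
    any(sc < cfg$reject_any_below) ||
      mean(sc < cfg$reject_frac_phred) > cfg$reject_frac_threshold ||
      mean(sc) < cfg$reject_mean_below
  }, logical(1), USE.NAMES = FALSE)
}

placeholder_read <- function(read_id, mate, cfg) {
  tibble(read_id = read_id,
         sequence = strrep("N", cfg$placeholder_length),
         quality = strrep("!", cfg$placeholder_length),  # Phred 0
         mate = mate, origin_gene_id = NA_character_)
}

is_placeholder <- function(reads) {
  grepl("^N+$", reads$sequence)
}

#' Quality-filter single-end (or merged) reads
#'
#' Trims, applies the rejection rules, and optionally caps identical
#' sequences (over-representation filter). Rejected reads are dropped; a
#' `qc_stats` attribute records the counts in/trimmed-out/kept.
#'
#' @param reads Read tibble.
#' @param cfg A [qc_config()].
#' @return Filtered read tibble with a `qc_stats` attribute.
#' @export
qc_reads <- function(reads, cfg = qc_config()) {
  n_in <- nrow(reads)
  trimmed <- trim_reads(reads, cfg)
  rej <- if (n_in > 0) reject_reads(trimmed, cfg) else logical(0)
  kept <- trimmed[!rej, , drop = FALSE]
  kept <- dedupe_overrepresented(kept, cfg)
  attr(kept, "qc_stats") <- list(n_in = n_in, n_rejected = sum(rej),
                                 n_kept = nrow(kept))
  kept
}

#' Quality-filter a read pair, preserving file parity
#'
#' Each mate is independently trimmed and tested; a rejected mate is replaced
#' by a 50-base all-N placeholder (Phred 0) so the R1 and R2 outputs keep
#' record-for-record parity. Pairs where both mates become placeholders carry
#' no sequence and are dropped before assignment by [drop_placeholder_pairs()].
#'
#' @param r1,r2 Read tibbles of equal row count (mates in matching order).
#' @param cfg A [qc_config()].
#' @return List with filtered `r1` and `r2` tibbles of the input row count.
#' @export
filter_pairs <- function(r1, r2, cfg = qc_config()) {
  stopifnot(nrow(r1) == nrow(r2))
  fix <- function(side, mate) {
    trimmed <- trim_reads(side, cfg)
    rej <- if (nrow(side) > 0) reject_reads(trimmed, cfg) else logical(0)
    if (any(rej)) {
      ph <- placeholder_read(trimmed$read_id[rej], mate, cfg)
      trimmed$sequence[rej] <- ph$sequence
      trimmed$quality[rej] <- ph$quality
    }
    trimmed
  }
  list(r1 = fix(r1, "R1"), r2 = fix(r2, "R2"))
}

#' Drop pairs in which both mates are placeholders
#'
#' @param pair List as returned by [filter_pairs()].
#' @return The same list without rows where both mates are all-N.
#' @export
drop_placeholder_pairs <- function(pair) {
  both <- is_placeholder(pair$r1) & is_placeholder(pair$r2)
  list(r1 = pair$r1[!both, , drop = FALSE], r2 = pair$r2[!both, , drop = FALSE])
}

#' Cap identical-sequence copies (over-representation filter)
#'
#' With `dedupe_cap` set, at most that many reads per identical sequence are
#' retained (first occurrences, stable order) to damp PCR duplicates and
#' extreme over-expression; with the default `NULL` the stream is unchanged.
#'
#' @param reads Read tibble.
#' @param cfg A [qc_config()].
#' @return Read tibble.
#' @export
dedupe_overrepresented <- function(reads, cfg = qc_config()) {
  if (is.null(cfg$dedupe_cap) || nrow(reads) == 0) return(reads)
  keep <- stats::ave(seq_len(nrow(reads)), reads$sequence,
                     FUN = seq_along) <= cfg$dedupe_cap
  reads[keep, , drop = FALSE]
}

#' Merge an overlapping read pair into one fragment
#'
#' R2 is reverse-complemented, then the longest suffix(R1)/prefix(revcomp R2)
#' overlap of at least `merge_min_overlap` bases and `merge_min_identity`
#' identity is accepted; merged qualities take the per-position maximum over
#' the two mates. Returns `NULL` when no acceptable overlap exists.
#'
#' @param r1,r2 Single-row read tibbles (R2 in sequencing orientation).
#' @param cfg A [qc_config()].
#' @return A single-row merged read tibble, or `NULL`.
#' @export
merge_pair <- function(r1, r2, cfg = qc_config()) {
  s1 <- r1$sequence[1]; q1 <- r1$quality[1]
  s2 <- revcomp(r2$sequence[1])
  q2 <- paste(rev(strsplit(r2$quality[1], "", fixed = TRUE)[[1]]), collapse = "")
  l1 <- nchar(s1); l2 <- nchar(s2)
  if (min(l1, l2) < cfg$merge_min_overlap) return(NULL)
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  for (o in seq(min(l1, l2), cfg$merge_min_overlap)) {
    m <- sum(a[(l1 - o + 1):l1] == b[1:o])
    if (m / o >= cfg$merge_min_identity) {
      p1 <- utf8ToInt(q1); p2 <- utf8ToInt(q2)
      ov_q <- pmax(p1[(l1 - o + 1):l1], p2[1:o])
      merged_q <- intToUtf8(c(p1[seq_len(l1 - o)], ov_q, p2[-seq_len(o)]))
      # overlap consensus: keep the higher-quality base at disagreeing columns
      ov_s <- ifelse(p1[(l1 - o + 1):l1] >= p2[1:o], a[(l1 - o + 1):l1], b[1:o])
      merged_s <- paste(c(a[seq_len(l1 - o)], ov_s, b[-seq_len(o)]), collapse = "")
      return(tibble(read_id = r1$read_id[1], sequence = merged_s,
                    quality = merged_q, mate = "single",
                    origin_gene_id = r1$origin_gene_id[1]))
    }
  }
  NULL
}
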