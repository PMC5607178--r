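#' Recovery rate of one gene
#'
#' The proportion of reads simulated from a gene that the pipeline assigns
#' back to that gene: 100 reads simulated, 80 of them assigned to their
#' source gene, gives rr = 80/100 = 0.8. Under the default tie policy a read
#' tied between several genes (`hit_multigene`) does not count as correctly
#' assigned; `ties = "duplicate"` counts it when the true gene is among the
#' tied set.
#'
#' @param truth Truth table (`read_id`, `origin_gene_id`).
#' @param assignments Assignment tibble from [assign_reads()].
#' @param gene_id Gene to evaluate (must have simulated reads).
#' @param ties `"exclude"` (default) or `"duplicate"`.
#' @return Fraction in `[0, 1]`.
#' @export
recovery_rate <- function(truth, assignments, gene_id,
                          ties = c("exclude", "duplicate")) {
  ev <- evaluate_assignment(truth, assignments, ties = ties)
  row <- ev[ev$gene_id == gene_id, ]
  if (nrow(row) == 0) abort(paste0("gene '", gene_id, "' has no simulated reads"))
  row$rr
}

#' Specificity rate of one gene
#'
#' The proportion of reads assigned to a gene that were simulated from it:
#' 150 reads assigned of which 80 originate from the gene gives
#' sr = 80/150 = 0.53. `NA` (undefined) when no read is assigned to the gene.
#'
#' @inheritParams recovery_rate
#' @return Fraction in `[0, 1]`, or `NA` when the gene received no reads.
#' @export
specificity_rate <- function(truth, assignments, gene_id,
                             ties = c("exclude", "duplicate")) {
  ev <- evaluate_assignment(truth, assignments, ties = ties)
  row <- ev[ev$gene_id == gene_id, ]
  if (nrow(row) == 0) return(NA_real_)
  row$sr
}

#' Five-way gene typology from (rr, sr)
#'
#' * `perfect`: rr = 1, sr = 1 — every simulated read recovered, no foreign
#'   read captured.
#' * `recipient`: rr = 1, sr < 1 — all own reads recovered but foreign reads
#'   captured.
#' * `donor`: 0 < rr < 1, sr = 1 — some own reads lost to other genes, none
#'   captured.
#' * `mixed`: rr < 1, sr < 1 — both losses and captures (includes rr = 0
#'   with sr = 0: only foreign reads assigned).
#' * `undetectable`: rr = 0, sr undefined — no read assigned at all.
#'
#' The state rr = 0 with sr defined and positive is impossible (a correctly
#' assigned read would make rr positive) and raises an error.
#'
#' @param rr,sr Numeric vectors (`sr` may contain `NA` for undefined).
#' @return Character vector of categories.
#' @export
classify_gene <- function(rr, sr) {
  stopifnot(length(rr) == length(sr), all(rr >= 0 & rr <= 1))
  bad <- rr == 0 & !is.na(sr) & sr > 0
  if (any(bad)) abort("impossible state: rr = 0 with sr > 0")
  dplyr::case_when(
    rr == 0 & is.na(sr) ~ "undetectable",
    rr == 1 & sr == 1 ~ "perfect",
    rr == 1 & sr < 1 ~ "recipient",
    rr < 1 & sr == 1 ~ "donor",
    TRUE ~ "mixed"
  )
}

#' Per-gene assignment evaluation (rr, sr, category)
#'
#' Joins the truth table against the assignment table and scores every gene
#' with simulated reads. Under `ties = "exclude"` (default) multigene reads
#' count neither as correct nor toward any gene's assigned total; the tally
#' of tied reads is kept in the `n_multigene_reads` attribute. With
#' `ties = "duplicate"` a tied read counts once per tied gene (and as correct
#' when its true gene is among the tie).
#'
#' @param truth Truth table (`read_id`, `origin_gene_id`).
#' @param assignments Assignment tibble from [assign_reads()].
#' @param catalog Optional gene catalog; adds a `gene_length` column.
#' @param ties `"exclude"` or `"duplicate"`.
#' @return Tibble of class `tx_assignment_eval`: `gene_id`, `gene_length`
#'   (if a catalog is given), `n_simulated`, `n_correct`, `n_assigned`,
#'   `rr`, `sr` (`NA` when undefined), `category`.
#' @export
evaluate_assignment <- function(truth, assignments, catalog = NULL,
                                ties = c("exclude", "duplicate")) {
  ties <- match.arg(ties)
  use <- if (ties == "exclude") {
    assignments[!assignments$hit_multigene, , drop = FALSE]
  } else {
    assignments
  }
  hits <- explode_assignments(use) %>%
    dplyr::left_join(truth[c("read_id", "origin_gene_id")], by = "read_id")
  per_gene_assigned <- hits %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_assigned = dplyr::n(),
      n_correct = sum(.data$origin_gene_id == .data$gene_id, na.rm = TRUE),
      .groups = "drop"
    )
  ev <- truth %>%
    dplyr::count(gene_id = .data$origin_gene_id, name = "n_simulated") %>%
    dplyr::left_join(per_gene_assigned, by = "gene_id") %>%
    tidyr::replace_na(list(n_assigned = 0L, n_correct = 0L)) %>%
    dplyr::mutate(
      rr = .data$n_correct / .data$n_simulated,
      sr = dplyr::if_else(.data$n_assigned > 0,
                          .data$n_correct / .data$n_assigned, NA_real_),
      category = classify_gene(.data$rr, .data$sr)
    ) %>%
    dplyr::arrange(.data$gene_id)
  if (!is.null(catalog)) {
    ev <- ev %>%
      dplyr::left_join(catalog[c("gene_id", "length")], by = "gene_id") %>%
      dplyr::rename(gene_length = "length") %>%
      dplyr::relocate("gene_length", .after = "gene_id")
  }
  attr(ev, "n_multigene_reads") <- sum(assignments$hit_multigene)
  class(ev) <- c("tx_assignment_eval", class(ev))
  ev
}

# width of the union of 0-based half-open intervals clipped to [0, Lg)
interval_union_width <- function(start, end, Lg) {
  start <- pmax(start, 0L)
  end <- pmin(end, Lg)
  ok <- end > start
  if (!any(ok)) return(0L)
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = start[ok] + 1L, end = end[ok])
  )))
}

#' Completeness of one gene's assembly
#'
#' Fraction of the gene's longest reference transcript (length `Lg`) covered
#' by the union of the aligned-contig intervals: `|union(C_gj) ∩ [0, Lg)| /
#' Lg`. Equals 1 when the combined aligned contigs tile the whole reference
#' transcript.
#'
#' @param starts,ends 0-based half-open subject intervals of the gene's
#'   contig HSPs on its longest reference transcript.
#' @param Lg Reference transcript length.
#' @return Fraction in `[0, 1]`; `NA` when there is no contig interval.
#' @export
completeness <- function(starts, ends, Lg) {
  if (length(starts) == 0) return(NA_real_)
  interval_union_width(starts, ends, Lg) / Lg
}

#' Contiguity of one gene's assembly
#'
#' Fraction of the longest reference transcript covered by the single
#' longest contig (by sequence length; ties broken by lexicographically
#' smallest contig id). Equals 1 when the longest contig matches the
#' reference transcript end to end. Always `<=` the gene's completeness.
#'
#' @param contig_id Contig id per interval row.
#' @param contig_length Contig sequence length per interval row.
#' @param starts,ends 0-based half-open subject intervals (as in
#'   [completeness()]).
#' @param Lg Reference transcript length.
#' @return Fraction in `[0, 1]`; `NA` when there is no contig.
#' @export
contiguity <- function(contig_id, contig_length, starts, ends, Lg) {
  if (length(starts) == 0) return(NA_real_)
  ord <- order(-contig_length, contig_id)
  best <- contig_id[ord[1]]
  sel <- contig_id == best
  interval_union_width(starts[sel], ends[sel], Lg) / Lg
}

#' Number of identified genes (NIG)
#'
#' A gene is identified when at least one validated contig is assigned to it.
#'
#' @param contigs Annotated contig tibble (with `gene_id`).
#' @return Integer count of distinct identified genes.
#' @export
count_identified_genes <- function(contigs) {
  if (nrow(contigs) == 0) return(0L)
  dplyr::n_distinct(contigs$gene_id)
}

#' Per-gene assembly evaluation (Cp, Ct)
#'
#' Scores every gene with at least one validated contig: completeness from
#' the union of all contig best-HSP intervals on the gene's longest
#' reference transcript, contiguity from the longest contig alone.
#'
#' @param contigs Annotated contig tibble from [guided_assembly()] /
#'   [annotate_contigs()].
#' @param catalog Gene catalog providing each gene's reference length.
#' @return Tibble of class `tx_assembly_eval`: `gene_id`, `Lg`, `n_contigs`,
#'   `Cp`, `Ct`.
#' @export
evaluate_assembly <- function(contigs, catalog) {
  lens <- stats::setNames(catalog$length, catalog$gene_id)
  ev <- contigs %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_contigs = dplyr::n(),
      Cp = completeness(.data$subject_start, .data$subject_end,
                        lens[[.data$gene_id[1]]]),
      Ct = contiguity(.data$contig_id, .data$length, .data$subject_start,
                      .data$subject_end, lens[[.data$gene_id[1]]]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(Lg = unname(lens[.data$gene_id])) %>%
    dplyr::relocate("Lg", .after = "gene_id") %>%
    dplyr::arrange(.data$gene_id)
  class(ev) <- c("tx_assembly_eval", class(ev))
  ev
}

#' Category counts by gene-length bin
#'
#' Bins genes by reference length (default 500-base windows up to 10 kb,
#' then open-ended) and tabulates the five categories per bin, with
#' per-bin proportions.
#'
#' @param evaluations A `tx_assignment_eval` with a `gene_length` column.
#' @param bin_width,max_bin Bin geometry in bases.
#' @return Tibble: `length_bin`, `category`, `n`, `proportion`.
#' @export
summarize_categories <- function(evaluations, bin_width = 500L, max_bin = 10000L) {
  stopifnot("gene_length" %in% names(evaluations))
  edges <- c(seq(0L, max_bin, by = bin_width), Inf)
  evaluations %>%
    dplyr::mutate(length_bin = cut(.data$gene_length, breaks = edges,
                                   right = FALSE, dig.lab = 6)) %>%
    dplyr::count(.data$length_bin, .data$category, name = "n") %>%
    dplyr::group_by(.data$length_bin) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
}
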