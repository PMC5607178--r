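#' Build a reference database from one or more sources
#'
#' Merges reference gene catalogs (and, optionally, annotated de novo contig
#' sets) into a single alignment database, the design that lets read
#' assignment profit both from sequence proximity to focal-species contigs
#' and from reference genes missing from the de novo assembly. Every member
#' sequence resolves to exactly one `gene_id`; the same `gene_id` may occur
#' in several sources (orthologs, or contigs annotated to a reference gene),
#' which is what the `hit_multispecies` flag detects.
#'
#' @param ... Named sources: each a tibble with `gene_id` and `sequence`
#'   columns (a gene catalog, or annotated contigs with a `gene_id`). Names
#'   are used as `species_tag`s; an unnamed source falls back to its
#'   `species_tag` column.
#' @param params An [align_params()].
#' @return An object of class `tx_reference_db` with the merged subject
#'   table and seed index.
#' @export
reference_db <- function(..., params = align_params()) {
  sources <- list(...)
  if (length(sources) == 0) abort("reference_db needs at least one source")
  tags <- names(sources)
  if (is.null(tags)) tags <- rep("", length(sources))
  subjects <- purrr::imap(sources, function(src, i) {
    tag <- if (is.character(i) && nzchar(i)) i
           else if ("species_tag" %in% names(src)) src$species_tag[1]
           else paste0("source", i)
    id_col <- if ("transcript_id" %in% names(src)) src$transcript_id
              else if ("contig_id" %in% names(src)) src$contig_id
              else src$gene_id
    tibble(
      seq_id = paste0(tag, ":", id_col),
      gene_id = src$gene_id,
      species_tag = tag,
      sequence = src$sequence
    )
  }) %>% purrr::list_rbind()
  if (anyDuplicated(subjects$seq_id) > 0) {
    abort("duplicated sequence ids across reference sources")
  }
  structure(
    list(subjects = subjects, index = seed_index(subjects, params),
         params = params),
    class = "tx_reference_db"
  )
}

#' Apply the assignment thresholds to HSPs
#'
#' An HSP supports assignment only when it spans more than 70% of the read
#' (`query_coverage > 0.70`) and more than 70% of its aligned columns are
#' identities (`identity_fraction > 0.70`); both inequalities are strict.
#' These cut-offs filter chimeras and contaminants while tolerating the
#' divergence expected between a non-model species and its reference.
#'
#' @param hsps HSP tibble from [local_align()].
#' @param min_coverage,min_identity Strict lower bounds (default 0.70).
#' @return The rows passing both thresholds.
#' @export
passes_thresholds <- function(hsps, min_coverage = 0.70, min_identity = 0.70) {
  hsps[hsps$query_coverage > min_coverage &
         hsps$identity_fraction > min_identity, , drop = FALSE]
}

#' Assign one read to gene-id(s) by best hit
#'
#' Among threshold-passing HSPs the maximal score defines the hit set: all
#' gene ids attaining it are recorded. A tie across distinct gene ids sets
#' `hit_multigene` (paralogs / multigene families); the same gene id at equal
#' best score from two or more sources sets `hit_multispecies` (orthologs).
#' Returns `NULL` when no HSP passes the thresholds.
#'
#' @param sequence Read sequence (one string).
#' @param db A [reference_db()].
#' @param params An [align_params()].
#' @param min_coverage,min_identity Assignment thresholds, see
#'   [passes_thresholds()].
#' @return One-row tibble (`gene_ids` semicolon-joined and sorted,
#'   `best_score`, `hit_multigene`, `hit_multispecies`,
#'   `n_hsps_considered`) or `NULL`.
#' @export
assign_read <- function(sequence, db, params = db$params,
                        min_coverage = 0.70, min_identity = 0.70) {
  hsps <- local_align(sequence, db$index, params)
  hsps <- passes_thresholds(hsps, min_coverage, min_identity)
  if (nrow(hsps) == 0) return(NULL)
  hsps <- dplyr::left_join(hsps, db$subjects[c("seq_id", "gene_id", "species_tag")],
                           by = c(subject_id = "seq_id"))
  # one representative (best) HSP per gene: multiple HSPs on a gene never sum
  per_gene <- hsps %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(best_score = max(.data$score),
                     n_species = dplyr::n_distinct(
                       .data$species_tag[.data$score == max(.data$score)]),
                     .groups = "drop")
  top <- max(per_gene$best_score)
  hits <- per_gene[per_gene$best_score == top, , drop = FALSE]
  tibble(
    gene_ids = paste(sort(hits$gene_id), collapse = ";"),
    best_score = top,
    hit_multigene = nrow(hits) > 1,
    hit_multispecies = any(hits$n_species >= 2),
    n_hsps_considered = nrow(hsps)
  )
}

#' Assign a read table to genes
#'
#' Runs [assign_read()] over a filtered read table. Placeholder (all-N) reads
#' produce no seeds and are skipped; unassigned reads contribute no row, so
#' `nrow(input) = nrow(assignments) + unassigned`. Deterministic.
#'
#' @param reads Read tibble (post-QC).
#' @param db A [reference_db()].
#' @param params An [align_params()].
#' @param min_coverage,min_identity Assignment thresholds.
#' @return Assignment tibble with one row per assigned read: `read_id`,
#'   `gene_ids`, `best_score`, `hit_multigene`, `hit_multispecies`,
#'   `n_hsps_considered`.
#' @export
assign_reads <- function(reads, db, params = db$params,
                         min_coverage = 0.70, min_identity = 0.70) {
  empty <- tibble(read_id = character(), gene_ids = character(),
                  best_score = integer(), hit_multigene = logical(),
                  hit_multispecies = logical(), n_hsps_considered = integer())
  keep <- which(!is_placeholder(reads) &
                  nchar(reads$sequence) >= params$word_size)
  if (length(keep) == 0) return(empty)
  hsps <- cpp_local_align_batch(reads$sequence[keep], db$index$ptr,
                                params$match, params$mismatch,
                                params$gap_open, params$gap_extend,
                                params$x_drop, params$band)
  if (nrow(hsps) == 0) return(empty)
  hsps <- tibble::as_tibble(hsps) %>%
    dplyr::mutate(
      read_id = reads$read_id[keep][.data$query],
      identity_fraction = .data$identities / .data$alignment_length,
      query_coverage = (.data$qe - .data$qs) /
        nchar(reads$sequence[keep])[.data$query]
    ) %>%
    passes_thresholds(min_coverage, min_identity)
  if (nrow(hsps) == 0) return(empty)
  # best HSP per (read, gene) is the gene's representative; never summed
  per_gene <- hsps %>%
    dplyr::left_join(db$subjects[c("seq_id", "gene_id", "species_tag")],
                     by = c(subject_id = "seq_id")) %>%
    dplyr::group_by(.data$read_id, .data$gene_id) %>%
    dplyr::summarise(
      best = max(.data$score),
      n_species = dplyr::n_distinct(
        .data$species_tag[.data$score == max(.data$score)]),
      n_hsps = dplyr::n(),
      .groups = "drop"
    )
  per_gene %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(
      gene_ids = paste(sort(.data$gene_id[.data$best == max(.data$best)]),
                       collapse = ";"),
      best_score = max(.data$best),
      hit_multigene = sum(.data$best == max(.data$best)) > 1,
      hit_multispecies = any(.data$n_species[.data$best == max(.data$best)] >= 2),
      n_hsps_considered = sum(.data$n_hsps),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$read_id)
}

#' Per-gene assigned-read counts
#'
#' Under the default `ties = "exclude"` policy a read tied between several
#' gene ids is excluded from every single gene's unambiguous count and
#' reported in the `n_multigene_reads` attribute instead — score ties are
#' recorded, not resolved. `ties = "duplicate"` counts a tied read once per
#' tied gene (sensitivity analysis).
#'
#' @param assignments Assignment tibble from [assign_reads()].
#' @param ties `"exclude"` (default) or `"duplicate"`.
#' @return Tibble (`gene_id`, `n_assigned`) sorted by `gene_id`, with
#'   attribute `n_multigene_reads`.
#' @export
count_assignments <- function(assignments, ties = c("exclude", "duplicate")) {
  ties <- match.arg(ties)
  use <- if (ties == "exclude") {
    assignments[!assignments$hit_multigene, , drop = FALSE]
  } else {
    assignments
  }
  counts <- explode_assignments(use) %>%
    dplyr::count(.data$gene_id, name = "n_assigned") %>%
    dplyr::arrange(.data$gene_id)
  attr(counts, "n_multigene_reads") <- sum(assignments$hit_multigene)
  counts
}
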