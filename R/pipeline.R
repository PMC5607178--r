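#' Run the guided assembly pipeline end to end
#'
#' Drives the full guided route: quality filtering, best-hit read assignment
#' against the reference database, per-gene greedy assembly, contig
#' annotation/validation, and (when a truth table is supplied) the full
#' evaluation layer. Every stage logs conservation-checkable counts; with
#' `out_dir` set, all intermediate tables, per-gene FASTA bins and a
#' reproducibility manifest are persisted.
#'
#' @param reads Read tibble (single-end or already-merged reads).
#' @param reference A gene catalog, or a named list of catalogs/annotated
#'   contig sets merged into one database (see [reference_db()]).
#' @param params An [align_params()].
#' @param qc A [qc_config()].
#' @param truth Optional truth table for simulated reads.
#' @param ties Tie policy, see [count_assignments()].
#' @param min_overlap,min_identity Assembler settings.
#' @param out_dir Optional output directory.
#' @return A list of class `tx_pipeline_result`: `qc_stats`, filtered
#'   `reads`, `assignments`, per-gene `counts`, validated `contigs`,
#'   `nig`, and (with truth) `evaluation` (a [evaluate_run()] object).
#' @export
run_guided_pipeline <- function(reads, reference, params = align_params(),
                                qc = qc_config(), truth = NULL,
                                ties = c("exclude", "duplicate"),
                                min_overlap = 30L, min_identity = 0.95,
                                out_dir = NULL) {
  ties <- match.arg(ties)
  db <- if (inherits(reference, "tx_reference_db")) {
    reference
  } else if (is.data.frame(reference)) {
    reference_db(reference, params = params)
  } else {
    do.call(reference_db, c(reference, list(params = params)))
  }
  catalog <- if (is.data.frame(reference)) reference else NULL

  filtered <- qc_reads(reads, qc)
  stats <- attr(filtered, "qc_stats")
  log_stage("qc", sprintf("reads in=%d rejected=%d kept=%d",
                          stats$n_in, stats$n_rejected, stats$n_kept))

  assignments <- assign_reads(filtered, db, params)
  log_stage("assign", sprintf(
    "assigned=%d multigene=%d unassigned=%d",
    nrow(assignments), sum(assignments$hit_multigene),
    nrow(filtered) - nrow(assignments)))
  counts <- count_assignments(assignments, ties)

  contigs <- guided_assembly(assignments, filtered, db,
                             params = params, min_overlap = min_overlap,
                             min_identity = min_identity,
                             out_dir = if (is.null(out_dir)) NULL
                                       else file.path(out_dir, "contigs"))
  nig <- count_identified_genes(contigs)
  log_stage("assemble", sprintf(
    "contigs=%d discarded=%d identified_genes=%d",
    nrow(contigs), nrow(attr(contigs, "discarded")), nig))

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- evaluate_run(truth, assignments, contigs,
                               catalog = catalog, ties = ties)
  }

  result <- structure(
    list(qc_stats = stats, reads = filtered, assignments = assignments,
         counts = counts, contigs = contigs, nig = nig,
         evaluation = evaluation, ties = ties),
    class = "tx_pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(assignments, file.path(out_dir, "assignments.tsv"))
    write_table(counts, file.path(out_dir, "gene_counts.tsv"))
    write_table(dplyr::select(contigs, -"member_read_ids"),
                file.path(out_dir, "contigs.tsv"))
    if (!is.null(evaluation)) {
      write_table(evaluation$genes, file.path(out_dir, "gene_evaluation.tsv"))
      if (!is.null(evaluation$assembly)) {
        write_table(evaluation$assembly, file.path(out_dir, "assembly_evaluation.tsv"))
      }
    }
    write_manifest(result, params, qc, file.path(out_dir, "manifest.tsv"))
  }
  result
}

log_stage <- function(stage, msg) {
  message(sprintf("[txguide:%s] %s", stage, msg))
}

write_manifest <- function(result, params, qc, path) {
  kv <- c(
    txguide_version = as.character(utils::packageVersion("txguide")),
    r_version = as.character(getRversion()),
    ties = result$ties,
    unlist(params[names(params)]),
    qc_min_length = qc$min_length,
    qc_trim_min_phred = qc$trim_min_phred,
    reads_in = result$qc_stats$n_in,
    reads_kept = result$qc_stats$n_kept,
    reads_assigned = nrow(result$assignments),
    contigs = nrow(result$contigs),
    identified_genes = result$nig
  )
  readr::write_tsv(tibble(parameter = names(kv), value = unname(kv)), path,
                   progress = FALSE)
  invisible(path)
}

#' Combined evaluation object for one pipeline run
#'
#' Bundles the per-gene assignment evaluation (rr, sr, typology) and, when
#' contigs are available, the per-gene assembly evaluation (Cp, Ct) plus the
#' number of identified genes. Supports [tidy()], [glance()] and
#' [ggplot2::autoplot()].
#'
#' @param truth Truth table.
#' @param assignments Assignment tibble.
#' @param contigs Optional annotated contig tibble.
#' @param catalog Optional gene catalog (adds lengths and enables the
#'   length-binned summary).
#' @param ties Tie policy.
#' @param condition Optional named list recording the simulation condition
#'   (read length, divergence, ...), carried into [glance()].
#' @return A list of class `tx_evaluation` with elements `genes`,
#'   `assembly` (or `NULL`), `nig`, `condition`.
#' @export
evaluate_run <- function(truth, assignments, contigs = NULL, catalog = NULL,
                         ties = c("exclude", "duplicate"), condition = list()) {
  genes <- evaluate_assignment(truth, assignments, catalog, ties)
  assembly <- NULL
  nig <- NA_integer_
  if (!is.null(contigs) && nrow(contigs) > 0 && !is.null(catalog)) {
    assembly <- evaluate_assembly(contigs, catalog)
    nig <- count_identified_genes(contigs)
  } else if (!is.null(contigs)) {
    nig <- count_identified_genes(contigs)
  }
  structure(list(genes = genes, assembly = assembly, nig = nig,
                 condition = condition),
            class = "tx_evaluation")
}

#' @export
tidy.tx_evaluation <- function(x, ...) {
  out <- tibble::as_tibble(x$genes)
  if (!is.null(x$assembly)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$assembly, "gene_id", "Cp", "Ct"),
                            by = "gene_id")
  }
  out
}

#' @export
glance.tx_evaluation <- function(x, ...) {
  g <- x$genes
  out <- tibble(
    n_genes = nrow(g),
    mean_rr = mean(g$rr),
    mean_sr = mean(g$sr, na.rm = TRUE),
    prop_perfect = mean(g$category == "perfect"),
    prop_undetectable = mean(g$category == "undetectable"),
    n_multigene_reads = attr(g, "n_multigene_reads"),
    nig = x$nig
  )
  if (!is.null(x$assembly)) {
    out$mean_cp <- mean(x$assembly$Cp)
    out$mean_ct <- mean(x$assembly$Ct)
  }
  if (length(x$condition) > 0) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(x$condition))
  }
  out
}

#' @export
print.tx_evaluation <- function(x, ...) {
  cat("<tx_evaluation>\n")
  print(glance(x))
  invisible(x)
}

#' @export
print.tx_pipeline_result <- function(x, ...) {
  cat("<tx_pipeline_result>\n")
  cat(sprintf("  reads: %d in, %d kept, %d assigned (%d multigene)\n",
              x$qc_stats$n_in, x$qc_stats$n_kept, nrow(x$assignments),
              sum(x$assignments$hit_multigene)))
  cat(sprintf("  contigs: %d validated; identified genes (NIG): %d\n",
              nrow(x$contigs), x$nig))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

#' Stacked category proportions by gene-length bin
#'
#' Mirrors the typology-by-size-class view: each bar is a gene-length bin,
#' filled by the proportion of perfect/recipient/donor/mixed/undetectable
#' genes in it.
#'
#' @param object A `tx_evaluation` (with gene lengths available).
#' @param bin_width,max_bin Bin geometry in bases.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tx_evaluation <- function(object, bin_width = 500L, max_bin = 10000L,
                                   ...) {
  summ <- summarize_categories(object$genes, bin_width, max_bin)
  summ$category <- factor(summ$category, levels = c(
    "perfect", "recipient", "donor", "mixed", "undetectable"))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$length_bin,
                                     y = .data$proportion,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(x = "gene length bin (bases)", y = "proportion of genes",
                  fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean recovery rate across divergence levels
#'
#' Line plot of mean rr (one line per read length) against divergence,
#' the qualitative signature being monotone degradation with divergence.
#'
#' @param summaries Tibble with columns `divergence`, `read_length`,
#'   `mean_rr` (e.g. row-bound [glance()] outputs).
#' @return A ggplot object.
#' @export
plot_divergence_sweep <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$divergence, y = .data$mean_rr,
                               colour = factor(.data$read_length))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "divergence (substitution rate)",
                  y = "mean recovery rate", colour = "read length") +
    ggplot2::theme_minimal()
}
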