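#' Greedy overlap-consensus assembly of a read bin
#'
#' A minimal overlap-layout-consensus assembler for per-gene read bins:
#' repeatedly merges the contig pair with the longest suffix-prefix overlap
#' of at least `min_overlap` bases at `min_identity` identity, considering
#' both relative orientations, with a per-column majority-vote consensus.
#' Reads that never merge become single-read contigs. Deterministic: ties
#' are broken by lexicographic read id. The default `min_overlap = 30`
#' matches the QC minimum read length.
#'
#' @param reads Read tibble (non-empty).
#' @param min_overlap Minimum merge overlap in bases (default 30).
#' @param min_identity Minimum identity over the overlap (default 0.95).
#' @return Contig tibble: `contig_id`, `sequence`, `length`,
#'   `member_read_ids` (list column), `n_reads`, `origin = "internal"`.
#' @export
greedy_assemble <- function(reads, min_overlap = 30L, min_identity = 0.95) {
  if (nrow(reads) == 0) abort("cannot assemble an empty read set")
  reads <- dplyr::arrange(reads, .data$read_id)
  res <- cpp_greedy_assemble(reads$sequence, as.integer(min_overlap), min_identity)
  tibble(
    contig_id = sprintf("ctg%03d", seq_along(res$sequence)),
    sequence = res$sequence,
    length = nchar(res$sequence),
    member_read_ids = lapply(res$members, function(i) reads$read_id[i]),
    n_reads = vapply(res$members, length, integer(1)),
    origin = "internal"
  )
}

#' Annotate contigs against the reference and validate them
#'
#' Each contig is aligned to the reference database; only its best
#' threshold-passing HSP is conserved and determines the annotation. Score
#' ties across gene ids are kept as multigene annotations. When the best HSP
#' is on the minus strand, the contig sequence is replaced by its reverse
#' complement so every retained contig sits on the reference plus strand.
#' Contigs with no threshold-passing HSP are discarded; the discard log is
#' attached as the `discarded` attribute.
#'
#' @param contigs Contig tibble (from [greedy_assemble()] or an external
#'   assembler adapter).
#' @param db A [reference_db()].
#' @param params An [align_params()].
#' @param min_coverage,min_identity Annotation thresholds (same rule as read
#'   assignment, see [passes_thresholds()]).
#' @return Annotated contig tibble with `gene_id` (primary annotation),
#'   `gene_ids`, `hit_multigene`, `oriented`, `subject_start`, `subject_end`
#'   (best-HSP interval on the annotated gene, 0-based half-open),
#'   `identity_fraction`, `score`; attribute `discarded` is a tibble
#'   (`contig_id`, `reason`).
#' @export
annotate_contigs <- function(contigs, db, params = db$params,
                             min_coverage = 0.70, min_identity = 0.70) {
  kept <- list()
  dropped <- list()
  for (i in seq_len(nrow(contigs))) {
    hsps <- local_align(contigs$sequence[i], db$index, params)
    hsps <- passes_thresholds(hsps, min_coverage, min_identity)
    if (nrow(hsps) == 0) {
      dropped[[length(dropped) + 1]] <-
        tibble(contig_id = contigs$contig_id[i], reason = "no_annotation")
      next
    }
    hsps <- dplyr::left_join(
      hsps, db$subjects[c("seq_id", "gene_id", "species_tag")],
      by = c(subject_id = "seq_id")
    )
    top <- max(hsps$score)
    best <- hsps[hsps$score == top, , drop = FALSE]
    gene_ids <- sort(unique(best$gene_id))
    # the representative HSP: best score, first gene id, plus strand preferred
    rep_hsp <- best[order(best$gene_id, best$strand != "plus",
                          best$subject_start), ][1, ]
    row <- contigs[i, ]
    oriented <- rep_hsp$strand == "minus"
    if (oriented) row$sequence <- revcomp(row$sequence)
    row$gene_id <- rep_hsp$gene_id
    row$gene_ids <- paste(gene_ids, collapse = ";")
    row$hit_multigene <- length(gene_ids) > 1
    row$oriented <- oriented
    row$subject_start <- rep_hsp$subject_start
    row$subject_end <- rep_hsp$subject_end
    row$identity_fraction <- rep_hsp$identity_fraction
    row$score <- rep_hsp$score
    kept[[length(kept) + 1]] <- row
  }
  out <- purrr::list_rbind(kept)
  if (length(kept) == 0) {
    out <- dplyr::mutate(contigs[0, ], gene_id = character(),
                         gene_ids = character(), hit_multigene = logical(),
                         oriented = logical(), subject_start = integer(),
                         subject_end = integer(), identity_fraction = double(),
                         score = integer())
  }
  attr(out, "discarded") <- if (length(dropped) > 0) {
    purrr::list_rbind(dropped)
  } else {
    tibble(contig_id = character(), reason = character())
  }
  out
}

#' Guided per-gene assembly with contig validation
#'
#' Bins assigned reads by gene (tied reads enter every tied gene's bin),
#' assembles each bin with [greedy_assemble()], then annotates and validates
#' every contig against the reference with [annotate_contigs()]. The
#' validation annotation is authoritative: a contig whose best hit is a
#' different gene than its bin is re-binned to the annotated gene, and
#' unannotated contigs are discarded. Duplicate contigs arising from tied
#' reads assembled in several bins are collapsed by identical sequence.
#'
#' @param assignments Assignment tibble from [assign_reads()].
#' @param reads Read tibble holding the assigned reads.
#' @param db A [reference_db()].
#' @param params An [align_params()].
#' @param min_overlap,min_identity Assembler settings, see
#'   [greedy_assemble()].
#' @param out_dir Optional directory; when given, one validated-contig FASTA
#'   per gene is written there.
#' @return Validated contig tibble (one row per contig, `gene_id` = final
#'   annotation) with attribute `discarded`.
#' @export
guided_assembly <- function(assignments, reads, db, params = db$params,
                            min_overlap = 30L, min_identity = 0.95,
                            out_dir = NULL) {
  bins <- explode_assignments(assignments) %>%
    dplyr::inner_join(reads, by = "read_id") %>%
    dplyr::group_by(.data$gene_id)
  keys <- dplyr::group_keys(bins)$gene_id
  pieces <- dplyr::group_split(bins)
  contigs <- purrr::map2(pieces, keys, function(bin, g) {
    ctg <- greedy_assemble(bin, min_overlap, min_identity)
    ctg$contig_id <- paste0(g, "_", ctg$contig_id)
    ctg
  }) %>% purrr::list_rbind()
  if (nrow(contigs) == 0) {
    ann <- annotate_contigs(contigs[0, ], db, params)
    return(ann)
  }
  ann <- annotate_contigs(contigs, db, params)
  # tied reads sit in several bins; identical re-annotated contigs collapse
  ann <- ann %>%
    dplyr::arrange(.data$gene_id, .data$contig_id) %>%
    dplyr::distinct(.data$gene_id, .data$sequence, .keep_all = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in unique(ann$gene_id)) {
      b <- ann[ann$gene_id == g, ]
      writeLines(paste0(">", b$contig_id, "\n", b$sequence),
                 file.path(out_dir, paste0(g, ".contigs.fasta")))
    }
  }
  ann
}

#' Command lines for external assembler adapters
#'
#' Builds the invocation the adapter would run: Trinity with read
#' normalisation and stranded-library handling, Spades with `--careful` and
#' automatic coverage cut-off, or CAP3 with defaults. Exposed separately so
#' the exact command can be inspected and tested without the binary.
#'
#' @param tool One of `"trinity"`, `"spades"`, `"cap3"`.
#' @param bin_fasta Input FASTA of binned reads.
#' @param out_dir Tool output directory.
#' @return Character vector: the program and its arguments.
#' @export
adapter_command <- function(tool = c("trinity", "spades", "cap3"),
                            bin_fasta, out_dir) {
  tool <- match.arg(tool)
  switch(tool,
    trinity = c("Trinity", "--seqType", "fa", "--single", bin_fasta,
                "--normalize_reads", "--SS_lib_type", "F",
                "--output", out_dir, "--max_memory", "4G"),
    spades = c("spades.py", "--careful", "--cov-cutoff", "auto",
               "-s", bin_fasta, "-o", out_dir),
    cap3 = c("cap3", bin_fasta)
  )
}

#' Run an external assembler on a read bin
#'
#' Thin adapter over Trinity, Spades or CAP3. Fails with an explicit
#' `txguide_adapter_unavailable` error when the binary is not on the PATH —
#' never a silent fallback to the internal assembler.
#'
#' @inheritParams adapter_command
#' @return Contig tibble parsed from the tool's FASTA output
#'   (`origin = "external_adapter"`).
#' @export
external_assembler_adapter <- function(tool = c("trinity", "spades", "cap3"),
                                       bin_fasta, out_dir = tempfile("asm")) {
  tool <- match.arg(tool)
  cmd <- adapter_command(tool, bin_fasta, out_dir)
  if (Sys.which(cmd[1]) == "") {
    abort(paste0("external assembler adapter unavailable: '", cmd[1],
                 "' not found on PATH"),
          class = "txguide_adapter_unavailable")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- system2(cmd[1], cmd[-1], stdout = FALSE, stderr = FALSE)
  if (status != 0) abort(paste0(tool, " exited with status ", status))
  out_fasta <- switch(tool,
    trinity = file.path(out_dir, "Trinity.fasta"),
    spades = file.path(out_dir, "contigs.fasta"),
    cap3 = paste0(bin_fasta, ".cap.contigs")
  )
  seqs <- Biostrings::readDNAStringSet(out_fasta)
  tibble(
    contig_id = sub("\\s.*$", "", names(seqs)),
    sequence = as.character(seqs),
    length = nchar(as.character(seqs)),
    member_read_ids = vector("list", length(seqs)),
    n_reads = NA_integer_,
    origin = "external_adapter"
  )
}
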