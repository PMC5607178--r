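#' Read a reference transcriptome FASTA into a transcript table
#'
#' Parses a FASTA file whose headers carry a gene identifier and a transcript
#' identifier separated by a delimiter (default `"geneid|transcriptid"`), the
#' usual layout for per-gene reference transcriptomes of non-model species.
#' Sequences are uppercased and RNA `U` is mapped to `T` on ingest; entry
#' order is preserved and multi-line sequences are concatenated.
#'
#' @param path Path to a FASTA file.
#' @param header_delim Single-character delimiter separating the gene id from
#'   the transcript id in each header (first whitespace-delimited token only).
#' @return A tibble with columns `gene_id`, `transcript_id`, `sequence`,
#'   `length`, one row per FASTA entry in file order.
#' @export
read_transcripts_fasta <- function(path, header_delim = "|") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  seqs <- Biostrings::readBStringSet(path)  # BString: tolerate case and U
  headers <- sub("\\s.*$", "", names(seqs))
  transcript_table(headers, unname(as.character(seqs)), header_delim)
}

transcript_table <- function(headers, sequences, header_delim = "|") {
  if (length(headers) == 0) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  sequence = character(), length = integer()))
  }
  parts <- stringr::str_split_fixed(headers, stringr::fixed(header_delim), 2)
  bad <- which(parts[, 1] == "" | parts[, 2] == "")
  if (length(bad) > 0) {
    abort(paste0("cannot extract gene_id/transcript_id from FASTA header '",
                 headers[bad[1]], "' (entry ", bad[1],
                 ") with delimiter '", header_delim, "'"))
  }
  sequences <- chartr("u", "U", toupper(sequences))
  sequences <- chartr("U", "T", sequences)
  if (any(nchar(sequences) < 1)) abort("empty sequence in FASTA input")
  tibble(
    gene_id = parts[, 1],
    transcript_id = parts[, 2],
    sequence = sequences,
    length = nchar(sequences)
  )
}

#' Build a gene catalog: one (longest) transcript per gene
#'
#' Reduces a transcript table to the assignment universe used throughout the
#' pipeline: for every distinct `gene_id` the longest transcript is kept (the
#' standard convention when a transcriptome is used as an alignment
#' reference), with length ties resolved to the lexicographically smallest
#' `transcript_id`. The operation is idempotent.
#'
#' @param transcripts A tibble as returned by [read_transcripts_fasta()].
#' @param species_tag Label identifying this reference (used to detect
#'   cross-species score ties when several references are combined).
#' @return A tibble with columns `gene_id`, `transcript_id`, `sequence`,
#'   `length`, `species_tag`, one row per gene, sorted by `gene_id`.
#' @export
build_gene_catalog <- function(transcripts, species_tag = "reference") {
  if (nrow(transcripts) == 0) abort("cannot build a gene catalog from zero transcripts")
  transcripts %>%
    dplyr::mutate(length = nchar(.data$sequence)) %>%
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$length), .data$transcript_id) %>%
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) %>%
    dplyr::mutate(species_tag = species_tag) %>%
    dplyr::select("gene_id", "transcript_id", "sequence", "length", "species_tag")
}

#' Read a FASTQ file into a read table
#'
#' Qualities are kept as Phred+33 strings (decode with [phred_scores()]).
#' A record whose quality string length differs from its sequence length, or
#' whose quality characters fall outside the Phred+33 range, is a parse error.
#'
#' @param path Path to a FASTQ file (Phred+33).
#' @param mate One of `"single"`, `"R1"`, `"R2"`.
#' @return A tibble with columns `read_id`, `sequence`, `quality`, `mate`,
#'   `origin_gene_id` (`NA` for real data).
#' @export
read_reads_fastq <- function(path, mate = c("single", "R1", "R2")) {
  mate <- match.arg(mate)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  parsed <- tryCatch({
    qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    if (any(Biostrings::width(qs) != Biostrings::width(Biostrings::quality(qs)))) {
      stop("sequence/quality length mismatch")
    }
    list(ids = names(qs), seqs = unname(as.character(qs)),
         quals = unname(as.character(Biostrings::quality(qs))))
  }, error = function(e) {
    abort(paste0("FASTQ parse error in ", path, ": ", conditionMessage(e)))
  })
  seqs <- parsed$seqs
  quals <- parsed$quals
  scores <- unlist(phred_scores(quals))
  if (length(scores) > 0 && (min(scores) < 0 || max(scores) > 60)) {
    abort("FASTQ parse error: Phred score outside [0, 60] (expected Phred+33)")
  }
  tibble(
    read_id = sub("\\s.*$", "", parsed$ids),
    sequence = toupper(seqs),
    quality = quals,
    mate = mate,
    origin_gene_id = NA_character_
  )
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    if (nchar(q) == 0) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

#' Write a read table to FASTQ (Phred+33)
#'
#' @param reads A read tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  if (nrow(reads) > 0) {
    lines[seq(1, length(lines), by = 4)] <- paste0("@", reads$read_id)
    lines[seq(2, length(lines), by = 4)] <- reads$sequence
    lines[seq(3, length(lines), by = 4)] <- "+"
    lines[seq(4, length(lines), by = 4)] <- reads$quality
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write one FASTA file of assigned reads per gene
#'
#' Reads flagged `hit_multigene` are written to the file of every tied gene,
#' so each gene's bin contains all reads that could belong to it.
#'
#' @param assignments Assignment table from [assign_reads()].
#' @param reads Read tibble holding every assigned read.
#' @param out_dir Output directory (created if needed).
#' @return Number of FASTA files written (= genes with at least one assigned
#'   read), invisibly.
#' @export
write_per_gene_fasta <- function(assignments, reads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bins <- explode_assignments(assignments) %>%
    dplyr::inner_join(reads, by = "read_id")
  missing <- setdiff(assignments$read_id, reads$read_id)
  if (length(missing) > 0) {
    abort(paste0("assignment references unknown read: ", missing[1]))
  }
  genes <- sort(unique(bins$gene_id))
  for (g in genes) {
    b <- bins[bins$gene_id == g, ]
    b <- b[order(b$read_id), ]
    writeLines(paste0(">", b$read_id, "\n", b$sequence),
               file.path(out_dir, paste0(g, ".fasta")))
  }
  invisible(length(genes))
}

# one row per (read, gene) from the semicolon-joined gene_ids column
explode_assignments <- function(assignments) {
  assignments %>%
    dplyr::mutate(gene_id = strsplit(.data$gene_ids, ";", fixed = TRUE)) %>%
    tidyr::unnest("gene_id")
}

#' Write a result table as deterministic TSV
#'
#' Rows are sorted by `gene_id` then `read_id` (whichever columns exist) so
#' that repeated runs produce byte-identical files.
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  keys <- intersect(c("gene_id", "read_id"), names(x))
  if (length(keys) > 0) x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(keys)))
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(v, collapse = ";"), character(1))
  ))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a gene catalog (or any sequence table) as FASTA
#'
#' Headers are `gene_id<delim>transcript_id` so the file round-trips through
#' [read_transcripts_fasta()].
#'
#' @param catalog Tibble with `gene_id`, `transcript_id`, `sequence`.
#' @param path Output path.
#' @param header_delim Delimiter for the header fields.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path, header_delim = "|") {
  writeLines(paste0(">", catalog$gene_id, header_delim, catalog$transcript_id,
                    "\n", catalog$sequence), path)
  invisible(path)
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
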