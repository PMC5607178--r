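# Shared in-code fixtures. Everything is generated programmatically under
# fixed seeds; nothing is read from disk except files the tests write first.

# quality string from integer Phred scores
qual_string <- function(scores) intToUtf8(scores + 33L)

make_read <- function(read_id, sequence, scores = rep(40L, nchar(sequence)),
                      mate = "single", origin = NA_character_) {
  tibble::tibble(read_id = read_id, sequence = sequence,
                 quality = qual_string(scores), mate = mate,
                 origin_gene_id = origin)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small word-disjoint catalog reused across files (cheap to regenerate)
toy_catalog <- function(n_genes = 6, gene_length = 400, seed = 101, ...) {
  synthesize_catalog(n_genes, gene_length, seed = seed, ...)
}
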