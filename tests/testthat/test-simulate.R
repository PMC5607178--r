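test_that("tiling emits ceil(coverage*L/r_eff) evenly spaced reads", {
  cfg <- sim_config(read_length = 100, coverage = 10, seed = 5)
  tx <- random_dna(300)
  reads <- tile_reads("g1", tx, cfg)
  expect_equal(nrow(reads), 30)  # ceil(10*300/100)
  expect_equal(range(reads$start), c(0, 200))
  # mean per-base depth equals coverage exactly for this geometry
  depth <- rep(0, 300)
  for (s in reads$start) depth[(s + 1):(s + 100)] <- depth[(s + 1):(s + 100)] + 1
  expect_equal(mean(depth), 10, tolerance = 0.01)
  expect_true(all(reads$origin_gene_id == "g1"))
  expect_true(all(phred_scores(reads$quality[1])[[1]] == 40))
})

test_that("transcripts shorter than the read length yield whole-transcript copies", {
  cfg <- sim_config(read_length = 100, coverage = 10, seed = 5)
  tx100 <- random_dna(100)
  r <- tile_reads("g1", tx100, cfg)
  expect_equal(nrow(r), 10)
  expect_true(all(r$sequence == tx100))

  tx50 <- random_dna(50)
  r <- tile_reads("g1", tx50, cfg)  # r_eff = 50, n = ceil(10*50/50)
  expect_equal(nrow(r), 10)
  expect_true(all(r$sequence == tx50))
})

test_that("divergence injection substitutes at the requested rate", {
  s <- random_dna(10000)
  expect_identical(inject_divergence(s, 0), s)

  set.seed(9)
  all_a <- strrep("A", 200)
  forced <- inject_divergence(all_a, 1)
  expect_false(grepl("A", forced, fixed = TRUE))
  expect_equal(nchar(forced), 200)

  set.seed(10)
  mut <- inject_divergence(s, 0.15)
  hamming <- sum(strsplit(s, "")[[1]] != strsplit(mut, "")[[1]])
  sd3 <- 3 * sqrt(10000 * 0.15 * 0.85)
  expect_lt(abs(hamming - 1500), sd3)
  expect_equal(nchar(mut), nchar(s))  # substitution-only, no indels
})

test_that("dataset simulation is deterministic and coverage-conserving", {
  cat_tbl <- toy_catalog(5, 1000)
  cfg <- sim_config(read_length = 100, divergence = 0, coverage = 10, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  sim1 <- simulate_dataset(cat_tbl, cfg, fastq_path = f1)
  sim2 <- simulate_dataset(cat_tbl, cfg, fastq_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(sim1$reads), 5 * ceiling(10 * 1000 / 100))

  # truth-table completeness: every read exactly once
  expect_setequal(sim1$truth$read_id, sim1$reads$read_id)
  expect_equal(anyDuplicated(sim1$truth$read_id), 0)

  # coverage conservation per gene
  cov <- sim1$reads %>%
    dplyr::mutate(len = nchar(sequence)) %>%
    dplyr::group_by(origin_gene_id) %>%
    dplyr::summarise(total = sum(len))
  expect_true(all(cov$total / 1000 >= 10))

  # zero divergence: every read is an exact substring of its transcript
  idx <- match(sim1$truth$origin_gene_id, cat_tbl$gene_id)
  hit <- mapply(function(r, tx) grepl(r, tx, fixed = TRUE),
                sim1$reads$sequence, cat_tbl$sequence[idx])
  expect_true(all(hit))
})

test_that("per-gene RNG substreams make simulation order-independent", {
  cat_tbl <- toy_catalog(4, 300)
  cfg <- sim_config(read_length = 100, divergence = 0.1, coverage = 5, seed = 8)
  a <- simulate_dataset(cat_tbl, cfg)
  b <- simulate_dataset(cat_tbl[4:1, ], cfg)
  expect_equal(dplyr::arrange(a$reads, read_id), dplyr::arrange(b$reads, read_id))
})

test_that("observed substitution fraction calibrates to the divergence", {
  cat_tbl <- toy_catalog(3, 2000, seed = 77)
  cfg <- sim_config(read_length = 200, divergence = 0.05, coverage = 10, seed = 4)
  sim <- simulate_dataset(cat_tbl, cfg)
  idx <- match(sim$truth$origin_gene_id, cat_tbl$gene_id)
  orig <- substring(cat_tbl$sequence[idx], sim$truth$start + 1,
                    sim$truth$start + nchar(sim$reads$sequence))
  mism <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                 orig, sim$reads$sequence)
  total <- sum(nchar(sim$reads$sequence))
  obs <- sum(mism) / total
  # substitutions replace with one of the three other bases, so the observed
  # mismatch fraction is the divergence itself
  expect_equal(obs, 0.05, tolerance = 0.05)
})

test_that("synthesized catalogs are word-disjoint and paralogs plant ties", {
  cat_tbl <- synthesize_catalog(6, 500, seed = 42)
  kmers <- function(s) {
    n <- nchar(s) - 8
    c(substring(s, 1:n, 9:nchar(s)))
  }
  all_km <- lapply(cat_tbl$sequence, function(s) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    unique(c(kmers(s), kmers(rc)))
  })
  for (i in 1:5) for (j in (i + 1):6) {
    expect_length(intersect(all_km[[i]], all_km[[j]]), 0)
  }

  withp <- synthesize_catalog(4, 300, n_paralog_pairs = 1,
                              paralog_divergence = 0, seed = 42)
  expect_equal(nrow(withp), 5)
  expect_equal(withp$sequence[withp$gene_id == "gene001p"],
               withp$sequence[withp$gene_id == "gene001"])
})
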