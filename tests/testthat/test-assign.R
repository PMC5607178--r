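test_that("assignment thresholds are strict 70% bounds", {
  h <- tibble::tibble(
    query_coverage = c(0.69, 0.71, 1.00, 0.71),
    identity_fraction = c(0.99, 0.71, 0.70, 0.70)
  )
  kept <- passes_thresholds(h)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$query_coverage, 0.71)  # only the (0.71, 0.71) row
})

test_that("reads assign to their origin gene at zero divergence", {
  cat_tbl <- toy_catalog(5, 400, seed = 90)
  db <- reference_db(reference = cat_tbl)
  sim <- simulate_dataset(cat_tbl, sim_config(100, 0, 5, seed = 2))
  asn <- assign_reads(sim$reads, db)
  expect_equal(nrow(asn), nrow(sim$reads))  # every read assigned
  expect_false(any(asn$hit_multigene))
  joined <- dplyr::left_join(asn, sim$truth, by = "read_id")
  expect_true(all(joined$gene_ids == joined$origin_gene_id))
})

test_that("identical paralog copies produce multigene score ties", {
  cat_tbl <- synthesize_catalog(3, 400, n_paralog_pairs = 1,
                                paralog_divergence = 0, seed = 33)
  db <- reference_db(reference = cat_tbl)
  read <- substr(cat_tbl$sequence[cat_tbl$gene_id == "gene001"], 101, 200)
  a <- assign_read(read, db)
  expect_true(a$hit_multigene)
  expect_equal(a$gene_ids, "gene001;gene001p")
  expect_false(a$hit_multispecies)
})

test_that("the same gene in two references flags multispecies, not multigene", {
  cat_tbl <- toy_catalog(3, 400, seed = 91)
  db <- reference_db(speciesA = cat_tbl, speciesB = cat_tbl)
  read <- substr(cat_tbl$sequence[1], 51, 150)
  a <- assign_read(read, db)
  expect_false(a$hit_multigene)
  expect_true(a$hit_multispecies)
  expect_equal(a$gene_ids, cat_tbl$gene_id[1])
})

test_that("placeholder reads and unassignable reads contribute no rows", {
  four <- synthesize_catalog(4, 400, seed = 92)
  db <- reference_db(reference = four[1:3, ])
  reads <- dplyr::bind_rows(
    make_read("ok", substr(four$sequence[1], 1, 100)),
    make_read("ph", strrep("N", 50), rep(0, 50)),
    # gene 4 is word-disjoint from the three indexed genes by construction
    make_read("junk", substr(four$sequence[4], 1, 100))
  )
  asn <- assign_reads(reads, db)
  expect_equal(asn$read_id, "ok")
})

test_that("assignment count conservation holds across tie policies", {
  cat_tbl <- synthesize_catalog(4, 400, n_paralog_pairs = 1,
                                paralog_divergence = 0, seed = 34)
  sim <- simulate_dataset(cat_tbl, sim_config(100, 0.05, 5, seed = 6))
  db <- reference_db(reference = cat_tbl)
  asn <- assign_reads(sim$reads, db)
  counts <- count_assignments(asn, ties = "exclude")
  n_multi <- attr(counts, "n_multigene_reads")
  n_unassigned <- nrow(sim$reads) - nrow(asn)
  expect_equal(sum(counts$n_assigned) + n_multi + n_unassigned, nrow(sim$reads))

  dup <- count_assignments(asn, ties = "duplicate")
  # duplication tallies a tied read once per tied gene
  extra <- sum(lengths(strsplit(asn$gene_ids[asn$hit_multigene], ";")))
  expect_equal(sum(dup$n_assigned), sum(counts$n_assigned) + extra)
})

test_that("lowering thresholds never decreases assigned reads", {
  cat_tbl <- toy_catalog(4, 400, seed = 93)
  sim <- simulate_dataset(cat_tbl, sim_config(100, 0.25, 3, seed = 7))
  db <- reference_db(reference = cat_tbl)
  strict <- assign_reads(sim$reads, db, min_coverage = 0.70, min_identity = 0.70)
  loose_cov <- assign_reads(sim$reads, db, min_coverage = 0.50, min_identity = 0.70)
  loose_id <- assign_reads(sim$reads, db, min_coverage = 0.70, min_identity = 0.50)
  expect_gte(nrow(loose_cov), nrow(strict))
  expect_gte(nrow(loose_id), nrow(strict))
})

test_that("best-hit gene agrees with the exact Smith-Waterman oracle", {
  set.seed(27)
  p <- align_params()
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (rep in 1:25) {
    ns <- sample(2:6, 1)
    subj <- vapply(seq_len(ns),
                   function(i) random_dna(sample(100:400, 1)), "")
    src <- sample(ns, 1)
    st <- sample(nchar(subj[src]) - 80, 1)
    read <- inject_divergence(substr(subj[src], st, st + 79), 0.1)
    idx <- seed_index(tibble::tibble(seq_id = paste0("s", seq_len(ns)),
                                     sequence = subj), p)
    h <- local_align(read, idx, p)
    heuristic <- if (nrow(h) > 0) sort(unique(h$subject_id[h$score == max(h$score)]))
                 else character(0)
    osc <- vapply(subj, function(s) {
      max(sw_oracle(read, s, p)$score, sw_oracle(rc(read), s, p)$score)
    }, 0)
    oracle <- if (max(osc) > 0) sort(paste0("s", which(osc == max(osc))))
              else character(0)
    expect_identical(heuristic, oracle)
  }
})

test_that("assignment tables are deterministic", {
  cat_tbl <- toy_catalog(3, 300, seed = 94)
  sim <- simulate_dataset(cat_tbl, sim_config(100, 0.1, 3, seed = 9))
  db <- reference_db(reference = cat_tbl)
  expect_identical(assign_reads(sim$reads, db), assign_reads(sim$reads, db))
})
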