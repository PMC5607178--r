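# hand-built truth/assignment tables for the worked rate examples
worked_example_tables <- function() {
  truth <- tibble::tibble(
    read_id = sprintf("r%03d", 1:170),
    origin_gene_id = c(rep("geneG", 100), rep("geneX", 70))
  )
  assigned_ids <- c(sprintf("r%03d", 1:80),     # 80 of geneG's 100 reads
                    sprintf("r%03d", 101:170))  # 70 foreign captures
  assignments <- tibble::tibble(
    read_id = assigned_ids,
    gene_ids = "geneG",
    best_score = 100L,
    hit_multigene = FALSE,
    hit_multispecies = FALSE,
    n_hsps_considered = 1L
  )
  list(truth = truth, assignments = assignments)
}

test_that("recovery rate reproduces the 80/100 worked example", {
  tabs <- worked_example_tables()
  expect_equal(recovery_rate(tabs$truth, tabs$assignments, "geneG"), 0.8)
  expect_error(recovery_rate(tabs$truth, tabs$assignments, "absent"),
               "no simulated reads")
})

test_that("specificity rate reproduces the 80/150 worked example", {
  tabs <- worked_example_tables()
  sr <- specificity_rate(tabs$truth, tabs$assignments, "geneG")
  expect_equal(sr, 80 / 150)
  expect_equal(round(sr, 2), 0.53)
  # a gene with zero assigned reads has undefined specificity
  expect_true(is.na(specificity_rate(tabs$truth, tabs$assignments, "geneX")))
})

test_that("the five-way typology follows the (rr, sr) rules", {
  expect_equal(classify_gene(1, 1), "perfect")
  expect_equal(classify_gene(1, 0.9), "recipient")
  expect_equal(classify_gene(0.7, 1), "donor")
  expect_equal(classify_gene(0.7, 0.6), "mixed")
  expect_equal(classify_gene(0, NA), "undetectable")
  expect_equal(classify_gene(0, 0), "mixed")  # only foreign reads assigned
  expect_error(classify_gene(0, 0.5), "impossible")
})

test_that("per-gene evaluation partitions all truth genes into categories", {
  tabs <- worked_example_tables()
  ev <- evaluate_assignment(tabs$truth, tabs$assignments)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$gene_id, c("geneG", "geneX"))
  expect_equal(ev$category[ev$gene_id == "geneG"], "mixed")
  # geneX lost all its reads and captured none: rr = 0, sr undefined
  expect_equal(ev$category[ev$gene_id == "geneX"], "undetectable")
  expect_true(all(ev$n_correct <= ev$n_simulated))
  # sr undefined exactly for genes with zero assigned reads
  expect_equal(is.na(ev$sr), ev$n_assigned == 0)
})

test_that("multigene reads are excluded under the default tie policy", {
  truth <- tibble::tibble(read_id = c("r1", "r2"),
                          origin_gene_id = c("geneA", "geneA"))
  asn <- tibble::tibble(
    read_id = c("r1", "r2"),
    gene_ids = c("geneA", "geneA;geneB"),
    best_score = 10L,
    hit_multigene = c(FALSE, TRUE),
    hit_multispecies = FALSE, n_hsps_considered = 1L
  )
  excl <- evaluate_assignment(truth, asn, ties = "exclude")
  expect_equal(excl$rr[excl$gene_id == "geneA"], 0.5)
  dup <- evaluate_assignment(truth, asn, ties = "duplicate")
  expect_equal(dup$rr[dup$gene_id == "geneA"], 1)
})

test_that("completeness is the covered fraction of the reference", {
  expect_equal(completeness(c(0, 400), c(500, 800), 1000), 0.8)
  expect_equal(completeness(0, 1000, 1000), 1.0)
  expect_equal(completeness(c(0, 0), c(100, 100), 1000), 0.1)  # union idempotent
  expect_true(is.na(completeness(integer(0), integer(0), 1000)))
})

test_that("contiguity uses only the longest contig", {
  expect_equal(contiguity("c1", 600L, 0, 600, 1000), 0.6)
  expect_equal(contiguity("c1", 1000L, 0, 1000, 1000), 1.0)
  # longest contig selected by length; lexicographic tie-break
  ct <- contiguity(c("c2", "c1"), c(500L, 500L), c(0, 400), c(500, 900), 1000)
  expect_equal(ct, 0.5)  # c1 wins the tie, covers [400, 900)
})

test_that("contiguity never exceeds completeness", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    Lg <- 1000
    st <- sample(0:900, n, replace = TRUE)
    en <- pmin(st + sample(50:400, n, replace = TRUE), Lg)
    id <- sprintf("c%d", seq_len(n))
    len <- en - st
    cp <- completeness(st, en, Lg)
    ct <- contiguity(id, len, st, en, Lg)
    expect_lte(ct, cp)
    expect_lte(cp, 1)
    expect_gte(ct, 0)
  }
})

test_that("identified-gene count matches genes holding contigs", {
  contigs <- tibble::tibble(gene_id = c("a", "a", "b", "c"))
  expect_equal(count_identified_genes(contigs), 3)
  expect_equal(count_identified_genes(contigs[0, ]), 0)
})

test_that("category summaries partition genes within length bins", {
  ev <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    gene_length = rep(c(250, 750, 1250, 12000), each = 5),
    category = rep(c("perfect", "mixed", "perfect", "undetectable"), each = 5)
  )
  summ <- summarize_categories(ev)
  expect_equal(sum(summ$n), 20)
  props <- summ %>% dplyr::group_by(length_bin) %>%
    dplyr::summarise(p = sum(proportion))
  expect_true(all(abs(props$p - 1) < 1e-12))
})
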