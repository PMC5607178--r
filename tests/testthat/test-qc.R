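test_that("end trimming removes low-quality flanks in lockstep", {
  r <- make_read("r", "ACGTA", c(10, 12, 30, 30, 12))
  t <- trim_reads(r)
  expect_equal(t$sequence, "GT")  # positions 3-4 survive
  expect_equal(phred_scores(t$quality)[[1]], c(30, 30))

  clean <- make_read("r", "ACGT", rep(40, 4))
  expect_equal(trim_reads(clean)$sequence, "ACGT")

  hopeless <- make_read("r", "ACGT", rep(10, 4))
  expect_equal(trim_reads(hopeless)$sequence, "")
})

test_that("rejection applies the four rules with strict boundaries", {
  cfg <- qc_config()
  pass <- make_read("a", random_dna(100), rep(40, 100))
  expect_false(reject_reads(pass, cfg))

  one_low <- make_read("b", random_dna(100), c(4, rep(40, 99)))
  expect_true(reject_reads(one_low, cfg))

  short <- make_read("c", random_dna(29), rep(40, 29))
  expect_true(reject_reads(short, cfg))

  # boundary values all pass: one base exactly 5; exactly 10% below 13;
  # mean exactly 20; length exactly 30
  b5 <- make_read("d", random_dna(100), c(5, rep(40, 99)))
  expect_false(reject_reads(b5, cfg))
  frac10 <- make_read("e", random_dna(50),
                      c(rep(40, 20), rep(12, 5), rep(40, 25)))
  expect_false(reject_reads(frac10, cfg))
  mean20 <- make_read("f", random_dna(50), rep(20, 50))
  expect_false(reject_reads(mean20, cfg))
  len30 <- make_read("g", random_dna(30), rep(40, 30))
  expect_false(reject_reads(len30, cfg))

  # just over the fraction boundary fails
  frac12 <- make_read("h", random_dna(50), c(rep(40, 22), rep(12, 6), rep(40, 22)))
  expect_true(reject_reads(frac12, cfg))
})

test_that("pair filtering keeps parity with 50-N placeholders", {
  r1 <- dplyr::bind_rows(
    make_read("p1", random_dna(50), rep(40, 50), mate = "R1"),
    make_read("p2", random_dna(50), rep(40, 50), mate = "R1"),
    make_read("p3", random_dna(50), rep(15, 50), mate = "R1")  # mean < 20
  )
  r2 <- dplyr::bind_rows(
    make_read("p1", random_dna(50), rep(40, 50), mate = "R2"),
    # the sub-5 base sits interior so end-trimming cannot rescue the read
    make_read("p2", random_dna(50), c(rep(40, 25), 4, rep(40, 24)), mate = "R2"),
    make_read("p3", random_dna(50), rep(15, 50), mate = "R2")
  )
  out <- filter_pairs(r1, r2)
  expect_equal(nrow(out$r1), 3)
  expect_equal(nrow(out$r2), 3)
  expect_equal(out$r2$sequence[2], strrep("N", 50))
  expect_equal(phred_scores(out$r2$quality[2])[[1]], rep(0, 50))
  expect_equal(out$r1$sequence[1], r1$sequence[1])

  dropped <- drop_placeholder_pairs(out)
  expect_equal(dropped$r1$read_id, c("p1", "p2"))  # p3 fully placeholder
})

test_that("over-representation capping keeps first occurrences in order", {
  reads <- dplyr::bind_rows(
    make_read(paste0("dup", 1:5), "ACGTACGT"),
    make_read("uniq", "GGGGCCCC")
  )
  capped <- dedupe_overrepresented(reads, qc_config(dedupe_cap = 3))
  expect_equal(sum(capped$sequence == "ACGTACGT"), 3)
  expect_equal(capped$read_id[capped$sequence == "ACGTACGT"],
               paste0("dup", 1:3))
  expect_equal(dedupe_overrepresented(reads, qc_config()), reads)  # cap unset
  one_each <- dedupe_overrepresented(capped, qc_config(dedupe_cap = 1))
  expect_equal(nrow(one_each), 2)
})

test_that("pair merging needs an 8-base 90%-identity read-through overlap", {
  set.seed(31)
  frag <- random_dna(60)
  r1 <- make_read("m", substr(frag, 1, 40), rep(40, 40), mate = "R1")
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  r2 <- make_read("m", rc(substr(frag, 33, 60)), rep(30, 28), mate = "R2")
  merged <- merge_pair(r1, r2)
  expect_equal(merged$sequence, frag)
  expect_equal(nchar(merged$sequence), 40 + 28 - 8)

  # full read-through: r1 == revcomp(r2) merges to r1 itself
  full <- merge_pair(r1, make_read("m", rc(r1$sequence), rep(20, 40), mate = "R2"))
  expect_equal(full$sequence, r1$sequence)
  # merged qualities take the per-position maximum
  expect_equal(phred_scores(full$quality)[[1]], rep(40, 40))

  # a best overlap of 7 bases is below threshold
  r2_short <- make_read("m", rc(substr(frag, 34, 60)), rep(30, 27), mate = "R2")
  expect_null(merge_pair(r1, r2_short))
})

test_that("qc survivors never violate any rejection rule", {
  set.seed(12)
  reads <- purrr::map(1:40, function(i) {
    n <- sample(20:120, 1)
    make_read(sprintf("r%02d", i), random_dna(n),
              sample(0:45, n, replace = TRUE))
  }) %>% purrr::list_rbind()
  kept <- qc_reads(reads)
  if (nrow(kept) > 0) {
    expect_false(any(reject_reads(kept)))
    expect_true(all(nchar(kept$sequence) >= 30))
  }
  stats <- attr(kept, "qc_stats")
  expect_equal(stats$n_in, 40)
  expect_equal(stats$n_rejected + stats$n_kept, 40)
  # trimming never lengthens a read
  expect_true(all(nchar(trim_reads(reads)$sequence) <= nchar(reads$sequence)))
})
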