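# txguide

Transcriptome-guided read assignment, assembly and evaluation for non-model
species.

When no genome is available for a species, RNA-seq reads are usually either
assembled de novo or mapped to the transcriptome of a related model species.
Mapping breaks down once the focal species diverges substantially from the
reference (roughly beyond 15% sequence divergence), while purely de novo
assembly struggles with paralogs and fragmented transcripts. `txguide`
implements the alternative: assign each read to a *gene* by best
local-alignment hit against one or more reference transcriptomes (optionally
augmented with annotated de novo contigs), assemble the assigned reads gene
by gene, validate every contig by re-annotation, and quantify how well the
transcriptome was recovered. It is aimed at researchers benchmarking read
assignment under divergence and at pipeline authors who need a
self-contained, scriptable implementation of the guided approach.

## The method

**Assignment.** Reads are quality-filtered (end-trimming to Phred ≥ 13, then
rejection of reads with any base < 5, > 10% of bases < 13, mean Phred < 20,
or length < 30), and aligned with a seed-and-extend local aligner (exact
9-mer seeding, ungapped x-drop extension, banded affine-gap refinement;
match +2, mismatch −3, gap open 5, gap extend 2). An HSP supports assignment
only if it spans > 70% of the read at > 70% identity. The best score wins;
score ties across distinct gene ids are recorded as `hit_multigene`
(paralogy), ties on one gene id across reference sources as
`hit_multispecies` (orthology). Ties are recorded, not resolved.

**Per-gene assembly.** Assigned reads are binned by gene and assembled with
a greedy overlap-layout-consensus assembler (longest suffix–prefix overlap
first, majority-vote consensus). Every contig is re-annotated against the
reference; the annotation is authoritative — contigs are re-binned or
discarded accordingly, and minus-strand contigs are reverse-complemented.
Adapters for Trinity/Spades/CAP3 are provided for use when those binaries
are installed.

**Evaluation.** With simulated reads of known origin, each gene *g* gets

- recovery rate `rr = n_correct / n_simulated`,
- specificity rate `sr = n_correct / n_assigned` (undefined if nothing was
  assigned),
- a five-way typology: *perfect* (rr = 1, sr = 1), *recipient* (rr = 1,
  sr < 1), *donor* (rr < 1, sr = 1), *mixed* (rr < 1, sr < 1),
  *undetectable* (rr = 0, sr undefined),
- completeness `Cp_g = |∪_j C_gj ∩ L_g| / |L_g|` (fraction of the longest
  reference transcript covered by all aligned contigs) and contiguity
  `Ct_g = |C_gjmax ∩ L_g| / |L_g|` (covered by the longest contig alone),
- and overall the number of identified genes (NIG): genes with ≥ 1
  validated contig.

A built-in simulator tiles reads over every gene at uniform coverage
(default 10X; read lengths 100/150/200/350) and injects substitutions at a
controlled rate (0–30%) standing in for sequencing error, polymorphism and
species divergence. A catalog synthesizer generates word-disjoint gene sets
(no shared 9-mers between genes) so the ideal case is exactly attainable,
plus optional planted paralog pairs.

## Worked example

```r
library(txguide)

catalog <- synthesize_catalog(n_genes = 10, gene_length = 1000, seed = 42)
sim <- simulate_dataset(catalog,
                        sim_config(read_length = 100, divergence = 0,
                                   coverage = 10, seed = 42))
result <- run_guided_pipeline(sim$reads, catalog, truth = sim$truth)
result
#> [txguide:qc] reads in=1000 rejected=0 kept=1000
#> [txguide:assign] assigned=1000 multigene=0 unassigned=0
#> [txguide:assemble] contigs=10 discarded=0 identified_genes=10
#> <tx_pipeline_result>
#>   reads: 1000 in, 1000 kept, 1000 assigned (0 multigene)
#>   contigs: 10 validated; identified genes (NIG): 10

head(tidy(result$evaluation), 4)
#>   gene_id gene_length n_simulated n_assigned n_correct rr sr category Cp Ct
#> 1 gene001        1000         100        100       100  1  1  perfect  1  1
#> 2 gene002        1000         100        100       100  1  1  perfect  1  1
#> 3 gene003        1000         100        100       100  1  1  perfect  1  1
#> 4 gene004        1000         100        100       100  1  1  perfect  1  1
```

Every simulated read returns to its source gene (rr = sr = 1 for all ten
genes), each gene is reconstructed by a single full-length contig
(Cp = Ct = 1), and all ten genes are identified (NIG = 10) — the expected
outcome at zero divergence on a word-disjoint catalog. Increasing divergence
degrades recovery monotonically while specificity stays high:

```r
db <- reference_db(reference = catalog)
sweep <- purrr::map(c(0, 0.05, 0.15, 0.30), function(d) {
  s <- simulate_dataset(catalog, sim_config(100, d, 10, seed = 42))
  a <- assign_reads(s$reads, db)
  glance(evaluate_run(s$truth, a, catalog = catalog,
                      condition = list(divergence = d)))
}) |> purrr::list_rbind()
sweep[, c("divergence", "mean_rr", "mean_sr", "prop_perfect")]
#>   divergence mean_rr mean_sr prop_perfect
#> 1       0.00   1.000       1          1.0
#> 2       0.05   1.000       1          1.0
#> 3       0.15   0.998       1          0.8
#> 4       0.30   0.557       1          0.0
```

`autoplot(result$evaluation)` draws the typology by gene-length bin, and
`plot_divergence_sweep(sweep)` the recovery-vs-divergence curves.

A thin command-line driver ships in `inst/cli/txguide.R`
(`txguide.R simulate ...`, `txguide.R pipeline ...`) for shell use.

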