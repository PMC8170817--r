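# targetec

Instance-based substitution-error correction for Illumina-style short
reads around a single target gene.

Genome-wide error correctors pool k-mer statistics over an entire read
set; around a specific locus — a disease gene, a SNP site — that global
view is blunted by uneven coverage and repeats. `targetec` instead
extracts only the reads relevant to one gene, stacks them into a
position-sorted **alignment array** against the flank-extended gene
reference, and corrects conservatively from per-column base statistics.
It is aimed at researchers who need maximally accurate reads (and an
updated gene consensus) for one locus of a WGS sample, and at
methodologists who want a transparent, fully testable reference
implementation of alignment-array correction.

## Method in brief

* **Extraction.** The gene reference `I_g` is extended by 50 bp of
  genomic context on each side; every read (or its reverse complement)
  with an ungapped placement at ≥ 95% identity — at most 5 mismatches per
  100 bp, absorbing both sequencing errors and SNPs between the sample
  and the reference — joins `subset(S, I_g)`. External alignments can be
  imported from SAM instead (insertions dropped, deletions gap-filled).
* **Column dominance.** For each array column with base-type frequencies
  `f(X)`, the column is *dominated* by its `m` most frequent types if the
  remaining bases number ≤ 3 or make up ≤ 2% of a column with ≥ 100
  bases; the smallest admissible `m ∈ {1,2,3}` wins, otherwise the column
  is four-type and untouched.
* **Correction.** Minor bases in dominance-`m` columns get priority
  `p = 0.1 m` and score `f + p`. Per read, the lowest-scoring ≤ 2% of
  bases are treated as errors: corrected to the dominant base (one-type
  columns) or partitioned among dominant types proportionally to their
  frequencies with neighbour-column phasing (two/three-type columns). A
  read with more than one candidate scoring above 0.2 is labeled `'out'`
  as likely repeat contamination and removed. The conservative pass is
  iterated to a fixpoint, then the flank-trimmed consensus is emitted.
* **Evaluation.** Against a simulation truth log: precision
  `TP/(TP+FP)`, recall `TP/(TP+FN)` and **gain** `(TP−FP)/(TP+FN)` — the
  net fraction of errors removed without inducing new ones (negative when
  correction does net harm).

The bundled simulator generates a uniform-random genome with gene-sized
targets, an individual genome diverged by planted SNPs, and single- or
paired-end 100 bp reads with uniform substitution errors plus a complete
truth log.

## Worked example

```r
library(targetec)

cfg <- sim_config(genome_len = 60000, gene_lengths = c(5000, 8000),
                  coverage = 30, error_rate = 0.01, seed = 7)
report <- run_study(cfg)
report[, c("gene_id", "n_extracted", "n_out", "passes",
           "tp", "fp", "fn", "precision", "recall", "gain", "consensus_diff")]
#>   gene_id n_extracted n_out passes   tp fp fn precision recall gain consensus_diff
#> 1      g1        1519     0      4 1546  0  0       100    100  100              M
#> 2      g2        2407     1      4 2384  0  0       100    100  100              M

glance(report)
#> # A tibble: 1 × 4
#>   n_genes precision recall  gain
#>     <int>     <dbl>  <dbl> <dbl>
#> 1       2       100    100   100
```

Reading the output: 1,519 of the 18,000 simulated reads were relevant to
gene `g1`; over 4 passes all 1,546 injected errors in them were restored
to the true base (`tp`) with no new errors (`fp = 0`), and the corrected
consensus matches the individual's true gene sequence exactly (`"M"`) —
including the planted SNP alleles, which correction preserves because
column dominance follows the reads, not the reference. One `g2` read was
discarded as `'out'`. `autoplot(report)` draws the per-gene metrics;
`tidy()` on a `correct_reads()` object returns the per-base audit trail.

A thin command-line wrapper with `simulate`, `extract`, `correct`,
`evaluate` and `run` subcommands is installed at
`system.file("scripts", "targetec", package = "targetec")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes from scratch the across-gene average gain of the corrector on
the package's reference experiment — a 1 Mb genome with seven 5–60 kb
genes, 100 bp reads at 30× coverage, 1% substitution errors, SNP rate
0.001 — for single-end (`t1`) and paired-end (`t2`) layouts, and writes
the two values as JSON. Each value is produced by running the full
simulate → extract → correct → evaluate pipeline at the given seed.
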