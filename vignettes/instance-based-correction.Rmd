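---
title: "Instance-based error correction around a target gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-based error correction around a target gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetec)
```

## The problem

Whole-genome sequencing reads carry substitution errors at roughly 0.5–2%
per base. Genome-wide ("global") correctors pool k-mer statistics across
the entire read set, where non-uniform coverage and repeats blur the signal.
When the question concerns a *single gene* — a disease-associated locus, a
candidate SNP site — it pays to correct only the reads relevant to that
gene, using local statistics: extract the reads that map to the gene
reference, stack them by position, and let per-column base-type frequencies
decide what is an error. `targetec` implements this instance-based
workflow end to end, together with the standard precision/recall/gain
evaluation and a synthetic data generator that stands in for full-scale
chromosome simulations.

## Read extraction

The gene reference $I_g$ is not assumed error-free, and the individual's
true gene sequence $T_g$ differs from $I_g$ at SNP positions. Extraction
must therefore be noise-tolerant:

* `extend_reference()` appends 50 bp of genomic context to each end of
  $I_g$ (truncated at contig ends), so reads straddling the gene boundary
  are still collected.
* `extract_subset()` places each read — and its reverse complement — on the
  extended reference without gaps and keeps the best placement with at
  least 95% identity, i.e. at most 5 mismatches in a 100 bp read. The
  threshold tolerates sequencing errors and SNPs simultaneously
  (`min_identity_pct` is exposed).

Mapping is seed-and-verify: exact 31-mers sampled every 10 bases along the
read are looked up in a full k-mer index of the extended reference, and
every candidate diagonal is verified by a complete Hamming count. Two
numerical details matter:

* Sampled 31-mer seeds cannot *guarantee* a hit for a read with 5
  mismatches (three disjoint 31-mers fit in 100 bp, and adversarial error
  placement can cover every sampled window). Reads left unplaced by the
  31-mer pass therefore get a rescue pass with *disjoint* 16-mer seeds: a
  100 bp read has six of them, so five mismatches always leave one clean
  seed, making the extraction contract ("≤ 5 mismatches ⇒ extracted")
  deterministic rather than merely probable.
* Ties (equal identity) break toward the smallest offset, then the forward
  strand; the subset is sorted by offset, then read id. Every downstream
  step inherits this determinism.

Alignments produced by an external mapper can be imported instead via
`read_sam()`; CIGAR insertions are removed from the read and deletions are
recovered as gap cells `-`, which carry no base evidence. An ungapped
perfect alignment imports to exactly the placement the built-in mapper
finds.

## The alignment array and column dominance

`build_alignment_array()` stacks the extracted reads in rows, stably
sorted by start offset; columns index positions of the extended reference.
For a column, let $f(X)$ be the fraction of base type $X$ among its
non-gap cells. The column is *dominated* by its $m$ most frequent
non-N types when the remaining bases together number at most 3, or make up
at most 2% of a column with at least 100 bases. The smallest admissible
$m \in \{1,2,3\}$ wins (one-type dominance is preferred to two-type, and so
on); otherwise the column is four-type dominated and receives no
correction.

Two reading choices are deliberate:

* The 2% rule is **inclusive** (≤ 2%). The worked two-type example with
  minor frequencies 0.8% + 1.2% sums to exactly 2%, and under a strict
  reading it could never classify two-type at any depth at which those
  frequencies are realizable as integer counts. The inclusive reading
  makes all the canonical examples classify as printed; the count rule
  ("0, 1, 2 or 3") and depth rule ("100 or more") are inclusive by their
  own wording.
* `N` counts toward depth but never dominates, and a dominant type must
  have a positive count; a column of nothing but `N` is unclassifiable and
  left alone. Frequency ties rank in the fixed order A<C<G<T everywhere,
  so no classification depends on input order.

Both thresholds (`minor_count = 3`, `minor_frac = 0.02`,
`min_depth_for_frac = 100`) are exposed, as data characteristics vary.

## Conservative row correction

Minor-type cells in dominance-1/2/3 columns are the only correction
candidates. Each receives a priority $p$ of 0.1, 0.2 or 0.3 by its
column's dominance, and the score $f + p$: among equally rare bases, those
in simpler columns are corrected first, because a minor base in a one-type
column is almost surely an error while one in a three-type column may be a
repeat or haplotype signal.

`correct_rows()` then ranks each row's scored cells ascending by $f + p$
and takes at most the first 2% of the read length
(`ceiling(row_error_fraction * n)`, 2 cells for 100 bp) as that row's
error candidates — matching the Illumina per-read error budget. Before
changing anything, the row is screened for repeat contamination: if **more
than one** candidate scores above `out_threshold` (default 0.2), the read
is likely a repeat copy from elsewhere that consistently disagrees with
the gene, so it is labeled `'out'` and removed. The default 0.2 places the
boundary just above the score of a lone sequencing error in a well-covered
one-type column ($1/30 + 0.1 \approx 0.13$) and below any minor base of a
two/three-type column ($\ge 0.2 + f$); it is exposed because no canonical
value exists.

Corrections are applied dominance-1 columns first, then 2, then 3. In a
one-type column the candidate becomes the dominant base. In two/three-type
columns the candidates of each column are partitioned among the dominant
types in proportion to their renormalized frequencies
(`proportional_assignment()`, largest-remainder rounding). When the
candidate's own read carries a dominant base at a nearby (± 50 bp)
two/three-type column, the dominant type that co-occurs most often with
that neighbour base across reads is preferred first — a minimal phasing
rule that keeps haplotypes consistent. Residual ties are resolved by a
seeded shuffle; the seed is the only stochastic input of the whole
corrector, and byte-identical outputs under a fixed seed are asserted in
the test suite.

### Why the pass is iterated

A single pass can correct at most $\lceil 0.02 n \rceil$ bases per read
(2 in 100 bp). At a 1% per-base error rate a 100 bp read carries
Poisson(1) errors, so about 8% of reads have three or more — a single
capped pass leaves roughly $E[(k-2)^+] \approx 0.10$ of all errors
untouched and caps recall near 90%, far below what this family of
correctors demonstrably achieves. `correct_reads()` therefore iterates
the conservative pass to a fixpoint: after each pass the column profiles
are recomputed from the partially corrected array and the next pass again
corrects at most 2% per read. Convergence takes 3–5 passes at 1% error;
the per-pass budget (asserted in tests) is what keeps the procedure
conservative, not the total. A `max_passes` bound (20) guards degenerate
inputs.

After the loop, `consensus_sequence()` emits per column the most frequent
non-gap base among retained rows (the highest-frequency dominant type in
two/three-type columns), falls back to the reference base at zero-coverage
columns, and trims the flanks — giving the updated gene sequence, which
preserves planted SNP alleles because dominance follows the reads, not the
reference.

## Evaluation

Against a truth log of injected errors, each base of each evaluated read
scores: corrected error → TP; untouched error → FN; error rewritten to a
*different* wrong base → FN and FP (the error persists *and* a new wrong
base was written); clean base changed → FP; clean base untouched → TN.
Then precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$ and gain
$= (TP-FP)/(TP+FN)$, reported as percentages; gain is the net fraction of
errors removed without inducing new ones, and is negative when more errors
are introduced than removed. Zero denominators use fixed sentinels
(flagged in the output): precision 100 when nothing was changed, recall
and gain 100 when there was nothing to correct and nothing was broken,
gain `NA` when there were no errors but changes were made.

Reads removed as `'out'` are excluded from the tallies and counted
separately: they no longer exist in the corrected set, and scoring their
bases as FN would conflate read filtering with base correction. Note the
wrong-base rule means TP+FP+TN+FN can exceed the number of evaluated bases
by the number of wrong-base rewrites.

`compare_sequences()` renders the consensus-vs-truth comparison as `"M"`
for a perfect match or `"d/L"` (d differing bases out of L, overhang
counting as differences).

## The synthetic world

`sim_config()` defaults describe the package's reference experiment, a
scaled-down stand-in for chromosome-sized simulations:

| parameter | default | meaning |
|---|---|---|
| `genome_len` | 1 Mb | i.i.d. uniform A/C/G/T contig |
| `gene_lengths` | 5–60 kb, 7 genes | placed non-overlapping, ≥ 200 bp apart |
| `snp_rate` | 0.001 | individual-vs-reference divergence inside genes |
| `error_rate` | 0.01 | uniform per-base substitution rate |
| `read_len` | 100 | fixed read length |
| `coverage` | 30 | mean depth, uniform read starts, both strands |
| `layout` | single | or paired, insert ~ Normal(300, 30) truncated |

Reads are simulated from the *individual* genome (reference + SNPs) while
extraction uses the unmutated reference — exactly the mismatch budget the
95% identity threshold must absorb. Every injected substitution is logged
(`read_id`, 0-based position in the read, true and observed base), and
truth-log completeness (log entries ⇔ read/origin mismatches) is verified
exhaustively in tests.

What the generator deliberately does **not** model: position-dependent
quality decay and empirical quality profiles, GC bias, real repeat
structure (a `decoy_repeat` hook plants one controlled repeat to exercise
`'out'` labeling), and indel errors (a SAM import path handles externally
aligned indels, but the built-in mapper is ungapped). A green end-to-end
test therefore establishes that the dominance machinery corrects uniform
substitution errors at realistic depth and divergence — not that it
handles quality-correlated error bursts or segmental duplications.

## Known limitations

* Ungapped built-in mapping: reads with true indels only enter via SAM
  import, and indel *errors* are out of correction scope (insertions are
  dropped, deletions become evidence-free gap cells).
* One gene per run; overlapping genes are corrected independently.
* Columns where an error type reaches dominance (e.g. four errors of one
  type at depth 30) absorb those errors into the dominant set — a
  conservative miss, bounded by the binomial tail, visible as the last
  ~0.01% of recall in the reference experiment.
* The `'out'` screen can discard legitimate reads whose errors fall in
  shallow (flank-edge) columns, where a lone error's frequency is high;
  such reads are excluded from evaluation rather than miscorrected.
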