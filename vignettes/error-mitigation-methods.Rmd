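---
title: "Models and methods for sequencing-error assessment and mitigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for sequencing-error assessment and mitigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqem)
library(ape)
```

## The problem

Low-coverage genome assemblies (around 2x average read depth, as produced
for many mammalian genomes by capillary sequencing) contain sequencing
error — miscalled bases, spurious insertions and spurious deletions — at
rates of roughly 1–4 events per kilobase.  That is modest in absolute
terms, but it rivals or exceeds the rates of many evolutionary events of
interest, so comparative analyses that treat draft sequence as truth can
be badly misled: an apparently lineage-specific coding insertion is more
often an artifact than a mutation, and the multiple-of-three length
preference of coding indels is largely erased by error.

`seqem` provides three connected tool sets:

1. **Assessment** — tabulate draft-vs-reference differences by phred
   quality bin and separate sequencing error from polymorphism.
2. **A coverage–error model** — predict assembly quality from the average
   read depth and the single-read quality distribution.
3. **Mitigation** — mask likely miscalled bases and revert likely
   spurious lineage-specific indels in multiple alignments.

A truth-tracked generator (`sim_config()`, `simulate_assembly()`,
`simulate_alignment()`, `inject_errors()`) produces synthetic inputs with
exactly the statistical structure the methods assume, so every claim the
package makes is testable without external data.

## Quality scores and binning

Phred quality scores are carried in MAF alignments in a reduced
representation with a resolution of 5 phred units: bin $b$ covers raw
scores $[5b, 5b+5)$ and all scores $\ge 45$ share bin 9 ('F' marks
finished sequence and also decodes to bin 9).  A bin's representative
value is its lower bound $5b$, so a threshold like "q < 20" corresponds
exactly to bins 0–3.  Using the lower bound is the conservative choice: a
bin straddling a threshold is treated as low quality.  Raw scores not
divisible by 5 are floored into their bin.  The coverage model works on
raw (unbinned) scores; binning is purely an I/O concern.

## Error assessment and the polymorphism correction

With a draft assembly aligned to a high-quality ("comparative-grade")
reference for the same species, mismatches suggest miscalled bases, gaps
in the reference suggest insertion errors, and gaps in the draft suggest
deletion errors.  But the two sequences come from different individuals,
so observed differences mix error with genuine polymorphism.  Writing
$d_{esq}$ for the rate of differences of type $e$, species $s$ at quality
bin $q$, the rate at the highest-quality bases $d_{esQ}$ ($q \ge 45$,
where error is negligible) estimates the nucleotide diversity $\pi$
between the sequenced individuals, and the corrected error rate is

$$ r_{esq} = \max(d_{esq} - d_{esQ},\ 0). $$

Negative values arise only from sampling noise and are clamped with a
warning.  The same logic adjusts decision evaluation: when a fraction
$f = d_{esQ}/d_{esq}$ of observed differences in a stratum is expected to
be polymorphic, that expected count is moved from true positives to false
positives (and from false negatives to true negatives) in
`confusion_adjusted()`, so TPR/FPR/PPV refer to *error*, not to mere
difference.  Indel events are assigned the minimum binned score over the
inserted bases (insertions) and up to five draft bases on each side;
events longer than 10 bp are tracked in a separate "long" bucket.  Sites
with an N in either sequence are excluded from numerator and denominator
alike.

## The coverage–error model

The model links average coverage $\lambda$ to assembly quality under four
assumptions: (1) read depth is Poisson($\lambda$); (2) quality scores
accurately predict error rates; (3) scores are independent across the
reads covering a position; (4) an assembled base's score is the sum of
its reads' scores (as assemblers that multiply independent error
probabilities do).  With $p_1$ the single-read score distribution, the
depth-$x$ distribution $p_x$ is the $x$-fold convolution of $p_1$, and
the assembly-wide distribution is the mixture of the $p_x$ under the
Poisson weights *truncated to $x \ge 1$* — an assembly contains no
zero-coverage base.  Truncation and renormalization over $1..x_{\max}$
(default: the 0.999 Poisson quantile, at least 10) is a documented
modelling choice; widening $x_{\max}$ moves the expected quality by less
than 0.01 phred.  Quality sums are *not* capped at 50 inside the model —
the cap is an encoding convention, and capping would artificially
saturate the quality-vs-coverage trend.

The expected assembly quality is the phred transform of the expected
error probability,

$$ Q^*(\lambda) = -10 \log_{10} \sum_q P_\lambda(q)\, 10^{-q/10}, $$

a generalized f-mean dominated by the few low-quality bases.  The error
budget decomposes by depth: `error_fraction_by_depth()` reports the
fraction $F_1$ contributed by single-coverage bases and the fraction from
single-coverage bases below a cutoff (default q < 20).  With a realistic
heavy-lower-tail $p_1$, $F_1$ stays above 0.9 even at 15x — error remains
a story about read ends in single-coverage regions at any practical
coverage:

```{r f1}
p1 <- sim_p1_default()
quality_curve(p1, c(2, 6, 10, 15))
```

## The phylogenetic error score

Aligned bases from other species carry information about error: an
apparent substitution at a deeply conserved column is more likely to be
an error than the same substitution at a fast-evolving column.
`error_logodds()` quantifies this as a log-odds between a one-error model
and an errorless model.  The errorless likelihood is the Felsenstein
pruning likelihood of the column under a reversible substitution model
(Jukes–Cantor by default; GTR parameters and frequencies can be
supplied).  The error likelihood sums over alternative true bases $i$ for
the focal species $s$, replacing its observed base $x_s$ and weighting by
an empirical error transition matrix $M^{(s)}$ ($M_{ij}$ = probability
that true $i$ is written as $j$ given an error; zero diagonal, rows
normalized, uniform 1/3 fallback for unseen rows; estimated from
sub-bin-9 mismatch counts with training and test data kept separate).
At most one error per column is assumed.  Each model gets its own
branch-length scaling factor $\rho$, optimized deterministically
(`stats::optimize`, interval [0.01, 20], tolerance 1e-4), which lets the
score respond to column-specific conservation.  The score is a monotone
ranking statistic used as a regression covariate, so no normalizing
constant is applied.  Columns with no aligned partner return `NA` and the
caller falls back to quality-only masking.

## Base masking

The baseline strategy masks (sets to N) every base whose quality-bin
representative falls below a threshold $T$ (default 20).  Masking never
changes alignment geometry, coordinates, other rows, or the quality
string, so a decision log makes it reversible.  The optional classifier
is a logistic regression of the error indicator on covariates —
by default the local quality score and the phylogenetic log-odds, the
combination that performs best; local G+C and window quality summaries
are available but add little.  Polymorphism-weighted fractional labels
enter as a weighted likelihood (two-row expansion).  Fitting uses R's
`glm` (IRLS, gradient tolerance 1e-8, deterministic given input order);
perfect separation falls back to an in-package IRLS with a 1e-6 ridge.

## Indel imputation

Indel error is handled by *imputation* rather than masking.  An **indel
region** (IR) is a maximal run of alignment columns each containing at
least one gap, flanked by gapless columns (block edges count as flanks).
Only gaps of at most 10 bp are modelled as events; a species' longer gap
run becomes missing data ('?') rather than disqualifying the region, and
species absent from the block are likewise '?'.  Runs of identical
columns are compressed with multiplicities, giving a width-$n$ 0/1 matrix
with $2^n$ possible **indel states** per node; regions with $n > 10$ are
skipped.

Every indel event costs 1 regardless of length.  The state-transition
cost $w_{ij}$ is the minimum number of events turning state $i$ into
$j$, computed by breadth-first search where one move inserts or deletes a
run *contiguous among the 1-columns of the larger state* — so deleting
two bases separated only by ancestral gap columns is a single event
(101 to 010 costs 2, where naive column counting would give 3).  The
naive per-column metric remains available via
`event_cost_matrix(n, method = "columns")` for comparison.

`parsimony_states()` runs exact min-sum message passing (the min-sum
analogue of max-product) up and down the phylogeny and enumerates, at
every node, *all* states consistent with some minimum-cost labeling.
'?' leaves are unconstrained.  Because $W$ is symmetric the total cost is
invariant to rooting, and unrooted trees are rooted arbitrarily.  A leaf
showing a base in a compressed column where *every* optimal parent state
has a gap is a lineage-specific (LS) insertion; a leaf gap where every
optimal parent state has a base is an LS deletion (the unanimity rule).
Calls are made column by column, so overlapping events in different
lineages disentangle naturally, and only LS events are ever corrected —
shared indels would require multiple coinciding errors.

An LS call is corrected iff its quality (minimum over inserted bases and
five flanking bases per side) falls below the threshold (default 25):
spurious insertions are excised (all-gap columns are then dropped) and
spurious deletions are filled with N at quality bin 0 so downstream
tabulation ignores them.  Row sizes and the start coordinates of later
blocks on the same source are updated; the alignment is never recomputed.
Because correcting one species can change the region decomposition for
another, `impute_until_stable()` iterates detection and correction — in
practice one or two rounds — until no correctable call remains.

## The synthetic-data generator

The generator encodes the study conditions the methods assume, and its
defaults are fixed once:

* **Coverage** $\lambda = 2$, truncated-Poisson depth per base.
* **Single-read qualities** `sim_p1_default()`: 13.7% of single-read
  bases below q 20 (the low-quality read ends) and a single-read mean
  error of 8.6e-3; with this profile the model puts ~99% of error in
  single-coverage bases at 2x.
* **Basecall errors** at probability $10^{-q/10}$ of the (capped)
  assembled score, with a transition-biased substitution spectrum.
* **Indel errors** at 0.2 of the basecall rate each for insertions and
  deletions, placed proportionally to the basecall error probability —
  indel and basecall error share the quality dependence; lengths are
  short (1–3 bp).
* **Polymorphism** at $\pi$ = 5e-3, independent of quality, matching
  average mammalian nuclear diversity.
* **True indels** at substitution rate / 20, lengths up to 10 bp; in
  coding mode 90% of true indels have multiple-of-three lengths.

`simulate_alignment()` evolves sequences down a tree recording true
homology (no aligner is involved), `inject_errors()` creates the
low-coverage condition for designated rows, and every stochastic output
is reproducible from the seed and reversible from the truth table
(`revert_errors()`).

What the generator deliberately does **not** emulate: correlated
qualities along reads (each assembled base draws its depth and scores
independently), repeats and alignment error, non-Poisson depth from
cloning bias, and assembler-specific behaviour.  Two consequences matter
when reading test results.  First, green parameter-recovery tests show
the estimators are correct *under the stated assumptions*, not that real
assemblies satisfy them.  Second, a deletion error deletes its own
low-quality trigger base, and with independent flank qualities the
designed detection rate for deletion errors is markedly lower than for
insertion errors (whose low-quality bases remain in place); in real reads
the neighbours of a deletion are themselves low quality, so real-data
detection rates for deletions sit closer to the insertion case.

## Numerical and design choices

* Coordinates are 0-based half-open throughout (MAF/BED native).
* Non-ACGTN characters are mapped to N with a warning.
* `optimize()` tolerances: 1e-4 for the branch scaling factor; `glm`
  gradient tolerance 1e-8; convolution mass conserved to 1e-9.
* Degenerate inputs: empty threshold lists, empty exon sets, all-missing
  columns and single-class training labels raise errors; absent
  qualities on a draft row are an error for operations that need them.
* Overlapping contradictory imputation calls resolve first-wins with a
  warning and a log entry.
* Problem sizes in the shipped tests (up to 1e5 simulated bases, 12 kb
  alignments on six-leaf trees) were chosen so that three-standard-error
  recovery bands are tight enough to be meaningful while the whole suite
  runs in a few minutes.

## Worked example

```{r example}
tr <- read.tree(text = "(((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1):0.05,(E:0.2,F:0.2):0.05);")
cfg <- sim_config(seed = 42, genome_length = 2000, tree = tr)
sa <- simulate_alignment(cfg)
corrupt <- inject_errors(sa$block, "A", cfg)

calls <- find_ls_indels(corrupt$block, tr)
subset(calls, species == "A")

res <- impute_until_stable(structure(list(corrupt$block), class = "qmaf"),
                           tr, "A", T = 25)
table(res$log$action)
```

## Limitations

* Alignments are consumed, not constructed; imputation does not realign.
* Indels longer than 10 bp and regions wider than 10 compressed columns
  are never corrected.
* The bin-9 difference rate is the only polymorphism estimator offered;
  it can be biased where high-quality regions are unrepresentative.
* Cross-block gap bridging is not implemented; blocks are treated as
  flanked at their edges.
* Replacement bases for miscalls are never imputed — only weak
  information about their identity exists, so masking is the honest
  operation.
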