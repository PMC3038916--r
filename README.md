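# seqem — sequencing error assessment and mitigation

Low-coverage (~2x) genome assemblies carry sequencing error — miscalled
bases and spurious short indels — at 1–4 events per kilobase.  That rate
is comparable to within-species nucleotide diversity and far above the
rate of many evolutionary events of interest, so comparative and
phylogenomic analyses that take draft sequence at face value can be
badly skewed: an apparently lineage-specific coding indel in a 2x genome
is more often an artifact than a mutation.  `seqem` is for researchers
working with quality-annotated multiple alignments of draft genomes who
need to quantify that error and remove most of it before downstream
analysis.

The package implements three connected pieces:

* **Assessment.**  Differences between a draft and a high-quality
  reference sequence are tabulated by phred quality bin (resolution 5,
  scores >= 45 pooled).  The difference rate at the highest-quality
  bases estimates the polymorphism rate `d_Q` (the two sequences come
  from different individuals), and quality-specific error rates are
  corrected by subtraction: `r_q = max(d_q − d_Q, 0)`.  The same
  polymorphic fractions adjust TPR/FPR/PPV when masking decisions are
  scored (`tabulate_differences()`, `polymorphism_correct()`,
  `roc_sweep()`).

* **A coverage–error model.**  Under Poisson read depth with mean λ,
  independent per-read scores drawn from a single-read distribution
  `p1`, and assembled scores that sum across reads, the assembly-wide
  quality distribution is a truncated-Poisson mixture of convolutions
  of `p1`, and the expected quality is
  `Q*(λ) = −10·log10 Σ_q P_λ(q)·10^(−q/10)`.  The model decomposes the
  error budget by depth: the fraction `F1` contributed by
  single-coverage bases stays above 0.9 far beyond 2x
  (`coverage_model()`, `expected_quality()`,
  `error_fraction_by_depth()`, `quality_curve()`).

* **Mitigation.**  Bases below a quality threshold (default T = 20) are
  masked to N; optionally a logistic regression combines the quality
  score with a phylogenetic error log-odds — the likelihood ratio of a
  one-error model (error transition matrix `M`, Felsenstein pruning,
  per-model branch-scaling factor ρ) against substitution alone.
  Spurious lineage-specific indels are found by exact Sankoff parsimony
  over 2^n indel states per region with an event-based cost matrix
  (every contiguous insertion/deletion costs 1), and low-quality calls
  (default T = 25) are reverted to the ancestral state
  (`mask_by_threshold()`, `error_logodds()`, `find_ls_indels()`,
  `impute()`).

All inputs (quality-augmented MAF, BED, FASTQ, Newick) are read with
standard conventions, and a seeded synthetic-data generator
(`sim_config()` and friends) produces truth-tracked fixtures with the
statistical structure the methods assume, so the whole pipeline is
testable offline.

## Worked example

```r
library(seqem)
library(ape)

tr  <- read.tree(text = "(((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1):0.05,(E:0.2,F:0.2):0.05);")
cfg <- sim_config(seed = 42, genome_length = 2000, tree = tr)
truth   <- simulate_alignment(cfg)          # true homology, no aligner
corrupt <- inject_errors(truth$block, "A", cfg)  # make A a "2x" draft

calls <- find_ls_indels(corrupt$block, tr)
head(subset(calls, species == "A"))
#>    species block start_col end_col      type length bin eligible
#> 4        A     1        59      62  deletion      4   5     TRUE
#> 26       A     1       258     258 insertion      1   9     TRUE
#> 30       A     1       293     293 insertion      1   9     TRUE
#> 32       A     1       338     338  deletion      1   5     TRUE
#> 35       A     1       397     406 insertion     10   7     TRUE
#> 38       A     1       436     436  deletion      1   9     TRUE

res <- impute_until_stable(structure(list(corrupt$block), class = "qmaf"),
                           tr, "A", T = 25)
table(res$log$action)
#> excised  filled    kept
#>       2       5      25
```

Thirty-two lineage-specific indels were detected in the corrupted row;
seven were supported only by quality below 25 and were reverted (two
spurious insertions excised, five spurious deletions filled with N), and
the remaining twenty-five — mostly genuine indels simulated on A's
branch — were left untouched.  The numbers shown are from the code above
with the seed shown; rerunning reproduces them exactly.

The coverage model in two lines:

```r
quality_curve(sim_p1_default(), c(2, 6, 10, 15))
#>   lambda    Qstar        F1   F1_lowq    slope
#> 1      2 25.81462 0.9917182 0.9626298       NA
#> 2      6 38.96123 0.9752925 0.9466859 3.286650
#> 3     10 54.05134 0.9590508 0.9309205 3.772529
#> 4     15 73.91292 0.9390070 0.9114646 3.972316
#> (expected quality rises ~3-4 phred per added 1x; >90% of error stays
#>  in single-coverage bases even at 15x)
```

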