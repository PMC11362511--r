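# surftime

Quantitative analysis of TMT10plex time-course surfaceome labeling
experiments, for proteomics groups profiling how the extracellularly
exposed proteome of two genotypes changes over minutes of stimulation.
The package covers the full protein-level path from MaxQuant-style
reporter-intensity tables to genotype-comparison statistics, and ships a
synthetic-data generator with known ground truth so every stage can be
validated without any external download.

## The quantities it computes

**riBAQ-TMT.** For protein *i* in TMT set *s* with reporter intensities
*x*<sub>1</sub>…*x*<sub>10</sub> and intensity-based absolute
quantification value iBAQ<sub>is</sub>, the channels are rescaled so that

&nbsp;&nbsp;&nbsp;&nbsp;riBAQ<sub>ic</sub> = *x*<sub>ic</sub> · iBAQ<sub>is</sub> / Σ<sub>c</sub> *x*<sub>ic</sub>,

putting all channels of a protein on a common absolute (molar-amount
proxy) scale. Each labeled channel then has its paired non-labeled control
channel subtracted; a zero or negative net intensity means the protein is
not detected in that sample.

**Imputation and IRS.** Missing reporter entries are filled by seeded
chained-equations imputation on log-intensities (sibling-replicate
regression with a k-nearest-neighbour fallback), except where a protein
has no signal in any of the six samples of a condition — those entries
stay zero. Between-set batch effects are removed by internal reference
scaling: per protein, each set's channels are multiplied by *R*/*T*<sub>s</sub>,
where *T*<sub>s</sub> is the set total and *R* the geometric mean of the
totals (the pseudo-reference).

**Pattern classification.** Each protein's five-point mean time course
(0, 1, 5, 10, 30 min) is normalized to a probability vector *p* and
assigned the theoretical model profile *q* minimizing the Bhattacharyya
distance

&nbsp;&nbsp;&nbsp;&nbsp;D(p, q) = −ln Σ<sub>t</sub> √(p<sub>t</sub> q<sub>t</sub>),

then collapsed to a simplified `x-x-x-x` label whose four fields give the
direction of change over each consecutive interval (`d` down, `c`
constant, `u` up; 3⁴ = 81 possible labels, plus "not detected"). Model
profiles are generated over a fold-magnitude grid and filtered to span at
least 50% of their maximum, keeping the static model.

**Genotype comparison.** Pattern overlaps between genotypes are scored by
the enrichment factor E = (*n*·*N*)/(wt·ko) with one-sided Fisher exact
p-values (transition cells display when *n* ≥ 5 and *p* < 0.05);
per-pattern ID fractions are contrasted with riBAQ fractions
(prominence); resting-state differences use two-tailed Welch tests with
the |log₂FC| > 1 and *p* < 0.05 rule; samples are clustered by
single-linkage on 1 − Pearson *r*. Small utilities compute peroxidase
activity from kinetic traces (initial slope over the longest prefix with
Pearson *r* ≥ 0.998) and normalize western-blot densitometry.

## Worked example

```r
library(surftime)

cfg   <- sim_config(n_proteins = 300, seed = 7)   # 2 genotypes x 3 TMT sets
sim   <- generate_dataset(cfg)
ribaq <- quantify_ribaq(sim$matrix, seed = 7)     # impute, IRS, subtract
fit   <- classify_profiles(ribaq)                 # nearest-model patterns
summary(fit)
mean(fit$label == sim$truth$labels[cbind(fit$protein, fit$genotype)])
```

which prints

```
Most populated simplified patterns per genotype:

WT:
c-c-c-c u-c-c-u d-u-u-u c-c-c-u d-d-d-u c-c-u-u d-d-u-u u-d-d-d d-d-d-c d-d-c-c
    120      41      35      27      21      16      15      12       5       4
...
[1] 0.9468439
```

The static pattern dominates both genotypes, the early-up (`u-c-c-u`),
late-up (`c-c-c-u`) and down-then-recover (`d-u-u-u`, `d-d-d-u`) families
follow, and 94.7% of the simulated proteins recover their true label at
10% multiplicative noise. `transition_table()` then tabulates which WT
pattern moves to which KO pattern with its enrichment factor and Fisher
p-values, and `run_pipeline()` executes the whole chain from a YAML/JSON
config, writing every intermediate table plus a JSON manifest.

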