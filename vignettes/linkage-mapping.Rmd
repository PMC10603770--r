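---
title: "Error-aware linkage mapping for full-sib F1 families"
author: "fsmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-aware linkage mapping for full-sib F1 families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genotyping-by-sequencing (GBS/RADseq) delivers thousands of SNPs at low
and uneven depth. In an outcrossing F1 (full-sib) family -- two
heterozygous, unrelated parents and their progeny -- those genotypes are
the raw material for a linkage map, but at 10x mean depth a substantial
fraction of heterozygotes are called homozygous (a single sampled allele
looks homozygous) and vice versa. Distance estimators that trust the
calls convert every miscall into a phantom recombination event, and the
map inflates: a 38 cM chromosome segment can easily come out several
hundred cM long. `fsmapr` implements the standard remedy: propagate
genotype *uncertainty*, not genotype calls, into the multipoint model.

## Cross types and observable classes

With up to four parental haplotypes segregating, what a marker reveals
depends on the parental genotype configuration:

| code  | cross     | progeny classes     | segregation | informative for |
|-------|-----------|---------------------|-------------|-----------------|
| A.1   | ab x cd   | ac, ad, bc, bd      | 1:1:1:1     | both            |
| A.2   | ab x ac   | aa, ac, ab, bc      | 1:1:1:1     | both            |
| B3.7  | ab x ab   | aa, ab, bb          | 1:2:1       | both            |
| D1.10 | ab x aa   | aa, ab              | 1:1         | P1 only         |
| D2.15 | aa x ab   | aa, ab              | 1:1         | P2 only         |
| NONINF| aa x aa,... | --                | --          | none            |

Only B3.7/D1.10/D2.15/NONINF can arise from biallelic SNPs; the A types
cover fully informative (e.g. haplotype-derived) markers. Types
requiring null alleles or dominance are out of scope. Expected
segregation ratios are derived from the four equally likely
homolog-transmission combinations rather than hard-coded, which keeps
them correct for every supported type.

## The hidden Markov model

The latent state of a progeny individual at locus $m$ is the ordered
pair $(i, j)$: which of P1's two homologs and which of P2's it
inherited -- four states. Meioses in the two parents are independent and
interference-free, so the transition matrix for an interval with
recombination fraction $r$ is the Kronecker product
$M(r) \otimes M(r)$ with $M(r) = \begin{pmatrix}1-r & r\\ r &
1-r\end{pmatrix}$, one shared $r$ per interval for both parents.

The emission for state $(i,j)$ is the prior probability of the genotype
class formed by the allele on P1 homolog $i$ plus the allele on P2
homolog $j$, under the current phase assignment. Priors come from
`create_priors()` in one of four modes:

* **global_error** $e$: the called class receives $1-e$, the other
  $k-1$ classes share $e$ uniformly. The historical default $e=10^{-5}$
  is kept as the package default for reproducibility, but it is far too
  optimistic for low-depth sequencing; $e$ around 0.05 is a realistic
  choice at 10x.
* **genotype_error**: same spreading rule with each observation's own
  error probability, e.g. $10^{-\mathrm{GQ}/10}$.
* **genotype_probs**: caller-reported class probabilities (from PL or a
  genotype caller's posterior), restricted to the observable classes
  and renormalized. Whether upstream software normalizes over all three
  biallelic classes or only the observable ones is rarely documented;
  we renormalize over the observable set.
* **probs_plus_global**: the per-genotype error $1 - \max_c p_c$ is
  combined with a global rate on the complement scale,
  $e = 1 - (1-e_g)(1-e_s)$, and the result is spread as in
  `global_error`. The complement-scale product is the scalar rule; the
  vector rule (apply to the maximum-probability class, spread the rest
  uniformly) is our design choice, as is the uniform split of error
  mass over the $k-1$ non-called classes.

Missing observations emit the all-ones vector, leaving the likelihood
unaffected. Parental genotypes are treated as known after filtering:
erroneous parents must be removed upstream, because the model will
otherwise distort distances for every progeny at once.

## Estimation

`forward_backward()` runs the scaled forward-backward recursions
jointly over all progeny with a uniform (1/4) initial distribution.
`estimate_map()` wraps it in EM: the M-step for interval $t$ is the
expected number of homolog switches (each parent contributing one
countable meiosis) divided by $2N$. Numerical choices:

* estimates clamped to $[10^{-8}, 0.5 - 10^{-8}]$;
* convergence when $\max_t |\Delta r_t| < 10^{-5}$ *or* the
  log-likelihood gain drops below $10^{-6}$, capped at 100 iterations
  (a run that hits the cap is flagged `max_iter`);
* initial $r_t$ from the two-point EM of the flanking pair when
  defined, else 0.1;
* per-locus scaling constants guard against underflow; a genuinely
  zero-probability observation sequence raises an error naming the
  marker and progeny.

Near $r = 0.5$ the likelihood is nearly flat, so any stopping rule may
halt a few hundredths below the boundary; this is a property of the
likelihood, not of the optimizer. Intervals flanked by a D1.10 and a
D2.15 marker (no shared informative parent) are identified only through
more distant informative markers, and in tiny marker sets they can be
non-identifiable outright -- the reason two-point estimation flags
D1 x D2 pairs as `unlinked-types` and why our estimator-versus-oracle
checks use B3.7-only instances.

Distances come from Haldane's map function ($d = -50\ln(1-2r)$),
matching the interference-free simulator, or Kosambi's
($d = 25\ln\frac{1+2r}{1-2r}$) for empirical data.

### Phases

`infer_phases()` fixes the gauge (phase 0 at the first marker
heterozygous in each parent -- the likelihood is invariant under a
global relabeling of a parent's homologs) and proceeds left to right,
scoring each marker's at most four compatible phase codes. Re-running a
full EM on every prefix for every candidate would cost $O(M^2)$
forward-backward passes; instead the forward variables are cached and a
candidate is scored by the prefix likelihood with only the new
interval's $r$ optimized (1-D, earlier intervals at their running
estimates), ties resolved toward code 0.

The prefix score is flat across intervals that carry no prefix
information (entering a D2.15 marker from a D1.10 stretch, say), so the
scan alone can occasionally lock in a wrong phase -- and a single
mis-phased marker doubles the apparent recombination around it. The
scan is therefore followed by full-likelihood polish rounds: fit the
map by EM, score every marker's feasible phase flips by the exact
change in total log-likelihood (a single-site emission swap against
cached forward/backward variables, $O(4N)$ per flip), apply improving
flips, and repeat until stable. On error-free data the combination
recovers the simulated phases exactly (modulo the gauge flip) in every
test, including seeds where the greedy scan alone errs.

### Haplotypes and breakpoints

`decode_haplotypes()` runs per-progeny Viterbi decoding -- a single
consistent state path, unlike locus-wise posterior argmaxes, so
adjacent-state changes are countable as recombination breakpoints.
Breakpoint accounting against simulated truth is by *count*, not
position: per progeny per parental haplotype, $\max(\hat b - b, 0)$
overestimated and $\max(b - \hat b, 0)$ underestimated events.

## Filters

`apply_filters()` runs, in order: missing-data/MAF (defaults 25% and
5%), non-informative removal (both parents homozygous or a parental
call missing), impossible-genotype masking (a `bb` call under
`aa x ab` becomes missing), genotype-probability threshold (default
0.8), chi-square segregation test, redundancy bins. Choices worth
stating:

* the segregation chi-square uses no continuity correction, and the
  Bonferroni denominator is the number of markers *entering* the test
  -- earlier filters reduce the number of tests and hence relax the
  per-marker threshold;
* MAF is computed on progeny calls only; parents (often sequenced as
  replicated libraries) would bias allele counts;
* redundancy is exact call-vector identity including the missing
  pattern; near-duplicates are kept;
* `sanitize_allele_depths()` zeroes AD/DP wherever the genotype call is
  missing, so depth-based re-callers cannot reuse counts that the
  caller itself rejected; zero and missing AD are equivalent
  downstream.

## The simulator

`simulate_f1()` closes the loop without external data. Defaults encode
the reference study conditions: 810 markers over 8.426 Mb / 38 cM in
proportions 126 B3.7 : 263 D1.10 : 278 D2.15 : 143 non-informative, 200
progeny, mean depth 10 with parents 8x deeper. Components:

* physical-to-genetic interpolation by Hyman-filtered monotone cubic
  splines (`stats::splinefun(method = "hyman")`), linearly extended
  outside the anchor range with the boundary slope;
* meiosis as a Markov chain over homolog origin, switch probability
  $r_t$ per interval, no interference;
* optional selection-driven segregation distortion: oversample the
  family 50-fold, eliminate carriers of one allele at the 30th marker
  independently with probability 0.5 (Bernoulli per carrier -- a
  deterministic half would also be consistent with "eliminating 50%";
  the bookkeeping records what happened), then sample 200 survivors;
* depths: negative binomial totals (overdispersion $\rho$, default 0.2,
  chosen as a mid-range value typical of GBS library variation;
  $\rho \to 0$ recovers Poisson), beta-binomial reference counts for
  heterozygotes (allelic bias default 0.5), per-read error
  $10^{-3}$;
* `call_genotypes()`: naive binomial-likelihood calls with flat prior,
  producing GT/AD/GQ/PL exactly as a minimal caller would.

This is a *count-level* model: it does not simulate reads, PCR
duplicates, enzyme cut-site loss, alignment error, or 3'-biased error
profiles. Consequently it under-represents some correlated error modes
of real GBS data, and passing tests demonstrate correct behaviour of
the estimator under the modelled error processes -- not end-to-end
accuracy of any particular wet-lab pipeline. Read-level simulators
reportedly under-represent empirical error too, so the count-level
model exposes the same qualitative failure modes (map inflation under
optimistic error rates, allele dropout from depth sanitization) at a
fraction of the cost.

## Evaluation statistics

`map_summary()` reports length, gaps above 10 cM and outlier markers
(internal markers with >10 cM on both flanks). The Euclidean distance
between maps is computed on *cumulative* positions of the shared
markers after re-zeroing both maps at the first shared marker --
cumulative positions (not adjacent intervals) because the comparison
targets positional agreement along the chromosome, and re-zeroing so
that filtering differences at the chromosome start do not dominate.
Note one consequence: a uniform shift of all positions is invisible to
this statistic by construction. `order_correlation()` is the absolute
Spearman correlation between marker orders (ordering itself is out of
scope; orders are inputs).

## Problem sizes used by the test suite

Tests run at deliberately desk-scale sizes chosen to keep each
statistical check's power adequate: oracle comparisons at 2-3 markers
and 4-8 progeny against exhaustive path enumeration and a 1e-4 grid
search; map-length recovery at 200 markers x 200 progeny (a single
family of 200 realizes its 38 cM with a sampling SD near 2.4 cM, so
headline numbers average five replicate families); the map-inflation
contrast at 40 markers x 100 progeny with 10% injected miscalls; the
distortion mechanics on the full 50 x 200 oversampled pool. Empirical
sequencing datasets (hundreds of samples, full chromosomes) are not
bundled and their published maps are not reproduced here.

## Known limitations

* Sex-averaged distances only: one shared $r$ per interval.
* No marker ordering: maps are estimated at the genomic order.
* Parental genotypes enter as fixed values, not probabilities.
* The greedy phase search can in principle lock in an early wrong
  phase on extremely noisy, sparse data; inspecting the two-point
  `rf_matrix()` heatmap is the practical diagnostic.
* Contaminant individuals are not detected; they show up as outliers
  in the per-progeny breakpoint table and should be removed upstream.
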