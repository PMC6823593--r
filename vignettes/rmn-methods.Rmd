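---
title: "Rule-based microbial network inference: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based microbial network inference: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmnet)
```

## The interaction model

`rmnet` infers directed, signed ecological interactions among microbial taxa
(OTUs, genera, or sub-OTU oligotypes) from a taxa-by-samples table of relative
abundances.  The underlying idea is a *rule-based* one rather than a
correlational one: for every ordered triplet of distinct taxa
(*target* \(x\), *cooperator* \(y\), *competitor* \(z\)) we ask whether the
target's abundance behaves as it should if \(y\) promotes \(x\) and \(z\)
suppresses \(x\).

Abundance changes are first discretized.  For a pair of samples \((s, s')\)
and a taxon \(t\) with relative abundances \(a_t(s)\), the change is

* UP if \(a_t(s') - a_t(s) > \varepsilon\),
* DOWN if \(a_t(s) - a_t(s') > \varepsilon\),
* STEADY otherwise,

where \(\varepsilon \ge 0\) is the half-width of a steady band in fraction
units.  A sample pair is *predictive* for a triplet when the regulators move
in opposition: cooperator UP with competitor DOWN predicts the target UP, and
cooperator DOWN with competitor UP predicts the target DOWN.  On predictive
pairs, a matching target change is *support*; an opposite **or steady** target
change is a *contradiction*.  A prediction that fails to materialise is
evidence against the hypothesis, which is why STEADY targets are not ignored.
Non-predictive pairs carry no information about the triplet and are skipped.

Writing \(m\) for the number of predictive ("informative") pairs and \(u\),
\(v\) for support and contradiction counts (\(m = u + v\)), the conformity
score is

\[ S = \frac{u - v}{m} \in [-1, 1]. \]

A triplet is accepted when \(m \ge m_{\min}\) and \(S \ge s_{\min}\).  Each
accepted triplet contributes two directed edges: a cooperative edge
\(y \to x\) and a competitive edge \(z \to x\).  Parallel edges of equal sign
are merged; the merged weight is the maximum score among contributing
triplets and `n_triplets` records how many were merged.  An immediate
structural consequence -- useful as a self-check and enforced by
construction -- is that **a node can only receive a cooperative edge if it
also receives a competitive edge**: the model never explains a target without
naming both a promoter and a suppressor.  Reciprocal competitive edges
between two taxa ("mutual negative" pairs) and unreciprocated cooperative
edges are first-class queries (`mutual_negative_pairs()`,
`unilateral_positive_edges()`), since they are the patterns of most
ecological interest.

The published description of the rule model is qualitative; the concrete rule
table (opposing regulators predict the target's direction), the
\(\varepsilon\)-band discretization and the conformity score used here are
this package's reconstruction, kept deliberately minimal and fully
parameterised so that alternative rule tables can be swapped in.

### Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `theta_min` | minimum max-abundance for a taxon to enter the network and count as "present" at a site | fraction | 0.001 (0.1 %) |
| `epsilon` | steady-band half-width of the change classifier | fraction | 0.001 |
| `pair_mode` | `all_pairs` (cross-sectional) or `consecutive` (time series) | -- | `all_pairs` |
| `m_min` | minimum informative pairs per triplet | pairs | 3 |
| `s_min` | minimum conformity score | -- | 1.0 |

`theta_min = 0.001` reflects the common practice of ignoring taxa that never
reach 0.1 % relative abundance.  The default `s_min = 1.0` accepts only
triplets with *zero* contradictions -- the most literal reading of "conforms
to the model"; together with `m_min = 3` it keeps spurious acceptances on
unstructured data rare.  `all_pairs` is the default because spatially
collected samples have no natural order; `consecutive` retains the
algorithm's original longitudinal setting.  On data with measurement noise,
`s_min` rather than `epsilon` is the effective robustness knob (see the
benchmark section): a strict zero-contradiction rule rejects true
interactions as soon as noise flips occasional marginal pairs, so tolerating
a share of contradictions commensurate with the noise level (e.g.
`s_min = 0.9`) is the recommended relaxation.

### Degenerate inputs and determinism

Inference requires at least three taxa after filtering and at least two
samples; both are hard errors.  A constant matrix yields no informative pairs
and an empty network.  The pipeline contains no randomness: the same matrix
and parameters always produce byte-identical exports (edge rows are sorted by
source, target, sign).  Figure layout is the only seeded step, and it is
deterministic given `--seed`.

## Oligotyping

Sub-OTU entropy decomposition follows the classical recipe: compute the
Shannon entropy of every alignment column, pick the \(k\) highest-entropy
columns (default \(k = 2\), ties broken toward the leftmost column), and
label every read by its residues at those columns.  Entropy is reported in
bits; the base only rescales the values and cannot change the ranking that
selects the loci.  Entropy ranking is computed on all reads pooled across
samples.  Gaps (`-`) and ambiguity codes are ordinary characters in both the
entropy and the labels -- silently dropping them would desynchronise read
counts.  No minimum-abundance or sample-count filtering is applied to the
resulting oligotypes, and decomposition is a single pass: oligotypes are not
recursively re-decomposed, mirroring the practice of not resolving them to
purity for this highly diverse gene.  Reads map to samples either through an
explicit mapping file or by splitting identifiers at the last underscore
(`<sample>_<serial>`), the common amplicon convention.

## Alpha diversity

The estimator set mirrors a mothur summary, computed per sample from integer
counts \(n_i\) with \(N = \sum n_i\), \(n_1\) singletons and \(n_2\)
doubletons:

* observed richness \(S_{obs}\);
* Good's coverage \(\hat C = 1 - n_1 / N\);
* bias-corrected Chao1 \(S_{obs} + n_1 (n_1 - 1) / (2 (n_2 + 1))\);
* plug-in Shannon \(H = -\sum p_i \ln p_i\) (natural log, the mothur
  convention; evenness \(H / \ln S_{obs}\) is base-free);
* the Chao--Shen coverage-adjusted ("non-parametric") Shannon
  \(H_{np} = -\sum \hat C p_i \ln(\hat C p_i) / (1 - (1 - \hat C p_i)^N)\),
  which is the column usually labelled "Shannon diversity" in
  mothur-derived summaries; both estimators are exposed;
* the unbiased finite-sample inverse Simpson
  \(1 / \sum [n_i (n_i - 1)] / [N (N - 1)]\) rather than the plug-in
  \(1/\sum p_i^2\), again following mothur.

Undefined cases are reported as missing rather than errors: inverse Simpson
when every taxon is a singleton, evenness when \(S_{obs} = 1\), and the
coverage-adjusted Shannon when coverage is zero.  When \(n_1 = 0\) the
coverage-adjusted Shannon converges to the plug-in value (equal to within
\(10^{-9}\) for \(N = 1000\)).

Rarefaction (`rarefy()`) emulates "normalising to the lowest sequencing
outcome": each sample is subsampled *without replacement* to a common depth
(default: the smallest sample total) in one seeded draw, as mothur's
`sub.sample` does, rather than averaging over draws.  A taxon absent before
rarefaction can never appear after it.

## The synthetic benchmark

Real amplicon data for this kind of analysis require a full upstream
processing pipeline, so the package ships a generator whose statistical
structure matches what the rule model assumes, with a known ground truth.

A background community of the non-target taxa is drawn per sample from a
symmetric Dirichlet distribution (concentration 1 by default; smaller values
give sparser, more uneven communities).  For each planted triple
\((t, c, k)\) the target's raw abundance is the linear response

\[ t = b + \beta_{coop} \, C - \beta_{comp} \, K + \eta, \qquad
   \eta \sim \mathcal N(0, \sigma), \]

floored at \(10^{-6}\), after which every sample is renormalised to sum to
one.  The compositional closure this induces is deliberate: real
relative-abundance data are compositional.  The baseline \(b = 0.5\) keeps
the response positive for every possible regulator draw, so the floor is
inactive in noiseless data; the default plants a single triple among taxa
1--3 of an 8-taxon, 40-sample, two-region community.  Planted regulators may
not themselves be planted targets, which keeps the responses well-defined
without solving a simultaneous system.

### What the ground truth contains

Because samples are renormalised, a deterministic linear response carries an
exact algebraic consequence.  With background fractions summing to one, the
sample total is \(\Sigma = 1 + t\), and the observed (post-closure)
abundances obey

\[ K_{obs} \;=\; \frac{b/\Sigma + \beta_{coop}\, C_{obs} - t_{obs}}
                      {\beta_{comp}}. \]

Whenever a sample pair shows \(C_{obs}\) UP and \(t_{obs}\) DOWN, all three
terms on the right move upward, so \(K_{obs}\) is UP -- *exactly*.  In other
words, the mirrored triplet \((K;\, C;\, t)\) conforms to the rule model
wherever the planted \((t;\, C;\, K)\) does.  This is not an inference
artifact but a real deterministic dependency of the simulated data (the
compositional analogue of spurious correlation), so the truth network
returned by `generate_planted()` contains, per planted triple, both the
planted edges \(c \to t\) (cooperative), \(k \to t\) (competitive) and the
closure-implied mirror \(c \to k\) (cooperative), \(t \to k\) (competitive).
Note the pleasing consequence: every planted triple induces one
mutual-negative pair \(\{t, k\}\) in the truth -- the same motif that
motivates the method on real communities.  Scoring a correct inference
against the planted edges alone would systematically report precision 0.5.

### Recovery guarantees and calibration

On noiseless data the response is exact, so the recovery analysis uses
\(\varepsilon = 0\) (a steady band is a device for noisy measurements; with
exact data, sign classification is exact) and strict conformity
(`s_min = 1`).  Under these settings every informative pair of a true or
mirror triplet is a support by the monotonicity argument above, so planted
edges are recovered with precision = recall = 1 for any seed -- the test
suite checks seeds 1--20 and `scripts/acceptance.R` re-checks with an
arbitrary user-supplied seed.

For noisy runs the benchmark adds Gaussian noise with standard deviation
equal to 10 % of the response-term standard deviation under the default
parameters (\(\sigma = 0.1 \times 0.5\sqrt{2\,p(1-p)/8}\) with \(p = 1/7\),
i.e. \(\sigma \approx 0.0088\)).  Strict conformity collapses under any
noise -- a single flipped marginal pair among hundreds of informative pairs
rejects the whole triplet -- so the calibrated analysis keeps
\(\varepsilon = 0\) and relaxes the conformity threshold to `s_min = 0.9`,
tolerating a share of contradictions commensurate with the noise.  The mean
F1 achieved over seeds 1--20 at this calibration is recorded as a regression
baseline in the acceptance tests.

As a negative control, unstructured Dirichlet communities (8 taxa, 10
samples) are screened at the default strict parameters over 50 seeds; the
median accepted-edge count at first release is 0 and is asserted never to
increase.

### What the generator does *not* emulate

Sequencing-depth variation and count noise (reads are never simulated),
taxonomic or phylogenetic structure, generalised Lotka--Volterra dynamics,
time autocorrelation, and more than two regions.  Passing the benchmark shows
that the inference machinery is correct on data satisfying the model's
assumptions; it does not certify discovery performance on real communities,
where interactions are neither linear nor deterministic and compositional
closure couples *all* taxa, not just planted ones.

## Problem sizes used in the checks

The shipped verification uses deliberately small instances: oracle
equivalence on 100 random matrices of up to 6 taxa by 8 samples against a
brute-force enumerator; the structural rule on 100 inferred networks; the
recovery benchmark on 8 taxa by 40 samples over 20 seeds per noise level; and
the null screen on 8 taxa by 10 samples over 50 seeds.  These sizes exercise
every code path (the triplet enumeration is cubic in taxa, so 8 taxa already
cover 336 ordered triplets) while keeping the whole suite fast.

## Known limitations

* Edges carry conformity scores, not statistical significance; no permutation
  p-values are computed.
* The rule table is a sign pattern; fold-change magnitudes are not used.
* Site-presence annotation supports exactly two regions.
* `all_pairs` mode treats samples as exchangeable; spatial or temporal
  autocorrelation is ignored.
* The strict default `s_min = 1` is appropriate for screening and for exact
  data, but real noisy data will usually need `s_min < 1`, with the attendant
  risk of false edges as the threshold drops.
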