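---
title: "Methods: founder-haplotype eQTL mapping on synthetic mosaic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: founder-haplotype eQTL mapping on synthetic mosaic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices, and numerical
decisions behind `mosaiceqtl`, and what the synthetic-data tests do and
do not establish about real data.

# The mapping model

Each gene's log-scale abundance is modelled as

$$y_i = s_i\beta_s + gen_i\beta_{gen} + \sum_{j=1}^{7} g_{ij}\beta_j +
\gamma_i + \varepsilon_i,$$

with sex and generation as additive covariates, $g_{ij}$ the founder
haplotype probabilities at the tested marker, and
$\gamma \sim MVN(0, \sigma_g^2 K)$ a polygenic random effect. Only 7
founder columns enter the design: the probabilities sum to one, so the
eighth founder is the reference level absorbed by the intercept, and the
allele effects are re-centered to 8 display values afterwards. This is
the standard identifiability convention for multiparent haplotype
regression.

**Kinship.** $K_{ab} = \tfrac1M \sum_m \sum_j p_{amj}\,p_{bmj}$ is the
expected founder-allele sharing. Scans on chromosome $c$ use the
leave-one-chromosome-out matrix computed from all other chromosomes, so
the random effect cannot absorb the locus being tested.

**Fitting.** The kinship is eigendecomposed once per (trait,
chromosome); rotating by the eigenvectors makes the observations
independent with variances $h^2\lambda_k + (1-h^2)$, so every fit is
weighted least squares. $h^2$ is maximized by Brent's bounded scalar
search on $[0, 1-10^{-6}]$ of the profile likelihood — REML by default,
which is less biased at moderate $n$; both endpoints are also checked
because a boundary optimum can escape a bracketing line search. The
marker LOD is $\tfrac n2 \log_{10}(RSS_0/RSS_1)$ on the rotated,
weighted data with $h^2$ fixed at its null-model value — the usual scan
approximation that makes the genome scan one GLS fit per marker.

**Heritability scale.** Before fitting, $K$ is rescaled by
$\kappa = (\mathrm{tr}\,K - \mathbf{1}'K\mathbf{1}/n)/n$, the mean
diagonal of the centered kinship. This is a pure reparameterization
(the likelihood family $\{\sigma_g^2K + \sigma_e^2I\}$ is unchanged, so
LOD curves are identical), but it pins the meaning of $h^2$ to "fraction
of phenotypic variance carried by the polygenic term". Without it, the
probability-based $K$ has mean diagonal around 0.5 and $h^2$ would be on
an arbitrary scale roughly double the phenotypic fraction; with it, the
simulator's variance-fraction ground truth and the estimator agree
directly, which the recovery tests confirm (median estimate within
±0.05 of a true 0.4 over 200 genes).

**Peaks and cis/trans.** One peak per chromosome per gene — the marker
with the maximum LOD, kept only if strictly above the threshold
(default 7, so a LOD of exactly 7.0 is not a peak); ties break to the
smallest bp. A peak is cis iff on the gene's own chromosome and within
the TSS window, *inclusive* at exactly 2,000,000 bp — the boundary
convention is ours and is stated in every output header (all
coordinates 1-based bp).

**SNP association.** A strain distribution pattern assigns each founder
an allele (8-bit code; monomorphic codes rejected). Dosage is the
founder-probability vector, linearly interpolated in bp between flanking
markers, dotted with the allele vector; the test is the same GLS with a
single dosage column. Interpolation in bp is the simplest defensible
rule; nothing downstream depends on its details at marker positions
themselves.

**Mediation.** At a QTL peak, each candidate mediator is appended to the
covariates, the null model is refit — $h^2$ *re-estimated*, since a
mediator can absorb polygenic variance — and the drop from the baseline
LOD is recorded. Mediation is evaluated at the single peak marker (the
interactive click-the-peak usage), not as a genome re-scan; candidates
collinear with the covariates are flagged rather than fatal. An optional
bp-window filter restricts candidates to genes local to the peak; it is
off by default because pre-filtering is a reviewer's choice, not part of
the statistic.

# Preprocessing

Counts are summed transcript-to-gene, TMM-normalized (edgeR, default
30%/5% trims — the tool's published defaults, since only the tool is
specified by practice), and log-transformed as
$\log_2\!\big((c + 0.5)/(\text{lib}\cdot f + 1)\cdot 10^6\big)$ — the
voom logCPM without its precision weights, which the downstream
homoscedastic Gaussian scan does not consume. Contamination by a second
tissue is scored per sample as the log-mean of designated marker genes
and removed by per-gene OLS residualization (a config choice could
instead carry the score as a scan covariate; residualization is the
default because it also cleans the co-expression layer). Sex-chromosome
aneuploidies are flagged from X/Y expression scores as robust z-scores
within annotated sex (median/MAD, $k = 4$); $k$ is a decision, and the
pipeline's own ROC-style sweep shows flags decrease monotonically in
$k$. An X0 female (−1 log2 X dosage) is comfortably above threshold; a
partial-XXY X shift of $+\log_2 1.5 \approx 0.58$ sits near the
detection limit by construction — a genuinely subtle anomaly.

Sample mixups are resolved by Hungarian assignment maximizing total
Pearson correlation between expression-derived and array-derived
haplotype-probability fingerprints; ties prefer the annotated pairing
(a conservative $10^{-9}$ diagonal bonus), and assignments below
$r = 0.8$ are reported as low-correlation rather than silently trusted.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
study conditions used throughout the tests.

* **Genomes.** Two chromatids per chromosome, Poisson breakpoints at 30
  per Morgan per chromatid, uniform founder labels per segment. 30/Morgan
  reflects the accumulated historical recombination of a many-generation
  outbred stock (mosaic blocks of a few cM), not a pedigree model —
  block structure, not demographic fidelity, is what the scan cares
  about. cM and bp interconvert at a fixed 0.5 cM/Mb so maps are
  invertible. Reconstruction uncertainty is a blur toward the uniform
  simplex, $p \leftarrow (1-\alpha)p + \alpha/8$ (default
  $\alpha = 0.05$), the simplest perturbation preserving the simplex.
* **Expression.** The generative twin of the mapping model. The QTL,
  polygenic, and noise components are each rescaled to their exact
  requested variance shares, so recovery tests compare against realized
  truth; founder effects are mean-centered at simulation, matching the
  scan's identifiability convention.
* **Counts.** Negative binomial around library-size-scaled relative
  abundances (log-normal library sizes, mean $10^7$, CV 0.2, dispersion
  0.05 — ordinary bulk-RNA-seq territory); dispersion 0 degenerates to
  Poisson for limit checks.
* **Corruption.** Contamination scores are half-normal
  ($\lambda \sim |N(0, 0.5)|$) with a marker-gene loading of 10 log2
  units per unit score — marker genes of the contaminating tissue are
  essentially absent in the target tissue, so they move by several log2
  units even under mild contamination, which is what makes them usable
  as unambiguous scores (the generator is required to deliver
  score-truth correlation above 0.95). Aneuploidy shifts default to −1
  (X0) and $+\log_2 1.5$ (XXY) in log2 units; no published magnitudes
  exist, so these are placeholders, not estimates. Swaps are disjoint
  label transpositions recorded as ground truth.

**What passing these tests shows — and does not.** The generator
produces Gaussian latent expression with exactly realized variance
fractions, independent genes (except planted modules/chains), and
contamination/aneuploidy effects that are clean additive shifts. Real
data have correlated gene programs, mean–variance structure, batch
effects, and messier contamination. Passing here establishes the
*algorithms* (the estimators recover what was planted, the scan matches
its closed-form oracle, the assignment is provably optimal), not that
any particular real dataset will reach the same rates.

**Desk-scale genome caveat.** The test genome has 3 chromosomes. A
purely polygenic gene then carries a third of its genetic variance *per
chromosome*, which LOCO correctly excludes from the random effect — and
which therefore surfaces as detectable fixed-effect association. On a
real 20-chromosome genome the per-chromosome share is ~7× smaller. For
this reason type-I control is measured on genes with no genetic effect
at all; the leakage on few-chromosome synthetic genomes is a property of
the design, not a defect of the scan.

# Co-expression layer

**bicor.** $u_i = (x_i - \mathrm{med})/(9\,\mathrm{MAD})$ with the raw
(unscaled) median absolute deviation, Tukey biweights
$(1-u_i^2)^2$ for $|u_i| < 1$, and the cosine of the weighted centered
vectors. A variable with MAD 0 falls back to Pearson weighting for pairs
involving it (the hybrid fallback, logged); constant variables are NA
with a warning. The reference implementation's `maxPOutliers`
side-constraint is deliberately not implemented — plain bicor is what
is specified.

**Networks.** Signed adjacency $((1+r)/2)^\beta$; scale-free fit by
equal-width binning of connectivity, regressing log-frequency on
log-mean-k, signed as $-\mathrm{sign}(\text{slope})\cdot R^2$. The
selected power is the lowest candidate meeting the $R^2$ target
(default 0.9); a non-positive target is treated as vacuous (lowest
candidate wins). Modules come from average-linkage clustering of
$1-\mathrm{TOM}$ with a *static* cut (default height 0.99) and a
minimum size of 30 — an intentionally simple replacement for dynamic
tree cutting: the deliverable is the gene sets, and the cut height is
exposed for tuning. On planted 3×50-gene modules, power 12 at the
default cut recovers membership with ARI 1.0; lower powers under-split
because between-module TOM dissimilarity stays below the cut.

**Paraclique.** Unsigned thresholding ($|r| \ge 0.5$) builds the graph;
the seed is an exact maximum clique (igraph's Bron–Kerbosch, ties broken
to the lexicographically smallest vertex set for determinism), guarded
by a vertex bound because exact max-clique does not scale — pre-filter
the gene set rather than raising it. Accretion ("glomming") admits one
vertex per step: the outside vertex with the most member edges, provided
it reaches $\lceil (1-g)\,|P| \rceil$ of them (an alternative
missed-edge-count rule, $|P| - \lfloor g\,|P| \rfloor$, is behind a
flag; the two differ on rounding boundaries). Sequential admission was
chosen deliberately: it makes the density guarantee a theorem — each
admission contributes at least a $(1-g)$ fraction of its possible
edges, so every emitted paraclique has density $\ge 1-g$ — whereas
admitting whole rounds at once can co-admit mutually non-adjacent
vertices and provably break that bound (we observed density 0.71 under
a 0.75 bound on random graphs). Extraction is validated against an
exhaustive subset-enumeration oracle on 500 random graphs.

# Numerical and interface decisions

* Degenerate markers (identical probabilities across samples) scan to
  LOD 0 via rank-deficient least squares, and are listed in an
  attribute rather than raised as errors.
* A null model that already explains essentially all variance (e.g.
  conditioning a gene on itself) reports LOD 0 instead of a 0/0 ratio.
* All tabular outputs serialize doubles as `%.17g`, so write→read
  round-trips are bit-exact and the end-to-end pipeline is
  byte-deterministic under a fixed seed.
* Founder probabilities travel in a directory container — a JSON
  manifest, sample/marker index tables, and one samples ×
  (marker·founder) TSV per chromosome — an open hierarchical layout
  with plain-text serialization.
* The analysis bundle mirrors the layout interactive QTL viewers
  consume (genoprobs, LOCO kinship, map, markers, and a dataset block
  with annotations, covariates, expression, and the peak table);
  validation runs before writing and again on load.

# Problem sizes used by the test suite

Recovery experiments run at $n = 400$ samples on 3 chromosomes × 50
markers (2 Mb spacing): 100 cis genes at QTL variance 0.2 and $h^2$
0.4, 100 null genes, 200 genes per heritability level, 100 mediation
chains × 50 decoys, and a 384-sample mixup panel with 10 swaps. The
end-to-end determinism run uses a 96-sample, 60-gene configuration.
These sizes were chosen so each property is measured with comfortable
Monte-Carlo margin while the whole suite stays quick to run.

# Known limitations

* The X chromosome is scanned with the autosomal model; no
  X-specific dosage model is attempted.
* One peak per chromosome per gene; secondary same-chromosome peaks are
  out of scope.
* Static-height module cutting will merge adjacent modules that dynamic
  tree cutting would separate; raise the power or lower the cut height.
* The mosaic simulator is not a pedigree model: founder dosages are
  uniform by construction and no allele-frequency drift or sibship
  structure is generated beyond what the kinship captures.
* voom precision weights are intentionally not computed.
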