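---
title: "Methods and modeling choices in lncmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in lncmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmeth)
```

# Scope

`lncmeth` implements the analysis stages of a tumor-methylation study of ten
lncRNA genes in epithelial ovarian cancer — quantification of qPCR data,
cohort statistics, co-expression screening, complementarity alignment,
ceRNA triplet assembly, and survival/marker-panel analysis — together with a
synthetic cohort generator that produces inputs with the statistical
structure those stages assume. The generator is first-class, tested code:
it is how the package demonstrates that every stage recovers the effects it
is designed to detect, at nominal error rates, without access to patient
data.

# Quantification

## Relative expression (ΔΔCt)

For a target assay and reference assay measured in the same sample,

$$\Delta Ct = \overline{Ct}_\text{target} - \overline{Ct}_\text{reference},
\qquad
\Delta\Delta Ct = \Delta Ct_\text{case} - \Delta Ct_\text{calibrator},
\qquad
\text{fold} = 2^{-\Delta\Delta Ct}.$$

Replicates (conventionally triplicates) are aggregated by arithmetic mean of
Ct; a spread above 0.5 cycles within a (sample, assay) group flags the
triplet but does not exclude it — 0.5 cycles is a common qPCR QC tolerance.
The calibrator ΔCt is either the mean over a calibrator sample set or, in
paired mode, the matched normal of the same patient. Small-RNA assays use
two reference assays (RNU48 and RNU6); their contribution is combined by
averaging the reference Ct, a symmetric choice when no combination rule is
prescribed.

Fold changes below twofold are treated as retention: the classification is
`retained` when $|\Delta\Delta Ct| \le 1$ (boundary inclusive), `down` when
$\Delta\Delta Ct > 1$, and `up` when $\Delta\Delta Ct < -1$. The inclusive
boundary follows the usual reading of a "less than twofold" criterion
expressed through $\Delta\Delta Ct \le 1$.

## Relative methylation (qMSP, PMR)

Methylation-specific qPCR is quantified as percent of methylated reference
(PMR) against a fully methylated control DNA:

$$\mathrm{PMR} = 100 \times
2^{-\left[(Ct_\text{locus} - Ct_\text{ACTB})_\text{sample}
        - (Ct_\text{locus} - Ct_\text{ACTB})_\text{control}\right]}.$$

PMR is the standard quantity consistent with an assay design that names a
converted-ACTB normalization locus and a 100%-methylated control; the
package adopts it as an explicit design decision. Three degenerate-input
rules matter in practice:

* an undetermined Ct at the methylated-specific locus with a valid ACTB
  assay yields PMR = 0 ("below detection"), keeping the sample usable in
  group statistics rather than discarding it;
* PMR is capped at 150 to absorb amplification-efficiency noise, and capped
  values are flagged;
* amplification of the unconverted-ACTB control below 35 cycles marks
  incomplete bisulfite conversion; the sample is flagged
  (`conversion_ok = FALSE`) and excluded from downstream statistics by
  default.

# Cohort statistics

Two-group comparisons use the Mann–Whitney U test, two-sided, with midrank
ties: the exact null distribution (full enumeration) when
$n_1 + n_2 \le 20$ and there are no ties, and otherwise the normal
approximation with tie and continuity correction. Two-sidedness is a
deliberate choice: group differences are reported without a prespecified
direction. Significance tiers follow the usual figure-caption convention
(\*, \*\*, \*\*\*, # at p < 0.05, 0.01, 0.001, 0.0001) and are assigned on
raw p-values; Benjamini–Hochberg q-values are reported alongside, with one
family per comparison design across the ten genes — this matches per-figure
reporting granularity and is configurable.

Spearman correlation is computed as Pearson correlation of midranks, with
the two-sided p-value from the t-approximation
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ degrees of freedom. The
t-approximation is used at all n for consistency between small RT-qPCR
subsets and large screening matrices.

The binary "hypermethylated tumor" call, needed by the survival and panel
stages, is a threshold at the 95th percentile of the pooled normal-tissue
and donor PMR distribution per gene. No published cutoff exists for this
call, so the percentile is a first-class, configurable parameter; 95%
bounds the false-positive call rate in reference tissue at 5% by
construction.

The paired peritoneal-metastasis comparison restricts both groups to
patients contributing both a primary tumor and a PM sample and applies the
same Mann–Whitney test to the restricted groups; a signed-rank test is not
used because the rank-sum test is the package's single two-group procedure
and keeps tiers comparable across designs.

# Co-expression screening and gene-set intersection

Candidate partners of each lncRNA are screened by rank correlation at fixed
thresholds. The strict default for mRNA partners is $r_s > 0.4$ at
$p < 10^{-8}$; a relaxed variant ($r_s > 0.3$, $p < 10^{-3}$) is
appropriate for sparsely correlated lncRNAs, and the miRNA screen uses
$r_s < -0.6$ at $p < 0.0025$. All three are run-time configuration, not
constants, because published screens of this design vary the gates between
analyses; negative-direction mRNA screening is enabled per-lncRNA for the
same reason.

Intersections with EMT gene sets are exact symbol matches after uppercase
normalization, with percentages rounded to two significant figures
(round-half-to-even), the printed precision of intersection-report tables.
Gene sets are supplied as GMT files; nothing is fetched from a database at
run time.

# Complementarity alignment

Smith–Waterman local alignment is implemented from scratch (Rcpp kernel)
because the complementarity-site metrics are defined directly on its
output. Complementarity mode reverse-complements the subject and runs the
standard identity-mode dynamic program, so a "match" is a Watson–Crick
pair on the original strands; coordinates are mapped back to the input
strand.

Scoring defaults are match +2, mismatch −3, gap −5 (linear), wobble G:U
disabled, minimum site score 12, minimum site length 6, at most 25 sites
per pair. No published parameterization exists for this analysis, so the
defaults were chosen once such that planted biological-scale sites (tens of
complementary nucleotides) dominate the random background, which was
verified by null simulation: in random 500–2000-nt pairs the longest exact
complementary run stays below 15 nt in ≥ 99% of replicates, so a planted
32-nt site is unambiguous. A linear gap penalty is the simplest scheme
consistent with an unspecified protocol; affine gaps would add a parameter
the metrics cannot constrain. Wobble pairing is off by default because the
site metric counts nucleotide identity in DNA space; a wobble score can be
enabled, and wobble pairs then contribute score but are never counted as
matched nucleotides.

Sites are enumerated by iterative best-site extraction: accept the maximal
local alignment, mask its footprint on both sequences (masked positions
force the DP cell to zero, so no later alignment can cross them), and
repeat. The per-pair metrics are the summed count of matched (complementary)
nucleotides over all accepted sites — gaps and mismatches inside a site do
not count — and that count divided by the subject (mRNA) length. The full
transcript length is used as the denominator; restricting to the CDS would
require annotation the pipeline does not consume.

Traceback is deterministic: diagonal preferred over up over left, and among
equal-scoring end cells the smallest subject-position pair wins. This makes
site tables bit-reproducible across runs and platforms.

## miRNA seed sites

Seed-site classification scans the target 5'→3' for complements of miRNA
seed positions (miRNA numbered 5'→3'): 6mer pairs positions 2–7; 7mer-m8
pairs 2–8; 7mer-A1 is a 6mer with an A in the target opposite position 1;
8mer pairs 2–8 with that A. The "7mer-m8 g-bulged" variant is read as a
2–8 pairing with exactly one unpaired G bulged on the target side strictly
inside the seed span — the natural single-bulge reading of that label; this
is recorded as an assumption. The strongest type is reported per position
(8mer > 7mer-m8 > 7mer-A1 > 6mer > g-bulged, configurable), and weaker
sites overlapping an accepted stronger site are suppressed.

# ceRNA triplet assembly

A triplet (lncRNA, miRNA, mRNA) is a pure relational join of three screened
edge lists under the ceRNA sign pattern: lncRNA–miRNA negative
($r_s \le -0.3$, p < 0.05 by default), miRNA–mRNA negative
($r_s \le -0.4$), lncRNA–mRNA positive ($r_s \ge +0.3$). Sequence evidence
(a seed site of the triplet's miRNA on the lncRNA or mRNA) is attached when
available but only enforced on request: triplets of this construction are
hypotheses, and requiring site evidence by default would conflate two
evidence tiers. Output is ordered by the weakest edge ($\min |r_s|$),
descending, so the best-supported hypotheses rank first.

# Survival and the marker panel

Kaplan–Meier curves, the two-group log-rank test and Cox regression go
through the `survival` package (product-limit estimator; 1-df
observed-minus-expected chi-square; Breslow tie handling with
Newton–Raphson maximization). The package adds an independent stationarity
diagnostic: the Breslow partial-likelihood score vector is recomputed
directly at the returned optimum, and its norm must be below $10^{-6}$ for
the fit to be reported as converged. Separation and infinite-coefficient
diagnostics from the fitter are captured into the result rather than
emitted as loose warnings.

The six-gene metastasis panel predicts metastasis when at least k of the
six markers carry a hypermethylation call; k = 4 by default, matching a
"four of six panel markers" operating rule, and k is a first-class
parameter because the combination rule behind such panels is rarely pinned
down. The ROC is traced by sweeping k from 7 (predict none) to 0 (predict
all) — the count of methylated markers is the only ordinal score this
classifier has — and the AUC is the trapezoid over those discrete points.
Survival at a 120-month horizon is reported descriptively per stratum.

# The synthetic cohort generator

The generator encodes the study conditions as defaults: 140 primary tumors,
123 matched normals, 18 cancer-free donor tissues and 59 peritoneal
metastases paired to tumors of the same patients; the clinical composition
(histology, stage, extent, grade, metastasis-type and ascites frequencies)
follows the reference clinical table proportionally, with 76% serous
tumors.

Methylation is generated on a 0–100 PMR scale from beta distributions
(mean–concentration parameterization, concentration 12): normal and donor
tissue at mean 0.15; tumors shifted by +0.25 per gene; tumors of patients
with a given metastasis type shifted a further +0.10 for the genes
associated with that type (lymphatic: HAND2-AS1; peritoneal: KCNK15-AS1,
MEG3, SEMA3B-AS1; omental: MEG3, SEMA3B-AS1, ZNF667-AS1); and PM samples
shifted −0.15 for the five reversal genes (MEG3, SEMA3B-AS1, SSTR5-AS1,
ZEB1-AS1, ZNF667-AS1). The beta form is an assumption — the distributional
family of PMR measurements is not published — chosen because PMR is a
bounded, right-skewed quantity and beta marginals make planted mean shifts
interpretable.

Expression is log2-scale:
$\mathrm{expr} = 2 - s_g \cdot m + \varepsilon$, with methylation
proportion $m$, per-gene slope $s_g = 3.5$ (GAS5: 1.5) and Gaussian noise
(sd 0.5 log2 units). These values realize Spearman correlations of about
−0.5 to −0.8 for nine genes and about −0.4 for GAS5 at n = 140 — the range
the analysis is designed to detect. Optional raw Ct tables are emitted that
back-compute through the quantification module to exactly the planted
values (relative error < 1e−9), closing the loop between generator and
quantifier.

Survival is exponential with per-patient hazard
$\lambda = \lambda_0 \prod_g \mathrm{HR}_g^{[\text{call}_g]}$, baseline
$\lambda_0 = 0.0007$ per month, HR 2.2 for the three survival marker genes
(SEMA3B-AS1, SSTR5-AS1, ZNF667-AS1) and 1 otherwise, with censoring times
uniform over a 180-month horizon (staggered accrual). The baseline was
calibrated once so that roughly a quarter of patients experience an event
under the default call rates, matching a cohort in which most patients are
alive at analysis; it was fixed before the test suite was finalized. The
exponential/uniform pair is the simplest model under which the KM, log-rank
and Cox stages have recoverable ground truth.

Metastasis patterns are drawn by first selecting the any-metastasis set
(96/140) and then assigning type flags conditionally (lymphatic 30/96,
peritoneal 70/96, omental 70/96, distant 15/96, with at least one type
guaranteed). This reproduces the marginal frequencies of the reference
table; the conditional independence of types within a metastatic patient is
a simplification — real peritoneal and omental involvement are strongly
coupled.

## What the generator does not emulate

Passing the suite demonstrates internal correctness — planted effects are
recovered, null effects are not — but not robustness to features of real
data the generator omits: plate and batch effects in Ct values,
amplification-efficiency differences between assays, non-beta PMR
distributions, missing clinical covariates, dependence between methylation
of different genes beyond the shared clinical drivers, sequence composition
bias and RNA secondary structure (alignment backgrounds are uniform
i.i.d.), and cohort selection effects.

# Numerical choices and problem sizes

* Alignment oracle checks enumerate all alignments recursively at lengths
  ≤ 6, compare against an independent substring Needleman–Wunsch oracle at
  lengths ≤ 12, and against an independent alignment library on 200 random
  pairs at lengths ≤ 30 — sizes at which exhaustive verification is
  tractable while covering every DP move.
* Rank-test oracles enumerate all group assignments at $n_1 + n_2 \le 12$.
* Type-I calibration uses 200 null cohorts of 30 + 30 samples (2000 tests)
  for the Mann–Whitney stage and 200 null survival datasets for the
  log-rank stage, with acceptance bands at the binomial 95% interval
  around 0.05.
* Hazard-ratio recovery uses 100 replicates at n = 1000 with censoring
  uniform over twice the mean event time, which leaves roughly 80% of
  subjects with observed events and gives the Cox estimate a standard error
  small enough that a [1.7, 2.3] bracket around HR = 2 is a sharp check.
* Seeds: every simulation consumes an explicit integer seed; the pipeline
  fans a single global seed out to per-stage sub-seeds through a fixed
  affine map, so stages re-run in isolation reproduce exactly.

# Known limitations

The screening stage is quadratic in the number of candidate partners (one
rank correlation per pair) and is intended for the focused matrices of this
design, not transcriptome-wide scans. The alignment kernel allocates the
full DP matrix and is sized for transcript pairs up to a few kilobases.
The panel is evaluated on the cohort that defines it — no held-out
validation is modeled, so panel metrics are resubstitution estimates, as in
the study design it mirrors. PMR values above 100 (up to the cap) are kept
as-is; no efficiency correction is attempted.
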