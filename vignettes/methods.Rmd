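---
title: "Methods: tumor-only somatic variant calling in lumoscall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-only somatic variant calling in lumoscall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumoscall)
```

Calling somatic variants without a matched normal sample requires separating
three confounded signals at every candidate site: sequencing/mapping
artifacts, private germline variants absent from population databases, and
true somatic mutations whose allele fractions are shifted by tumor purity and
copy-number state. `lumoscall` addresses this with a four-step pipeline.

## Step 1: position reliability from unmatched controls

Each position observed in a panel of unmatched control samples is scored by
the posterior probability that it is *unreliable*. Four states explain a
control's B-allele counts $(R_B, R_T)$:

* homozygous reference — B reads are base-call errors:
  $P(D \mid G_{AA}) = \mathrm{Binom}(R_B; R_T, 10^{-Q_B^b/10})$
* heterozygous — $P(D \mid G_{AB}) = \mathrm{Binom}(R_B; R_T, 0.5)$
* homozygous alternate — A reads are base-call errors:
  $P(D \mid G_{BB}) = \mathrm{Binom}(R_A; R_T, 10^{-Q_B^a/10})$
* unreliable — a flat likelihood $10^{-\min(Q_M^a, Q_M^b)/10}$ set by the
  worse mean mapping quality.

Genotype priors follow Hardy–Weinberg from the population allele frequency
$F_B$ ($F_A^2$, $2 F_A F_B$, $F_B^2$), plus a constant unreliable prior
$\pi_U = 0.05$. The per-position score is the Phred transform
$-10 \log_{10} \overline{P(U \mid D)}$ of the mean posterior across controls,
capped at 250 (a perfectly diploid panel would otherwise yield
$-\log 0$) and floored at 0. The hom-alternate state matters in practice: a
control that happens to carry B/B at a common SNP is a perfectly ordinary
diploid genotype, and without that state it would be absorbed by the
unreliable component and poison the position for every tumor analyzed
against the panel.

```{r panel-example}
ctl <- data.frame(
  chrom = "chr1", pos = 100L, ref = "A", alt = "T",
  r_t = 100, r_a = 50, r_b = 50, qb_a = 30, qb_b = 30,
  qm_a = 60, qm_b = 60, strand_b_fwd = 25, strand_b_rev = 25,
  is_indel = 0, softclip_frac = 0, low_mapq_frac = 0, homopolymer = 0
)
exons <- data.frame(chrom = "chr1", start = 0L, end = 1000L,
                    control_1 = 100, control_2 = 100)
panel <- build_panel(list(ctl, ctl), exons)
panel$positions
```

## Step 2: semi-supervised site quality

Sixteen per-site metrics (depth, B-allele fraction, base/mapping qualities
and their A/B differences, strand balance, soft-clip and low-mapping-quality
fractions, homopolymer context, the panel Phred score, ...) feed a quadratic
discriminant model trained without hand labels. Training labels come from
conservative threshold rules: a site is labeled `PASS` only if *all*
pass-thresholds hold, `REJECT` if *any* reject-threshold trips, otherwise it
is unlabeled. Two models are fit:

* a **strict** model (`PASS` vs `REJECT`) giving $P_T$, the probability the
  site is a trustworthy position, and
* a **lenient** model (`VARIANT` = `PASS` + unlabeled, vs `REJECT`) giving
  $P_V$.

Sites with $P_T > 0.99$ form the *high-confidence* tier used to train the
copy-number model; sites with only $P_V > 0.99$ form a *low-confidence* tier
that is still genotyped; the rest are rejected as artifacts. Covariances are
ridge-regularized (with a warning) when a training class is too small to
support a full 16-dimensional covariance.

## Step 3: allele-specific copy number and clonal fractions

Exon-level $\log_2$ tumor/control depth ratios are segmented by circular
binary segmentation. The most significant candidate split within a segment
is accepted when its two-sample $t$-like statistic exceeds a Bonferroni-style
normal bound at level `alpha_seg` (an analytic stand-in for the usual
permutation reference, which keeps the procedure deterministic), subject to
a minimum segment width of 5 exons.

Each segment is then assigned a clone $i$ with sample fraction $f_i$ and an
allele-specific copy state $(N, M)$ (total and minor copy number) by
maximizing a joint objective combining:

* a Poisson likelihood for each exon's tumor depth around
  $\hat{R} = R_{Cn} \, (fN + 2(1 - f)) / C$, where $R_{Cn}$ is the control
  depth and $C$ a per-clone centering constant;
* a beta-binomial likelihood for each high-confidence heterozygous variant's
  B-allele counts around the expected het allele fraction
  $\phi^G = fM/N + (1 - f)/2$;
* a beta-binomial likelihood for somatic candidates around
  $\phi^S = f(N - M)\,/\,(fN + 2(1 - f))$;
* categorical priors on $N$ and $M$ and a Beta prior (mode `f_pi`, shape
  `alpha_pi`) on each $f$.

The continuous parameters ($f_i$, over-dispersions $W_i$, centering $C$) are
fit by coordinate ascent (EM-style alternation with `optimize`), restarted
from three deterministic initializations; copy states are re-derived each
iteration by inverting the expected-depth and expected-het-AF relations:
$N = \max(\mathrm{round}((C \rho - 2(1 - f))/f), 0)$ from the mean segment
ratio $\rho$, and $M = \mathrm{round}(N(\bar{\phi} - (1 - f)/2)\,f^{-1})$
from the mean het allele fraction, clamped to $0 \le M \le N \le 8$ and
folded to the minor allele.

Two numerical choices deserve note. First, heterozygous B-allele counts are
*not* folded to the minor allele inside the likelihood; instead the het
likelihood is an equal-weight mixture over the two phases,
$\tfrac12 \mathrm{BB}(R_B; W\phi, W(1-\phi)) +
 \tfrac12 \mathrm{BB}(R_B; W(1-\phi), W\phi)$.
Folding biases the diploid BAF mean below 0.5 (the expectation of
$\min(X, n - X)/n$ is about 0.467 at typical depths) and creates a spurious
EM optimum in multi-clone fits; the phase mixture is exact and reduces to
the plain form at $\phi = 0.5$. Second, the objective is normalized by an
effective term count so segments with many exons do not drown the allele
fraction evidence.

```{r em-example, warning = FALSE}
sp <- data.frame(n_exons = c(120L, 60L), N = c(2L, 1L), M = c(1L, 0L),
                 clone = c(0L, 1L))
coh <- synthesize_cohort(fractions = 0.6, segments_spec = sp,
                         n_artifacts = 0, seed = 2)
ex <- coh$tumor_exons
ex$depth_control <- rowMeans(
  coh$exon_depths[, grep("^control", names(coh$exon_depths))])
hets <- coh$tumor[grepl("germline_het", coh$truth$class), ]
cfg <- default_config(); cfg$K <- 1L
fit <- fit_clone_model(ex, hets, config = cfg)
fit$model$f           # recovered sample fraction (truth: 0.6)
fit$segments[, c("clone", "f", "N", "M", "n_exons")]
```

## Step 4: Bayesian genotype posteriors

Every candidate site is scored under four models — somatic ($S$), germline
heterozygous ($G_{AB}$), germline homozygous ($G_{AA}$), other ($O$) — using
beta-binomial likelihoods at the copy-state-adjusted expected allele
fractions of its segment's clone. For somatic variants the expected fraction
is evaluated per clone (taking the best clone), including variants private
to a minor clone. Priors combine the somatic rate $\rho$ scaled by the
database recurrence count $\omega$, $\pi_S = \rho(\omega + 1)$, with
Hardy–Weinberg germline priors scaled by $(1 - \pi_S)$; alleles at database
frequency above `F_max_somatic` are never called somatic. Steps 3 and 4
alternate — posterior calls re-select the heterozygous and somatic training
sets for the copy-number fit — until the set memberships stabilize (at most
10 iterations).

The key protection against miscalling private germline variants as somatic
is structural: an unseen allele still carries the germline prior mass of the
population floor frequency (`F_p_snv` $= 7.14 \times 10^{-5}$), and at
ordinary depths a het allele fraction is far better explained by $G_{AB}$
than by a purity-shifted somatic fraction.

## Power simulation and synthetic cohorts

`power_grid()` estimates detection power (posterior $P(S \mid D) \ge 0.8$)
on a grid of coverage, tumor fraction, and copy state. Depths are drawn from
a mean-anchored lognormal with `sigma_log = 1` — heavier-tailed than a
Poisson, matching the exome-capture depth dispersion regime the defaults
target — and B-allele counts are binomial at the true $\phi^S$. Evaluation
assumes the copy model is known (one clone at the true $f$, $N$, $M$) with
the over-dispersion at its upper bound $W = 10^4$, i.e. effectively binomial
likelihoods, so the grid isolates the counting-statistics limit of
detection. `synthesize_cohort()` generates a full multi-clone dataset —
tumor counts, unmatched controls, exon depths, a priors table, and a truth
table — for end-to-end testing.

```{r power-example}
power_grid(c(100, 400), 0.5, list(c(2, 1)), n = 200, seed = 1)
```

## Problem sizes and limitations

The implementation targets exome-scale inputs: thousands of exons, tens of
thousands of panel positions, and thousands of candidate sites per tumor.
EM fits with $K \le 3$ clones on a few hundred segments complete in seconds.

Known limitations:

* Segmentation uses an analytic significance bound rather than permutations;
  very short copy events (< 5 exons) are not detected.
* The clone model assumes clones are nested or disjoint only through their
  sample fractions; it does not reconstruct a phylogeny.
* Power estimates assume the copy state and sample fraction are known; they
  are upper bounds on end-to-end sensitivity.
* Tumor fraction near 1 makes clonal diploid somatic variants statistically
  indistinguishable from germline hets ($\phi^S \to \phi^G$); only the prior
  separates them, so sensitivity collapses by design.
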