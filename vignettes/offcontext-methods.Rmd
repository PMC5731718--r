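---
title: "Detecting off-context gene expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting off-context gene expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offcontext)
```

## The problem

A hallmark of the cancer-cell "identity crisis" is the ectopic activation of
genes that are normally silent outside a narrow set of tissues — male
germline, placenta and embryonic stem (ES) cells being the classic sources
of such off-context genes (cancer-testis antigens are the prototype). The
same screen is informative in other diseases with cancer-like hallmarks,
such as pulmonary arterial hypertension. `offcontext` implements the full
screen as a reusable, tested pipeline:

1. **Atlas stage** — classify every gene of a multi-tissue reference atlas
   as *restricted* to, or *predominant* in, one of the target classes
   (germline, placenta, ES cells), versus *unrestricted*.
2. **Ectopic stage** — in a case/control cohort, flag case samples in which
   an atlas-flagged gene exceeds a per-gene control threshold, and
   aggregate flags into "all cases" and "at least one case" gene sets with
   a three-group reporting partition.
3. **Concordance stage** — replicate the calls across independently
   processed datasets and count per-gene support.
4. **Synthetic stage** — a seeded generator with planted ground truth, so
   every stage is testable without any external download.

## The statistical model

Both detection rules are the same primitive: a value is called *above
background* when it exceeds

$$\tau \;=\; \hat\mu + k\,\hat\sigma, \qquad k = 3 \text{ by default,}$$

with $\hat\mu,\hat\sigma$ estimated from a reference set — somatic tissue
means in the atlas stage, control samples in the ectopic stage. The SD
always uses the $n-1$ denominator, and in the atlas stage it is computed
across *tissue-level means*, not raw samples: the threshold is phrased over
tissues, and tissues are the exchangeable units there.

**Atlas stage.** For gene $g$ with somatic tissue means
$m_{g1},\dots,m_{gT}$ and target-class mean $c_{g}$ (mean of the class's
tissue means):

* *predominant*: $\max_\text{class} c_g > \bar m_g + k\,\mathrm{sd}(m_g)$;
  the class is the argmax, ties broken by the configured class order
  (germline, placenta, ES by default).
* *restricted*: every somatic $m_{gt} \le$ `detection_floor` **and** at
  least one target tissue mean $>$ `detection_floor`. A gene silent
  everywhere is unrestricted — "restricted to" a tissue implies presence in
  it.
* restricted takes precedence over predominant (it is the stronger claim),
  so every gene has exactly one status.

**Ectopic stage.** A (gene, case) cell is flagged iff its value **strictly**
exceeds $\tau_g = \bar x_{\text{ctrl},g} + k\max(s_{\text{ctrl},g},
\varepsilon)$. Equality is not aberrant: a deterministic boundary makes the
call reproducible to the last bit. Calls are computed only for atlas-flagged
candidate genes (an `all_genes = TRUE` escape hatch exists for exploration),
and no multiple-testing correction is applied by default — the headline
analysis is a screen, not a test; `permutation_null()` provides an optional
label-shuffling empirical null with `p.adjust` support for users who want
error control.

## What three controls buy you: exact null calibration

Under a Gaussian null with $n$ controls,
$(x_{\text{case}} - \hat\mu)/(\hat\sigma\sqrt{1 + 1/n})$ is $t_{n-1}$, so
the exact per-cell false-flag rate is

$$p(n) = P\!\left(t_{n-1} > \frac{k}{\sqrt{1 + 1/n}}\right),$$

which the simulated `calibration_experiment()` reproduces (the unit tests
compare against `stats::pt` as an independent oracle). The asymptotic rate
is $\Phi(-3) = 0.00135$; with $n = 3$ controls it is $P(t_2 > 2.598)
\approx 0.061$ — roughly 45 times the nominal rate. This is a real property
of minimal case/control designs and the reason the aggregation into
"flagged in *all* cases" matters: under independence the all-cases rate at
3 cases is $\approx 0.061^3 \approx 2\times10^{-4}$ per gene.
`analysis/05_calibration.R` tabulates these rates.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `k_atlas` | 3 | SDs | predominance threshold over somatic tissue means |
| `detection_floor` | 25th percentile of atlas values | working scale | silence cutoff for restriction |
| `k_control` | 3 | SDs | ectopic-call threshold over controls |
| `epsilon` | 0.01 × median control value | working scale | pseudo-SD floor for zero-variance controls |
| `aggregation_mode` | `all` / `any` | — | conjunction vs disjunction over case samples |
| `min_datasets` | — | datasets | replication threshold in the concordance stage |

Working scale: all statistics are computed on $\log_2(x+1)$ intensities by
default — the microarray convention, and mean + SD is far better behaved on
the log scale under intensity skew; `scale = "linear"` computes on raw
intensities instead, and mixing scales between atlas and cohort is a hard
error. The detection floor is the one quantity with no principled external
definition ("restricted" is operationalised differently by every atlas
paper); the 25th-percentile default is reproducible and data-driven, and an
absolute override is accepted. With `epsilon = 0` and linear intensities the
whole pipeline is equivariant under global rescaling, which the tests
assert.

## The synthetic generator

`synthetic_config()` defaults mirror a minimal array study: 112 somatic
tissues (plus testis, ovary, placenta, ES cells), 3 samples per tissue,
1000 genes, 30 restricted + 40 predominant planted genes, 3 control and 3
case samples, activations 10 control-SDs above baseline. Noise is additive
Gaussian on the log2 scale (log-normal intensities), SD 0.5; baseline
log2-intensity 5; restricted genes sit at 1 (silent) somatically and 10 in
their target tissue; predominant genes sit 6 log2 units above baseline in
their class.

Two deliberate modelling choices:

* **Somatic tissue offsets.** Each somatic tissue has a baseline offset
  drawn once (SD 1 log2 unit) and shared across genes, modelling the
  systematic tissue-to-tissue intensity differences real atlases show,
  while target tissues sit at the global baseline. Consequently each gene's
  somatic mean + 3 SD threshold is dominated by genuine tissue spread
  (SD ≈ 1) while a null gene's class mean fluctuates only by
  `noise_sd`/√(samples) ≈ 0.3, so unplanted genes essentially never cross
  the threshold: exact recovery of the planted truth is a property of the
  generative model, not of a lucky seed.
* **Silent genes carry no tissue effect.** A silenced gene is at assay
  background, and background does not track tissue identity.

What the generator does **not** emulate: probe-level artifacts, batch and
platform effects (Affymetrix vs Illumina), heavy-tailed or
intensity-dependent noise, correlated co-expression modules, and real
biological "leaky" expression just above background. Passing the recovery
tests therefore demonstrates correctness of the *method's logic and its
calibration under its own assumptions* — not that real cohorts of three
patients yield stable gene lists (the calibration analysis in fact
quantifies how permissive the 3-control design is).

## Numerical and degenerate-input choices

* Strict `>` at both thresholds; ties never flag.
* SD with $n-1$; a single control or a single somatic tissue is a hard
  error, not an NA.
* Zero-variance controls: without the `epsilon` floor, $\tau$ collapses
  onto the mean and any noise flags the gene; the floor (default 1% of the
  median control intensity) makes such genes require a visible shift.
* Duplicate probes collapse to the per-gene maximum at load time
  (conservative for presence-calling); genes with missing cells are
  dropped; both are logged and counted, because every downstream gene count
  hinges on these silent filters.
* Gene ids are uppercased and whitespace-stripped before cross-dataset
  comparison; symbol aliases are deliberately not resolved (no annotation
  database dependency, deterministic offline behaviour).
* Ties between target classes break by the configured class order, making
  every output deterministic.

## Problem sizes used by the test-suite experiments

The packaged experiments run at sizes chosen to make Monte-Carlo error
negligible relative to the quantities tested while completing in seconds:
calibration at 200,000 draws per condition (MC SE ≈ 8×10⁻⁵ at the
asymptotic rate), recovery over ≥ 10,000 planted events accumulated across
replicate cohorts of the default 1000-gene study (half the planted genes
activated, so the same run measures the false-flag rate on the unactivated
half), and oracle-equivalence checks on twenty 200-gene × 30-sample
instances.

## Known limitations

* The atlas stage classifies on tissue means; it does not model
  within-tissue cell-type heterogeneity (a bulk-transcriptomics screen by
  construction).
* With 3 controls the per-cell null rate is ~6%, so single-patient calls on
  large candidate lists contain expected false positives; replication
  (all-cases aggregation, cross-dataset concordance) is the intended
  mitigation, as no multiple-testing correction is applied by default.
* Concordance is set-level only: it counts replicated calls and does not
  pool effect sizes across datasets.
* The detection floor is a data-dependent quantile by default; comparing
  restricted-gene lists across atlases requires fixing it absolutely.
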