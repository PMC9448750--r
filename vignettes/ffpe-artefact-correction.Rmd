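---
title: "Correcting formalin-fixation artefacts in mutational signature analysis"
author: "ffpecorrect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting formalin-fixation artefacts in mutational signature analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Formalin fixation, the standard preservative treatment behind virtually every
pathology archive, hydrolytically deaminates cytosine to uracil (and
5-methylcytosine directly to thymine). During library amplification these
lesions are read as C>T substitutions, so sequencing data from
formalin-fixed, paraffin-embedded (FFPE) tissue carries thousands of
artefactual C>T calls on top of the tumour's real somatic mutations. Any
downstream mutational-signature analysis that ingests the raw catalogue will
misattribute this artefact mass to biological processes — most damagingly to
the clock-like CpG deamination signature and to base-excision-repair
deficiency signatures, which are the biological twins of the two artefact
spectra.

`ffpecorrect` models an observed 96-channel single-base-substitution (SBS)
catalogue $V$ as a linear combination of a *fixed* artefact signature $W_1$
and a *free* biological spectrum $W_2$:

$$ V \approx W_1 H_1 + W_2 H_2, $$

with non-negative activities $H_1, H_2$. Given $V$ and $W_1$, the package
infers $H = [H_1, H_2]^\top$ and $W_2$ by minimising the generalized
Kullback–Leibler divergence

$$ D(V \,\|\, \hat V) = \sum_i \Big( V_i \log \tfrac{V_i}{\hat V_i} - V_i + \hat V_i \Big), \qquad \hat V = W_1 H_1 + W_2 H_2, $$

with Lee–Seung multiplicative updates in which the artefact column is never
updated. This is a one-free-column constrained KL-NMF: the natural noise
model for count data, and the same machinery used across the
mutational-signature field.

## The fitting procedure and its tunables

`ffpe_correct()` is the core fitting function; it returns a classed
`ffpe_fit` object with the usual `print`, `summary`, `coef`, `fitted`,
`residuals`, `predict`, `plot` and `simulate` methods. Each *restart* draws
$W_2$ from a symmetric Dirichlet(1) over the active channels and initialises
the activities at an equal split of the catalogue total, each jittered by a
Uniform(0.5, 1.5) factor. The Dirichlet draw guarantees full support: zero
entries are absorbing under multiplicative updates, so the initial spectrum
must touch every channel the solution might need. $W_2$ is renormalized to
sum to one after every iteration with the scale absorbed into $H_2$; this is
a pure reparametrization (the update rules are scale-covariant, and we
verified the trajectories are identical either way) that keeps $(W_2, H_2)$
identifiable.

Convergence follows a batched plateau rule (`correction_control()`):
divergence is averaged over the last 20 iterations and divided by the mean
of the previous 20; since the divergence is non-increasing this ratio is at
most 1, and the run stops once it reaches 0.95 — i.e. the divergence is
falling by less than 5% per batch — subject to a minimum of 200 and a
maximum of 3000 iterations. One hundred restarts (seeds `base_seed + 0..99`)
are run by default and their $W_2$, $H_1$, $H_2$ averaged; the restart
spread of $H_1$ is retained in the fit as an instability diagnostic.

Two corrected catalogues are emitted and both are tested:

* `corrected` (**primary**): the channel-wise subtraction
  $\max(V - H_1 W_1, 0)$. It preserves observed per-channel detail, which is
  what signature refitting should see.
* `corrected_model`: the smooth model reconstruction $H_2 W_2$.

The division guard `epsilon = 1e-12` only protects $0/0$ inside the update
rules; it is never added to reported outputs.

### Known failure modes

Correction quality is governed by two sample statistics:

* **SNR** — biological C>T count divided by the artefact count. Below
  roughly 0.1 the Poisson variability of the artefact outweighs the signal
  and accuracy degrades quickly.
* **SNS** — the cosine similarity, on the 16 C>T channels, between the
  biology and the artefact signature. As SNS approaches 1 the decomposition
  becomes unidentifiable: the model cannot tell artefact from biology, which
  manifests as a widening restart spread of $H_1$ rather than as a
  biased point estimate. The package's tests assert exactly this behaviour.

A genuinely non-identifiable configuration is also worth spelling out
because a naive intuition fails: even when the biology has *no* C>T content
at all beyond what the artefact explains (disjoint supports plus a uniform
C>T block), the KL optimum is a continuum — the free spectrum can absorb an
arbitrary share of the C>T mass while fitting the other channels exactly.
The multiplicative dynamics then settle at a point determined by the
initialisation, empirically ~4% short of assigning the whole C>T block to
the artefact. The restart average is therefore reported with its spread, and
users should read $H_1$ as a model attribution, not a count estimate, when
supports overlap this way.

## Deriving artefact signatures from labelled cohorts

`derive_noise_signature()` reconstructs an artefact spectrum from a cohort
of FFPE profiles labelled by repair protocol. Profiles are first projected
to the non-T>C (80-channel) probability simplex — T>C mutations recur across
samples and batches in a way incompatible with random formalin damage, so
they are treated as missing data and zeroed. Each repeat embeds the cohort's
pairwise cosine distances into 2-D with exact t-SNE, evaluates a Gaussian
kernel density (Scott's rule bandwidth) at every embedded point *within each
protocol group*, keeps the densest half of each group (strictly above the
group median, median ties broken toward the lower index up to the quota
$\lceil N/2 \rceil$), and averages the retained profiles into one candidate
signature. The final signature is the renormalized mean over 100 embedding
seeds.

Choices the underlying procedure leaves open, fixed here once:

* t-SNE perplexity `min(30, floor((N-1)/3))`, 2 components, exact
  (`theta = 0`) gradient on the precomputed distance matrix; recorded in
  `Embedding$params` for provenance.
* Density is estimated per protocol label, not per unsupervised cluster:
  the labels are known, and the embedding's job is only to expose outliers.
* The candidate seed list (0..99) is stored on the derived signature.

## The bundled signatures are synthetic stand-ins

The package ships two artefact signatures
(`inst/extdata/synthetic_ffpe_signatures.tsv`, loaded by
`bundled_signatures()`). They are **synthetic**: deterministic constructions
that emulate the published artefact spectra rather than transcriptions of
them. The unrepaired signature spreads C>T mass across all 16 trinucleotide
contexts with mild flank preferences and CpG depletion (deamination of any
cytosine); the repaired signature concentrates 87% of its mass at the four
N[C>T]G channels (5-methylcytosine deamination, which uracil-DNA-glycosylase
treatment cannot excise) with a small non-CpG residue. Both carry zero T>C
mass. The construction recipe is `scripts/make_fixtures.R` in the source
repository. Analyses that depend on the *exact* published spectra — e.g.
cosine comparisons against the COSMIC catalogue — require the user to supply
those matrices; every structural and behavioural property exercised by this
package (C>T dominance, CpG contrast between protocols, SNS/SNR behaviour)
is preserved by the stand-ins.

The same applies to the reference set `synthetic_reference_signatures.tsv`
(`SBS1like`, `SBS5like`, `SBS18like`, `SBS40like`): shapes after well-known
signature classes — CpG clock spikes, flat, ROS-driven C>A, and a flat tilt
deliberately confusable with the flat signature — not COSMIC data.

## What the simulator emulates — and what it does not

`simulate_cohort()` reproduces the in-silico experimental design used to
validate this class of correction: biological catalogues are multinomial
draws from signature mixtures (defaults: a colorectal-like mixture
`SBS1like 0.25 / SBS5like 0.55 / SBS18like 0.20`, Dirichlet-jittered with
concentration 10 per sample; totals log-uniform on $10^4$–$10^5$), and
artefacts are independent per-channel Poisson counts with mean
`noise_total * W1_i` — equivalently a Poisson(`noise_total`) total split
multinomially, an identity the tests verify via the moments of the injected
totals. The default `noise_total = 1e4` matches the artefact burden used in
the validation experiments, and T>C channels of the observed catalogue are
zeroed by default (`drop_TC = TRUE`), mirroring the recommended treatment of
real samples whose T>C content is of unknown origin. A master seed derives
per-sample child seeds as `(seed + 1000003 * i) mod (2^31 - 1)`, so cohorts
are exactly reproducible.

The simulator does **not** emulate: read-level errors and coverage,
allele-frequency or strand-orientation structure of artefacts (upstream
filters remove those in real pipelines), inter-channel correlation of
residual noise, or fixation-time kinetics. Passing the recovery suites
therefore demonstrates correctness of the decomposition machinery under the
stated noise model, not performance on any particular wet-lab protocol.

## Refitting, presence calls and the 80-channel spectrum

`refit_activities()` fits non-negative activities of a *fixed* signature set
by the same multiplicative machinery with every column frozen. That
objective is convex in the activities, so a single deterministic run from an
equal split suffices; tests cross-check it against non-negative least
squares and a KL grid search. Presence calls use a strict threshold
(relative activity > 0.1), and activity error is the absolute difference of
relative activities.

For samples where T>C mutations must be discarded, signatures are reduced to
80 channels and renormalized; fitted 80c activities are rescaled back to the
full-spectrum scale by dividing by the signature's non-T>C mass. The
80c/96c *inconsistency rate* is `log10(activity_80c / activity_96c)`, with
the well-refitted band applied exactly as printed, $[-0.30, 0.18]$ — note
`log10(0.5) = -0.301` falls just outside the rounded lower endpoint, and the
package follows the printed endpoints rather than re-deriving them. Zero
activities on either side yield a counted `NA`, never $\pm\infty$.

## Numerical and design notes

* Channel order is the COSMIC convention (C>A, C>G, C>T, T>A, T>C, T>G
  blocks; contexts lexicographic by 5' then 3' flank) and fixes every vector
  index in the package. Purine-centred variants are folded to the pyrimidine
  strand before classification; opportunity vectors are 32 pyrimidine-centred
  trinucleotide frequencies for the same reason.
* Zero-count catalogues are representable (an empty mutation table builds
  one, with a warning) but rejected by the analytic operations.
* Cosine similarity on an empty or zero-masked sub-vector is an error, never
  a silent 0; undefined SNR/SNS are `NA` sentinels excluded from summaries.
* Equal-SNS ties in the protocol advisor break toward the repaired protocol,
  which carries the lower absolute artefact burden.

## Problem sizes used by the test and acceptance suites

The shipped suites run at desk scale, chosen to exercise every claim with
comfortable statistical margins: 50-sample recovery cohorts and 20 samples
per SNR level (SNR ladder 0.02–1.0), with 20 restarts per correction — the
restart average is already stable at 20 for these problems, and the 100
restart default remains available. The derivation tests use cohorts of 16–32
profiles with 5 embedding seeds. The million-count law-of-large-numbers
check and the 1000-instance monotonicity sweep run in seconds.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
all cohorts from scratch and reports: the worst relative KL change across
1000 random multiplicative updates (negative: monotone), the
disjoint-support artefact activity, mean C>T correction accuracy and the
corrected/uncorrected activity-error pair on the 50-sample cohort, the
SNR-ladder accuracies, fixture invariants and SNS statistics, and the
80c/96c consistency quantities. See the README for a worked example with
the numbers it prints.
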