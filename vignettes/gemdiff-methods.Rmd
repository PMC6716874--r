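---
title: "Differential flux capacity from batch-structured transcriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential flux capacity from batch-structured transcriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gemdiff` compares the metabolic capacity of two cellular conditions —
its motivating system is naive versus primed human pluripotent stem
cells — by integrating transcriptomes into a genome-scale metabolic
model (GEM) and contrasting condition-specific flux ranges. This
vignette explains each model and procedure, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## The constraint-based model

A GEM is a stoichiometric matrix $S$ (metabolites × reactions) with
per-reaction flux bounds $l \le v \le u$ (mmol/gDW/h) and boolean
gene–protein–reaction (GPR) rules. Feasible steady states satisfy
$S v = 0$. Flux balance analysis (FBA) maximizes a biomass
pseudo-reaction over this polytope; flux variability analysis (FVA)
then reports, for every reaction, the attainable flux interval
$[v^{\min}, v^{\max}]$ subject to retaining a fraction of the biomass
optimum. We default that fraction to 0.9 — the conventional
"near-optimal growth" setting; it is a `pipeline_config` parameter
(`objective_fraction`) because no single value is canonical. At
fraction 1 the interval collapses wherever the optimum pins fluxes; at
fraction 0 it is the unconditional flux range.

All LPs are solved by a bounded-variable two-phase simplex written for
this package (Bland's rule for anti-cycling, dense refactorization
every iteration). At the package's problem sizes — tens to a few
hundred variables — exactness and determinism matter more than speed,
and the implementation is cross-checked in the test suite against an
independent LP route (scipy's HiGHS interface via the system `python`)
and against hand-enumerated vertices of small motifs.

## Expression integration

Expression matrices are log2-scale, genes × samples, with per-sample
batch and condition labels. The stages:

**Median normalization.** Each sample is shifted so its median equals
the global median of sample medians. This deliberately modest
between-platform reconciliation preserves within-sample ranks; it is
the package's documented choice where stronger count-based
normalizations are out of scope (the DE stage is a two-group test on
log intensities, not a count model).

**Batch correction.** The parametric empirical-Bayes location/scale
model (ComBat, via the `sva` package) with the condition label always
included in the design, so condition differences are never absorbed
into batch estimates. A batch containing only one condition is
rejected by name — its effect is not estimable separately from the
condition. Diagnostics: PCA of the gene-centered matrix and seeded
k-means (50 restarts) with the mean silhouette width and the adjusted
Rand index against any reference labelling. We call "no major
heterogeneity" at mean silhouette < 0.25; the threshold is a
convention of this package (the visual judgement it replaces has no
numeric criterion) and is surfaced in the function documentation
rather than buried.

**Differential expression.** Per gene, logFC = mean(naive) −
mean(primed) and a Welch two-sample *t*-test, BH-adjusted. Genes with
zero variance in both groups get p = 1 and a flag. Welch rather than
pooled-variance: merged multi-study compendia have no reason to share
within-group variances.

## Reaction scoring and confidence tiers

Each reaction's GPR is evaluated over mean gene expression with
`and` → min (a complex is limited by its scarcest subunit) and
`or` → max (isozymes substitute). Genes in the model but absent from
the data count as "not expressed" (score 0); genes in the data but not
the model are ignored. Reactions without a GPR, or whose GPR genes are
all missing from the data, are unscored.

Tiers: among scored reactions the top `ceiling(0.10 N)` by score are
*high* confidence, the bottom `ceiling(0.10 N)` *negative*, everything
else — including all unscored reactions — *medium*. Two open choices
were resolved as follows. (1) The 10% cutoffs are taken over *scored*
reactions: expression evidence can only rank reactions it speaks to;
GPR-less reactions get medium so that network topology, not absence of
annotation, decides their inclusion. (2) Ties at a cutoff break by
lexicographic reaction id, making tier assignment a pure function of
the scores.

## Context-specific extraction

The extraction is a deterministic cost-penalized dependency assessment
over the tiers. The model is first split into irreversible halves
(`r_f`, `r_b`), so penalties apply to nonnegative fluxes. For each
high-confidence reaction the LP

$$\min \textstyle\sum_i c_i v_i \quad \text{s.t.} \quad S v = 0,\;
0 \le v \le u,\; v_{\text{target}} \ge \tau$$

is solved with medium candidates at cost 1, negative candidates at
cost 100, and everything else free; candidates with flux $> 10^{-6}$
at the optimum form the target's *support*. The flux demand
$\tau = 1$ is clipped per target to its maximum feasible flux, so
low-capacity reactions are not declared unsupportable by scaling
alone. When a split half is assessed, its reverse partner is forced to
zero — otherwise the futile two-cycle `r_f + r_b` satisfies any flux
demand at zero net conversion and the assessment learns nothing (this
is easy to miss and silently breaks extraction).

Medium reactions appearing in any support are promoted; negative
reactions are promoted when they support at least `nc_promotion_min
= 2` high reactions. Promoted mediums are then re-assessed against the
remaining negatives (with non-promoted mediums removed) and any
further support promoted. Two safeguards close the procedure. A
*rescue sweep* re-assesses any high reaction still blocked in the
assembled submodel and pulls in whatever it needs — in particular, a
negative reaction that is the *unique* support of a single high
reaction enters regardless of its tally. Then a *pruning sweep*
repeatedly removes reactions that cannot carry $|v| \ge 10^{-6}$ in
any steady state, so the advertised invariant — every retained
reaction can carry flux — is checkable by FVA. High reactions are
never pruned; one going blocked is an extraction failure, except for
high reactions that cannot carry flux even in the generic model, which
are reported as unsupportable and excluded rather than aborting the
run. Unlike the randomized-cost original of this algorithm family, all
costs here are deterministic: reproducibility and testability were
judged worth the loss of the noise-averaged occurrence counts, whose
role the support tally takes over.

## Condition submodels and the six-status classifier

For each condition, genes significantly downregulated in it (BH
p < 0.05 and |logFC| beyond a threshold) are switched off and every
reaction whose GPR evaluates false has both bounds set to zero.
Full GPR evaluation is the default — an isozyme-redundant (`or`)
reaction survives losing one gene — with an "any-association" mode
behind a flag for the stricter reading. Because a threshold choice
moves the removed gene set, the analysis runs at 1.00, 0.85 and 0.70
log2 units and keeps only consensus calls.

Each reaction's FVA intervals under the two condition models,
$N = (a_n, b_n)$ and $P = (a_p, b_p)$ (a reaction absent from one
model is exactly $(0,0)$ there, since removal is bound-zeroing), are
classified with tolerance $10^{-6}$:

* **F** — all four endpoints within tolerance of zero (inactive in both);
* **A** — $a_n > b_p$ (naive interval entirely above primed); **B** symmetric;
* **C** — both endpoints of $N$ at least match $P$'s and one strictly
  exceeds (naive-shifted); **D** symmetric;
* **E** — otherwise (overlapping/unchanged).

A and C mark capacity up in naive, B and D up in primed. A reaction is
*robustly* up in a condition only if its status lands in that
condition's pair at every fold-change threshold. The classifier works
on signed intervals; reversible reactions are compared on the single
signed flux axis.

## Reporter metabolites

For metabolite $m$ with $k$ neighborhood genes (the union of genes in
GPRs of reactions producing or consuming it, one step,
compartment-specific):

$$Z_m^{\text{raw}} = \frac{1}{\sqrt{k}} \sum_{g} \Phi^{-1}(1 - p_g),$$

with DE p-values clamped to $[10^{-15}, 1-10^{-15}]$. Because hubs
accumulate large sums by chance, $Z^{\text{raw}}$ is standardized
against a sampled background: for each distinct $k$, 10,000 random
size-$k$ gene sets are drawn from *all* genes with a DE p-value — the
whole dataset, not only metabolic genes, matching the statistic's
published form and keeping the null moments uncontaminated by
pathway-level signal. $p = 1 - \Phi(Z^{\text{corrected}})$,
BH-adjusted across metabolites (a raw-p mode exists for comparison).
Direction is reported separately as the mean sign of neighborhood
logFCs; the statistic itself is one-tailed significance aggregation.
No currency-metabolite exclusion list is applied by default — NAD⁺
itself is a finding of interest in the motivating analysis, so highly
connected species must stay scorable; an exclusion list is a
parameter. Metabolites with a degenerate background ($\sigma_k = 0$)
are flagged and excluded rather than scored at $\pm\infty$.

## Enrichment

Pathway over-representation is the hypergeometric upper tail of the
observed overlap, BH-adjusted across sets, with the DE-tested gene
universe as background. The weighted running-sum statistic of GSEA is
deliberately not implemented: the package's contribution is the input
gene lists (flux-derived, reporter-derived), and a transparent exact
test keeps those lists auditable.

## The synthetic study

`make_toy_network()` builds a ~36-reaction GEM: glucose uptake →
glycolysis-like chain → pyruvate; a TCA-like cycle with an anaplerotic
entry (whose product the biomass drains — without that drain the
anaplerotic step would be structurally blocked); oxygen uptake and an
OXPHOS-like ATP producer; a tryptophan → kynurenine → NAD⁺ branch of 8
reactions and 9 dedicated genes with an IDO1-like gene on the first
committed step; three background nutrient chains; and a biomass
objective consuming ATP, pyruvate, oxaloacetate and NAD⁺. Every
enzymatic reaction carries a GPR; exchanges and biomass are GPR-less
pseudo-reactions (they have no enzyme), which also keeps the
unscored-reaction path of the tier logic exercised. The default
medium (`toy_medium()`) lists every nutrient the network was built to
consume. The size — 30–50 reactions, 8–12 branch genes — keeps the
10% tiers non-degenerate while every LP remains brute-force checkable.

`simulate_expression()` draws
$x_{gs} = \mu_g + \Delta_g \mathbb{1}[\text{naive}] + \gamma_{g,b(s)}
+ \varphi_{g,b(s)} \varepsilon_{gs}$ with $\mu_g \sim N(7, 1.5)$ (log2
microarray-like scale), per-batch mean shifts and per-gene additive
effects of SD `batch_shift_sd`, multiplicative scales uniform in
`batch_scale_range`, and noise SD `noise_sd`. The reference conditions
— 3 batches, 20 samples per condition per batch, shift SD 2 log2
units, scale range (0.8, 1.25), noise SD 0.5, planted branch logFC
−1.5 — were fixed once to mirror the structure of merged multi-study
stem-cell compendia: batch displacement well above biological effect
size, effects recoverable at the compendium's sample count. All
generators are pure functions of their spec (every `set.seed` is
derived from the spec's seed).

What the generator does **not** emulate: count-based (RNA-seq) noise,
gene–gene correlation beyond the planted pathway, compositional or
length biases, partially confounded designs, and any disagreement
between transcript abundance and enzyme capacity. Passing tests
therefore certify the pipeline's statistical and flux machinery under
an idealized signal model, not performance on real compendia.

## Numerical choices and degenerate inputs

* LP tolerances: reduced-cost and ratio tests at $10^{-9}$; "carries
  flux" and interval comparisons at $10^{-6}$; phase-I feasibility at
  $10^{-7}$.
* Tier ties and all sort orders break lexicographically; extraction,
  FVA and the pipeline are deterministic given the config seed.
* Zero-variance genes: p = 1, flagged. Constant-zero samples: left
  unshifted by normalization, warned. Empty models, empty rules, empty
  gene sets: handled as identities or validation errors, tested.
* Problem sizes in the shipped tests were chosen so the whole suite
  and the acceptance script run in a few minutes on one core: the
  toy GEM (~36 reactions) for all flux work, 2,000–2,200 genes and
  40–120 samples for the statistical stages, 100 replicates for the
  reporter null calibration, 10,000 background draws where a
  Monte-Carlo moment is compared against an independent resampling.

## Known limitations

* The extraction is a faithful-in-spirit, deterministic variant of the
  CORDA family, not a reimplementation of any published variant's
  exact parameterization; on real data its submodel size will differ
  from published context models.
* The simplex refactorizes densely every iteration; genome-scale
  models (thousands of reactions) parse and validate fine, but FVA on
  them is outside the intended scale of this solver.
* Median normalization cannot reconcile platform differences beyond a
  location shift; strongly scale-discordant studies should be
  pre-normalized upstream.
* The reporter statistic aggregates significance, not direction; a
  metabolite whose neighbors move strongly in both directions scores
  high, and the separately reported mean sign is a summary, not a test.
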