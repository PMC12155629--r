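---
title: "Methods: co-prescription mining and network-proximity drug screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-prescription mining and network-proximity drug screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`copresnet` implements an integrative pharmacoepidemiology workflow
developed around long-term peritoneal dialysis (PD) care, where patients
accumulate complex co-medication over years of treatment. The pipeline
links two worlds: a longitudinal prescription database (which drugs were
recorded together, for whom, and when) and a molecular network model of
the disease (which proteins are dysregulated and how drug targets relate
to them). Its end product is a shortlist of drug *combinations* whose
members act on distinct dysregulated molecules within the same disease
process — candidates for complementary, potentially synergistic
pharmacology.

This vignette documents the models and procedures stage by stage, the
tunable parameters and the reasoning behind their defaults, the synthetic
data generator used for validation, and the numerical conventions and
known limitations.

## 1. Drug-name harmonization

Clinical prescription tables contain free-text drug names with
typographical errors. Harmonization is a two-stage, semi-automated
pipeline:

1. **Exact stage.** Raw names are normalized (case fold, whitespace
   collapse, dosage-suffix strip) and matched against catalog entries
   that carry at least one ATC code. Entries without an ATC code are not
   considered identified drugs and never match — identification is
   anchored on the ATC system.
2. **Clustering stage.** The residue is pooled with the catalog names;
   pairwise distances are `1 − JW` where `JW` is the Jaro–Winkler
   similarity (match window `⌊max(|s1|,|s2|)/2⌋ − 1`, half-transposition
   count, prefix bonus `0.1` capped at 4 characters, applied
   unconditionally). The distance matrix is agglomerated with Ward
   linkage and the tree is cut; within each cluster every raw name is
   assigned to the cluster's catalog name of highest `JW`. Clusters with
   no catalog name remain *unresolved*; a reproducible overrides table
   (raw name → drug id) stands in for the manual review such pipelines
   end with, and takes precedence over the clustering.

**Cut height.** Ward merge costs grow with cluster size, so the
cophenetic heights of `hclust(..., "ward.D")` are not on the `[0, 1]`
distance scale: with hundreds of typo variants the root height reaches
the tens while individual typo–canonical distances sit below 0.05. The
cut parameter (default 0.2) is therefore interpreted as a *fraction of
the tree height*. Typo recovery on synthetic corrupted names is
insensitive to this fraction across 0.1–0.3, which is the robustness one
wants from a screening cut. `ward.D2` produces non-monotone merge
heights on this non-Euclidean dissimilarity (height inversions break
`cutree`), so plain Ward is used; Ward on a non-Euclidean distance is a
documented heuristic, not a variance decomposition.

## 2. Cohort construction and co-prescription mining

Only each patient's **first treatment phase** enters the analysis (a
second phase, e.g. after a failed transplant, is a different clinical
situation). Patients are assigned to the decade (1990–1999, 2000–2009,
2010–2022) containing the majority of their prescription events, ties
toward the earlier decade.

The co-prescription strength of a drug pair is the **patient-time
Jaccard**

$$J(A,B) = \frac{|S_A \cap S_B|}{|S_A \cup S_B|},\qquad
  S_X = \{(\text{patient}, \text{visit date}): X \text{ prescribed}\},$$

so `J = 1` means the two drugs were always prescribed together. Pairs
are enumerated among drugs co-prescribed at the same patient-visit at
least once (an `all_pairs` flag lifts this); this matches how unique
observed combinations are counted in practice, and guarantees `J > 0`
for every enumerated pair. Each pair is classified by patient
prevalence: group `both` if both drugs exceed the 30% prevalence
threshold (strict `>`), `one` if exactly one does, `neither` otherwise —
the three groups partition the pair table by construction.

Longitudinal summaries use months = days / 30.4375 (the mean Gregorian
month). Endpoint comparisons (kidney transplantation vs transfer to
hemodialysis vs death) use the Kruskal–Wallis test followed by pairwise
**rank-sum** tests with Benjamini–Hochberg adjustment. The post-hoc
choice deserves a note: clinical reports in this area sometimes label
the post hoc a signed-rank test, but endpoint groups are independent
samples, so the rank-sum (Mann–Whitney) test is the defensible choice
and is what the package computes. The per-pair effect size is the
rank-biserial correlation `2U/(n₁n₂) − 1`, chosen because it is the
natural effect measure attached to `U` and bounded in `[−1, 1]`.
Prevalence denominators are the analysis cohort (patients surviving the
first-phase filter), not all database patients.

## 3. Drug–drug similarity metrics

Five Jaccard-type similarities per drug pair, each in `[0, 1]` or
undefined-with-reason when both sets are empty:

- **mechanism**: literature-derived mechanism gene sets (taken as a
  catalog column; their provenance is upstream of this package);
- **target**: direct drug-target gene sets;
- **pathway**: the sets of *enriched* pathways per drug — one-sided
  hypergeometric over-representation of the drug's targets in each
  pathway, keeping pathways with target overlap ≥ 3 **and** BH-adjusted
  p < 0.05, adjusted per drug across its tested pathways (the adjustment
  scope is a convention; per-drug is the conservative reading when drugs
  are screened independently);
- **structure**: Tanimoto on fingerprint bit sets (ECFP4-convention bit
  indices; fingerprints are consumed precomputed, keeping the package
  free of a cheminformatics dependency);
- **ATC**: Jaccard of the 4th-level ATC class sets, i.e. the 5-character
  code prefixes under the WHO level convention (levels 1–5 = 1/3/4/5/7
  characters).

The enrichment universe defaults to the union of network genes and
gene-set genes; pathway similarity can be high while target similarity
is zero when two drugs hit disjoint target sets inside the same
pathways — the pattern that makes pathway similarity informative beyond
shared targets.

## 4. Disease-module extraction

Differentially expressed genes (DEGs) from a transcriptomics contrast
are mapped onto a background protein–protein interaction network. The
candidate set is every mapped DEG with at least one edge **plus all
network neighbors of those DEGs**; the module is the largest connected
component of the induced subgraph (ties broken toward the component
containing the lexicographically smallest label, for determinism);
smaller components are discarded and reported, and a `keep_all` flag
retains them. This DEG-plus-first-neighbors construction is the common
network-medicine reading of a "connected subgraph around the DEGs";
keeping one component reflects that a disease module is meant to be a
single connected region. Gene identifiers match case-sensitively after
whitespace trimming; alias resolution is out of scope.

The module is then annotated with biological-process gene sets; the
default process list for prioritization is angiogenesis, sprout
angiogenesis, positive regulation of angiogenesis and inflammatory
response — the processes most implicated in peritoneal membrane failure
(neoangiogenesis and chronic inflammation drive ultrafiltration loss and
fibrosis).

## 5. Network proximity with a degree-preserving null

Drugs with *identical* target sets are collapsed into clusters first
(equality classes; provably the same partition as connected components
of the thresholded similarity-equals-1 adjacency, since set equality is
transitive), and each cluster is scored once, with a dictionary mapping
clusters back to member drugs.

The proximity of a target set `T` to module `M` is the **closest
measure** of network medicine:

$$d(T, M) = \frac{1}{|T'|}\sum_{t \in T'} \min_{m \in M} \mathrm{dist}(t, m),$$

over the mapped, reachable targets `T'` (unmapped and unreachable
targets are excluded and counted). `d = 0` means every usable target
lies inside the module. Shortest paths respect edge weights when the
network carries them; hop counts otherwise. Because the minimum distance
to the module is a per-node quantity, the package precomputes the
module-distance profile once (`module_distances()`) and reuses it across
clusters and null iterations — the screen over a whole catalog runs in
seconds.

**Null model.** Significance comes from degree-preserving
randomization of the drug side only (the module is fixed): nodes are
binned by `⌊log₂ degree⌋`, sparse bins merged upward until each holds at
least 20 nodes, and each real target is replaced by a uniform draw from
its bin, with distinct nodes enforced within a set; 1000 iterations by
default. Then

$$z = \frac{d - \mu_{null}}{\sigma_{null}},$$

with the null mean and *population* standard deviation, `p_normal` the
lower normal tail (proximity is one-sided: interesting means closer than
random), and `p_empirical = (1 + \#\{d_{null} \le d\})/(n_{iter}+1)`,
which is never zero and is exact under exchangeability. Both p values
are reported because a normal tail on a discrete, often skewed null is
an approximation; filtering uses `p_normal` by default (switchable), at
`alpha = 0.05` with **no multiplicity correction** — the screen is a
hypothesis generator, and correcting here would change the stated
operating characteristics of the published procedure this follows.

The calibration property that justifies the empirical p is checked in
the acceptance suite: when the "drug" target set is itself drawn from
the null sampler, the rejection rate at `p_empirical < 0.05`, pooled
over set sizes k ∈ {1, 3, 10} with about 2000 replicates, must lie in
[0.03, 0.07]. The calibration study runs on a weighted network: with
integer hop distances the null is coarsely discrete and the empirical p
becomes conservative by construction (ties count against rejection),
which is a property of discreteness, not of the sampler; continuous
weights remove the ties and expose the sampler's true behavior. Set
size k = 1 remains slightly conservative even then because the atom at
`d = 0` (a draw landing inside the module) can carry more than 5%
probability; this is expected and documented rather than corrected.

## 6. Prioritization of drug combinations

A candidate combination (a, b) must satisfy all four criteria:

1. both drugs' target clusters passed the proximity screen
   (`p < alpha`), and each drug has ≥ 1 direct target inside ≥ 1
   annotated process;
2. **distinct witnesses**: some shared process P contains molecules
   `m₁ ≠ m₂` with `m₁` a target of a and `m₂` a target of b — the two
   drugs engage the same biological process through different
   dysregulated molecules (the complementary-mechanism requirement; a
   witness pair per process is recorded in the output);
3. ATC similarity exactly 0 — no shared 4th-level class, excluding
   same-class pseudo-combinations;
4. structural Tanimoto ≤ 0.3 — "low structural similarity" is not
   quantified in the source procedure; 0.3 is a conventional Tanimoto
   dissimilarity ceiling, exposed as configuration and echoed in the
   report.

Witness membership is checked against the module's process annotations
(any module member, not only DEGs — a strict-DEG restriction is the
natural variant and can be imposed by annotating with DEG-intersected
sets). Emitted pairs are annotated by cohort usage (both / one / none
prescribed, and whether the two drugs were ever co-prescribed in the
same patient) and sorted both-prescribed first, then by ascending
combined p, then ascending structural similarity — deterministic and
aligned with the translational emphasis on combinations already touching
clinical practice. The report records the funnel counts at every filter
stage.

## 7. The synthetic-data generator

No public dataset reproduces a single-center prescription database, so
the package ships a seeded generator (`synth_config()`,
`generate_synth_data()`) that emulates the statistical structure each
stage consumes, together with the ground truth needed for recovery
testing. Identical config + seed is byte-identical, including on disk.

Default study conditions (each a `synth_config()` argument):

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 150 | a realistic single-center dialysis cohort, scaled so the full pipeline and tests run in seconds |
| `n_drugs` | 60 | enough for a heavy-tailed prevalence spectrum and ~1.7k co-prescribed pairs |
| `n_genes`, `ppi_attachment` | 500, 2 | preferential-attachment (scale-free) background, mean degree ≈ 4, typical of curated high-confidence PPI subsets; growth is connected by construction |
| `module_size`, `n_degs`, `deg_noise` | 30, 15, 0.2 | a compact disease region; 80% of DEGs inside it, 20% distractors placed ≥ 3 hops away |
| `frac_proximal_drugs` | 0.2 | a minority of drugs genuinely engage the disease region |
| `typo_rate` | 0.1 | roughly one corrupted mention in ten, the regime a semi-automated harmonization is built for |
| `mean_visits`, `mean_interval_days` | 9, 85 | about nine prescription points ~2.8 months apart — a multi-year course |
| `planted_pairs` | 5 | fixed-combination pairs forced to co-occur (≥ 0.9 per visit) |
| `prevalence_dispersion` | 8 | Beta(0.15, 8) per-drug start probabilities: a minority of drugs exceed 30% patient prevalence, most stay rare |

Structural choices worth explaining:

- **Module growth.** The planted module grows by a random walk from a
  low-degree seed, accepting each walk position whose *closed
  neighborhood* still fits and absorbing that neighborhood; remaining
  slots fill with the boundary nodes most connected into the module.
  Pure walk-visited node sets in a scale-free graph are hub-heavy and
  have large boundaries — no DEG selection can then recover them from a
  DEG-plus-neighbors rule, which does not match the premise that a
  disease module is a locally coherent region. Neighborhood closure
  gives the module a partially self-contained interior, the property
  real modules owe to community structure that a plain
  preferential-attachment graph lacks. In-module DEGs are the walk core
  first, then the most interior remaining nodes.
- **Typos** are substitutions, adjacent transpositions and deletions
  only (pharmacy-style errors), 1–2 per corrupted mention, never on the
  first character — so the Jaro–Winkler prefix bonus stays informative.
  Canonical names are generated pairwise-dissimilar (JW < 0.88), the
  curation property a real drug catalog has.
- **Prescription dynamics.** A started drug persists across visits
  (continuation 0.85) until a random stop, emulating active-medication
  lists carried forward between appointments; visit counts are shifted
  Poisson, gaps exponential (the inter-visit law is a modeling
  convenience — the emulated setting reports only a mean and range);
  endpoints follow realistic marginals (38/25/32/1/3/0.2% for
  KTx/HD/death/recovery/transfer/lost); 10% of patients receive a
  second phase; dates span 1990–2022 to exercise decade assignment.
- **Catalog.** Proximal drugs draw targets from the module (80%) and
  its neighbors (20%); background drugs draw degree-matched targets
  from the whole network, so proximity signal cannot be a degree
  artifact. Some drug pairs share identical target sets on purpose
  (cluster collapsing must be exercised); drugs in one 4th-level ATC
  class share a fingerprint bit core; mechanism genes are supersets of
  targets.
- **Gene sets.** Half the pathways are biased toward the module
  neighborhood so drug-target enrichment has signal; four process sets
  with the default process names each overlap the module in ≥ 5 genes.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: dosing and pharmacokinetics;
real chemical structures (fingerprints are abstract bit sets);
indication-driven prescribing (drug choice here is independent of the
simulated endpoint); database-era effects (drug availability does not
drift across decades); gene aliasing and identifier noise; and the
community structure, edge confidence and literature bias of real PPI
networks. Recovery rates on synthetic data validate the *machinery* —
they are not estimates of performance on clinical records.

## 8. Numerical conventions and degenerate inputs

- Jaccard of two empty sets is undefined (`NA` with the reason carried),
  not 0 or 1; a drug with no targets is excluded from clustering into a
  flagged pool.
- `p_empirical ≥ 1/(n_iter + 1)` by construction; a zero-spread null
  yields `NA` z with the empirical p still defined.
- Strict inequality at the 30% prevalence threshold; a pair at exactly
  (0.30, 0.30) is `neither`.
- Single-visit patients have zero time on treatment and an undefined
  (flagged) inter-visit gap; constant inputs make correlations undefined
  with a warning, never an error.
- Seeds are mandatory and every stage derives its stream from the master
  seed; no wall-clock entropy anywhere.
- Duplicate edges keep the maximum weight; self-loops are dropped and
  counted.

## 9. Known limitations

- Ward linkage on a non-Euclidean string distance and the
  fraction-of-tree-height cut are heuristics; they are validated by
  typo-recovery behavior, not by clustering theory.
- The normal-tail proximity p is an approximation on a discrete null;
  the empirical p is exact but floor-limited at `1/(n_iter+1)`. For
  single-target clusters on unweighted networks both are conservative.
- The screen applies no multiplicity correction by design; its output is
  a shortlist for downstream review, not a set of confirmed hits.
- Pathway enrichment requires ≥ 3 target-pathway overlap, so drugs with
  one or two targets have empty enriched sets and undefined pathway
  similarity; this mirrors the sparsity of real target annotations.
- The generator's planted truth makes recovery testable but is
  necessarily cleaner than clinical reality; see §7.
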