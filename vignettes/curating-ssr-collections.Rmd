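---
title: "Curating clonal SSR collections: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating clonal SSR collections: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrcurate)
```

## The problem

Fruit genebanks preserve clonally propagated cultivars as living trees,
often at several sites and under names of uncertain provenance. Curation
asks three questions of a collection fingerprinted with SSR (microsatellite)
markers: which trees are the *same* cultivar (deduplication into molecular
groups), whether each tree is *true to type* given an independent
pomological determination, and what the deduplicated collection looks like
genetically (diversity, marker discriminating power, relationships,
pedigree plausibility). `ssrcurate` implements that workflow end to end for
diploid fragment-length data: two integer allele sizes per locus per tree,
with missing loci, typing error and inter-laboratory sizing shifts as facts
of life rather than exceptions.

All user-facing functions take a genotype tibble first — one row per tree,
passport columns, then `<locus>.1`/`<locus>.2` allele columns — and return
tibbles, so the pipeline composes with ordinary dplyr verbs.

## Harmonization

Fragment sizes from different sequencers and protocols differ by small,
locus-specific constants. When a set of reference genotypes has been run in
every batch, `estimate_offsets()` recovers a per-(batch, locus) additive
offset as the rounded median of size differences to the designated
reference batch (median because a reference reaction can itself fail;
halves round toward zero). On synthetic two-lab data with error-free
references the planted offsets are recovered exactly, and this is tested.

Within a batch, sizing still jitters by about ±1 bp, so sizes 1 bp apart
are treated as one allele. `build_bins()` makes that tolerance an explicit,
auditable transform: per locus, distinct observed sizes are sorted and runs
with consecutive gaps ≤ 1 bp are merged; the bin center is the modal
observed size (ties to the smaller). The pairwise ±1 bp rule
under-determines *chains* (150, 151, 152 all merge although 150 and 152 are
2 bp apart); we allow the chain but record affected loci in the `chained`
attribute, because on a dinucleotide ladder a chain usually means the locus
needs curator review. This is also why the synthetic generator's default
sizing-jitter rate is low (0.02 per allele): jittered sizes bridge adjacent
rungs of a 2 bp ladder, and with common jitter the greedy merge would chain
whole ladders into one bin and destroy the locus. `harmonize_genotypes()`
applies offsets then bins; it is idempotent, never changes the number of
records or the missing mask, and snaps an unseen allele to a bin only if it
lies within 1 bp.

## Molecular groups and trueness to type

`ssr_similarity()` scores every pair of trees with a simple matching
coefficient: over loci typed in both, count shared alleles (multiset
matching within the diploid pair — exact for pairs of size two) and divide
by twice the number of shared loci. Pairs sharing fewer than `min_shared`
loci (default 8 of 16, configurable) are not comparable; the denominator
deliberately excludes loci missing in either tree, because a failed PCR is
not evidence of difference. The 90% grouping threshold reflects an SSR
artifact rate of roughly 10% per reaction: two honest clones with a typical
artifact load still exceed it.

The field convention speaks of accessions being "included in one molecular
group" without fixing a linkage rule; we use single linkage (connected
components of the above-threshold graph), which matches that language, and
flag groups that are held together only by chained links (`transitive`
attribute) for review, since single linkage can merge two cultivars through
an intermediate. The group representative is the modal exact genotype, ties
broken toward completeness then accession id.

Categories combine the group with the pomological determination per tree:
determined and consistent with the group's majority determined name → 1
(true to type; a conflicting determination is reported under the consensus
name with a relabel flag — identical fingerprints under two names are
synonym candidates, not proof of error, which is why the flag exists);
no pomological reference for the name → 3; no determination possible → 4;
determination approved with reservation → 5. Category 2 is reserved for
sour cherries and never emitted. A group whose two leading determined names
tie has no consensus; its determined members are reported unresolved rather
than forced into category 1, mirroring what a curator would do.

## Diversity, identity probability, marker sets

On the deduplicated representatives, `locus_diversity()` reports the
standard per-locus table — N, Na, Ne = 1/Σp², Ho, He = 1−Σp², rarefied
allelic richness, PI and PIsib — with unweighted arithmetic means via
`glance()`. Frequencies count two gene copies per typed individual;
computing them on representatives (not all trees) avoids weighting a
cultivar by how many clones a genebank happens to hold.

Allelic richness uses the exact rarefaction formula
`Ar(g) = Σ_i [1 − C(N−n_i, g)/C(N, g)]`, with `g` defaulting to the
smallest per-locus number of gene copies so loci with missing data are
comparable; tests verify it against exhaustive subsample enumeration.

The identity probabilities assume Hardy–Weinberg proportions — that is what
the standard formulas encode — even though cherries are self-incompatible
clones; PI is therefore read as a marker-power index, not a literal
probability for this mating system, and PIsib (full-sib pairs) is the
conservative companion for collections full of relatives. Both formulas are
verified against genotype-space enumeration and a Monte-Carlo pair oracle.
`minimal_marker_set()` answers "how few markers suffice": empirical mode
adds loci in ascending-PI order until every genotype pair differs
somewhere; sib mode adds loci in ascending-PIsib order until the cumulative
PIsib falls below a threshold, default `1/choose(n, 2)` (fewer than one
chance-identical relative pair expected among all pairs) — the stopping
rule is one documented interpretation and is configurable.

`fst_pairwise()` computes the heterozygosity-based estimator
`(Ht − Hs)/Ht` per locus (unweighted cluster means, pooled frequencies as
the simple average) and averages loci with `Ht > 0`. Cluster labels are
inputs; the package does not infer genetic clusters.

## Neighbor joining and bootstrap

`neighbor_joining()` is the classic Saitou–Nei agglomeration on
`1 − similarity`, written here so its numerical conventions are pinned
down: Q-ties break toward the lexicographically smallest label pair (a
cluster is labeled by its smallest tip label), giving order-independent,
reproducible trees; negative branch lengths are clamped to zero with the
total deficit recorded. Tests require exact recovery of random additive
matrices and agreement with the independent implementation in `ape`.
`bootstrap_support()` resamples *loci* with replacement — the natural unit
for a marker matrix with fixed genotypes — rebuilds the tree B times
(default 1000) and reports bipartition frequencies as integer percentages
on internal nodes; replicate r draws from the deterministic substream
`seed + r`.

## Parentage verification

Pedigree hypotheses are scored with a likelihood ratio per locus: child
genotype given the named parents under Mendelian transmission versus an
unrelated Hardy–Weinberg child, with each *observed* genotype independently
mistyped with probability `error_rate` (a mistyping is a fresh
Hardy–Weinberg draw — the classic likelihood-based parentage error model,
chosen over per-allele models to stay close to the engines practitioners
use). An unnamed or locus-missing parent is integrated over the
collection's allele frequencies; loci missing in the child or all named
parents are skipped, and fewer than `min_typed_loci` (default 13) usable
loci leaves the hypothesis unevaluated. With `error_rate = 0` a single
Mendelian exclusion drives the LOD to −∞, which tests assert.

Verdicts come from simulation-calibrated thresholds
(`calibrate_thresholds()`): simulate progeny of random Hardy–Weinberg
parents (default 100,000; the test and acceptance suites scale to
5,000–10,000, which this vignette's problem sizes reflect), apply the
observation model (proportion of loci typed 0.9, mistyping 0.1, true
parent among candidates with probability 0.95), score the candidate set,
and find the statistic value above which the best-candidate assignment is
correct in ≥ 95% (strict) / ≥ 80% (relaxed) of simulations. Candidate
counts default to 31 (parent pairs), 18 (mothers), 7 (fathers). Two design
points deserve emphasis:

* **Trio candidate pools contain half-true pairs.** For parent-pair
  analysis the pool mixes the true pair, pairs of one true parent with an
  unrelated candidate, and fully unrelated pairs (candidate mothers and
  fathers are sampled independently). Pools of only unrelated pairs would
  put the strict cut far below the LOD of a "right mother, wrong father"
  hypothesis, which must *not* be confirmed; with mixed pools, planted
  wrong-father hypotheses are rejected essentially always in our
  simulations. A side effect worth knowing: trio thresholds are not
  necessarily above single-parent thresholds, because trio LODs separate
  true from false far better than pair LODs do.
* **The confidence is a guarantee, not an estimate.** The threshold scan
  uses a Wilson lower bound (z = 3.89) on the cumulative precision instead
  of the raw proportion; picking the raw 95% boundary in-sample would leave
  fresh simulations below 95% about half the time (binomial noise plus the
  optimism of scanning every cut). Out-of-sample precision was verified on
  independent panels and seeds.

The `statistic` option switches between the LOD of the named hypothesis
(default — curation verifies *given* pedigrees) and the Δ best-minus-second
statistic used when a candidate list is searched.

## The synthetic generator

`generate_collection()` emulates the statistical structure the analysis
assumes, with complete ground truth: per-locus allele ladders strictly 2 bp
apart (dinucleotide motifs; planted ±1 bp jitter is then unambiguously a
sizing artifact), allele frequencies from a symmetric Dirichlet
(concentration 0.2 over 5–24 alleles per locus, giving an expected
heterozygosity near 0.67 and a mean allele count near 15 — the profile of a
characterized sweet-cherry collection; `target_profile()` gives the
analytic expectation), founder cultivars as Hardy–Weinberg draws, designed
trios and full-sib families as Mendelian crosses, and 1–6 clonal trees per
cultivar (mean ≈ 3.5, close to the ~3.8 trees per unique genotype of a
real curated network). Clones are corrupted by per-locus mistyping (default
0.10, the commonly cited SSR PCR-artifact rate), ±1 bp jitter (0.02),
missing loci (0.03) and constant per-batch offsets; reference cultivars can
be emitted clean in every batch for offset estimation. Every corruption is
logged, and `replay_corruptions()` reproduces the emitted records from the
pristine genotypes — tested exactly.

What the generator does *not* emulate: stutter and null alleles, mutation
across clonal generations, population structure among founders (unless
planted as two islands), and realistic pomological noise (statuses are
planted labels). Passing tests therefore demonstrate correctness of the
algorithms under the stated error model, not robustness to every artifact
of real capillary data.

`certify_margins()` makes the recovery guarantee explicit: grouping
recovers the planted clone structure exactly when each clone has an
above-threshold link inside its cultivar and no cross-cultivar pair
exceeds the threshold. Recovery suites use corruption levels that certify
those margins (mistyping 0.05 with at most one mistyped locus per clone —
at most ~3% of alleles — and no jitter); at the full default corruption the
margins can genuinely fail, which is precisely why the 90% threshold is a
curator's tolerance and not a proof of identity.

## Numerical and degenerate-input conventions

Allele pairs are stored sorted ascending; a homozygote given once is
expanded. Monomorphic loci: Ne = 1, He = Ho = 0, PI = PIsib = 1, zero LOD
contribution. Rarefaction requires `2 ≤ g ≤ min(copies)`. Loci typed in no
individual are dropped with a warning; clusters of fewer than two
genotypes are excluded from Fst. An allele absent from a frequency table
(possible for a child genotyped outside the collection) receives half the
smallest observed frequency. All stochastic stages take explicit integer
seeds, and `run_curation()` writes a manifest from which identical outputs
can be reproduced byte for byte.

## Problem sizes used in the checks

The shipped verification suites run on one CPU with no external data:
collections of 50–60 cultivars (≈ 150–250 trees) for grouping, 383 clean
genotypes for diversity and parentage frequency panels, 10⁶ Monte-Carlo
genotype pairs per locus for the identity-probability oracle, 10 random
additive trees (n ≤ 10) for neighbor joining, and 5,000–10,000 simulated
progeny for threshold calibration. These sizes were chosen so each check
exercises the asymptotics that matter while the whole suite stays
interactive.

## Worked example

```{r example, eval = FALSE}
library(ssrcurate)
library(dplyr)

col <- generate_collection(generator_config(seed = 1, n_trios = 5,
  clone_error_rate = 0.05, sizing_jitter_rate = 0,
  max_corrupt_loci_per_clone = 1, clones_per_cultivar = c(2, 6)))
out <- run_curation(col$records, col$panel, tempfile("curation"),
                    reference_names = col$truth$reference_names,
                    pedigree = col$truth$pedigree,
                    parentage = parentage_config(n_simulated_progeny = 5000),
                    seed = 1)
glance(out$groups)          # groups found among the trees
out$category_summary        # trueness-to-type table
glance(out$diversity)       # mean Na / Ne / Ho / He / Ar / PI
plot_pi_curve(out$pi)       # marker discriminating power
out$parentage               # verdicts per pedigree hypothesis
```

## Known limitations

Single linkage can merge distinct cultivars through intermediates (logged,
not auto-resolved). The ±1 bp chain rule can fuse true alleles when jitter
is common. PI under Hardy–Weinberg understates sharing among clonal,
related material — use PIsib. The parentage engine verifies named
hypotheses; it is not a full paternity search over the collection, and its
thresholds inherit every assumption of the simulation (candidate counts,
error rate, sampling proportion). Triploid or tetraploid individuals,
which occur occasionally in wild cherry, are outside the diploid data
model.
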