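---
title: "Methods: authenticating ancient peptides and mapping collagen chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: authenticating ancient peptides and mapping collagen chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Shotgun proteomics of archaeological and paleontological material faces a
problem modern proteomics does not: a large share of the identified
peptides are not ancient at all, but keratins, trypsin, and other
laboratory or post-excavation contaminants. `paleopept` implements the
standard computational countermeasures as one coherent, fully testable
pipeline:

1. **Damage-based authentication.** Asparagine and glutamine deamidate
   spontaneously over archaeological time, so the deamidation level of a
   peptide population separates endogenous ("original") peptides from
   modern contaminants. Other spontaneous oxidative modifications (Trp,
   Tyr, Cys, Met, and — characteristic of collagen — Pro) show the same
   contrast.
2. **Taxonomic profiling.** Each peptide is assigned the lowest common
   ancestor (LCA) of all taxa whose proteins contain it, giving the most
   specific defensible taxonomic claim per peptide.
3. **Marker-based protein classification.** Proteins are accepted as
   endogenous only when authenticated by at least one clade-unique marker
   peptide, with a conservative reclassification of human-shared proteins
   whose damage profile looks modern.
4. **Collagen chain characterization.** Observed peptides are placed on a
   reference alpha chain with a substitution/indel-tolerant aligner,
   producing coverage, edit calls in mature-chain coordinates, diagnostic
   sites against a species panel, and Gly-Xaa-Yaa triplet validation.

# Modification-level estimation

## The estimator

For a residue class $R$ (for example N, Q, or both pooled) and a
modification $m$, the level is the intensity-weighted site fraction

$$\hat{\theta} = 100 \cdot
  \frac{\sum_i I_i k_i}{\sum_i I_i n_i},$$

where for evidence record $i$, $n_i$ is the number of $R$ residues in the
peptide, $k_i$ the number of those carrying $m$, and $I_i$ the MS1
intensity. Records without the residue or without intensity are excluded
(not imputed). When no record carries the residue the estimate is
*undefined* (`NA`), which is deliberately distinct from an estimate of 0%.

Intensity weighting mirrors the aggregation of the widely used
evidence-table deamidation calculator: high-intensity features carry more
of the measured signal and their modification state is better determined.
The exact aggregation of that tool is not fully specified publicly, so the
choice is exposed: `weighting = "unweighted"` switches to equal per-record
weights. The estimator is scale-invariant in intensity and always lies
between the smallest and largest per-record ratio. On data simulated with
a per-site modification probability $p$ it converges to $100p$.

N and Q are always estimated separately in the default panel (their
deamidation kinetics differ by orders of magnitude, so pooling them hides
information); a pooled `NQ` row is added by the pipeline for the
conservative contaminant rule, which needs one number per protein.

## Bootstrap confidence intervals

Uncertainty is quantified by resampling whole records with replacement
(B = 1000 by default), recomputing $\hat{\theta}$ on each replicate, and
taking the percentile interval. Records — not sites — are the resampling
unit because sites within a peptide share one intensity and one
identification. A seed is mandatory; results are reproducible and the
caller's RNG stream is left untouched. The interval degenerates correctly:
a single record, or fifty identical ones, give zero-width intervals.

With heavy-tailed intensity weights the percentile interval is expected to
undercover mildly (in our replicate studies a nominal 95% interval covers
the generating probability roughly 92–93% of the time at 500 records);
this is a known property of percentile bootstraps for ratio statistics
with a few dominant weights, and is why the calibration test demands 90
of 100 coverages rather than 95.

Samples are never pooled: each `sample_id` is estimated independently, and
original and contaminant groups are always estimated separately.

# Taxonomic profiling

The taxonomy is a rooted tree read from a minimal two-file TSV dialect
(`taxon_id`, `parent_id`, `rank` + `taxon_id`, `name`). The LCA of a taxon
set is computed by depth-equalized walking; it is commutative and
associative over set union, and the test suite checks it against a
brute-force root-path-intersection oracle on a thousand random trees.

Two conventions matter:

* **I/L equivalence.** Isoleucine and leucine are isobaric in MS, so all
  peptide keys are normalized (I becomes L) before lookup.
* **Reference-group exclusion.** When separate database searches are run
  against disjoint reference groups (here: the endogenous clade, plants,
  bacteria + nematodes), a peptide matching two or more groups is not a
  valid identification for any of them and is excluded with a reason.

Tree views report, per node, the direct assignments, the subtree count,
and the subtree count as a percentage of the *parent's* subtree count
(the parent is the 100% reference). Sibling percentages therefore need not
sum to 100 when some peptides stop at the parent. Order is deterministic
depth-first with children sorted by id. A Newick export (with counts
appended to labels) is provided for tree viewers.

# Protein classification

A protein is *identified* only with at least two matched peptides. The
class logic, applied in order:

1. accession on the contaminant list → `contaminant`;
2. fewer than two peptides → `not_identified`;
3. at least one peptide whose species set lies entirely inside the target
   clade (a *marker peptide*) → `endogenous_specific`;
4. otherwise, any peptide shared with human → `shared_including_human`,
   else `shared_non_human`.

Species sets come from a reference panel (an offline, I/L-normalized
peptide-to-species lookup standing in for an online homology search, which
keeps the pipeline deterministic and network-free). Peptides missing from
the panel are counted, logged, and ignored for the decision. The
classification is total and monotone: adding a clade-unique peptide can
only move a protein toward `endogenous_specific`.

The *conservative contaminant rule* formalizes the precautionary judgment
applied to keratin-like proteins: a `shared_including_human` protein whose
own pooled N/Q deamidation point estimate falls **inside** the contaminant
group's bootstrap CI and **outside** the original group's CI is
reclassified as `contaminant`. Proteins without N/Q evidence are flagged
indeterminate and left unchanged. The CI-overlap criterion is one
admissible formalization of a qualitative "similar profile" judgment; both
CIs are taken from the group-level profile, and with several samples the
widest envelope is used.

# Collagen mapping

## Digestion

In-silico tryptic digestion cleaves after K/R, by default not before
proline, and enumerates all products with up to 3 missed cleavages
(matching the usual search settings for ancient samples, where digestion
is incomplete). Zero-missed products concatenate exactly back to the
input; coordinates are 1-based inclusive.

## Alignment

Observed peptides are placed by a fit alignment: the whole peptide against
the best local window of the reference, scored match +1, mismatch −1,
gap −2, with at most `max_edits = 2` edits (substitutions + indels). This
small-edit model is sufficient to reproduce every published collagen edit
call we use as ground truth, while rejecting spurious placements.
Deterministic tie-breaking: fewest indels, then leftmost placement; the
traceback prefers diagonal steps, so a deletion adjacent to a substitution
is reported in the left-to-right order a reader of the reference expects.
If several placements remain equally optimal (repeated Gly-Xaa-Yaa motifs
make this genuinely possible in collagen) the alignment carries an
`ambiguous` flag while still reporting the leftmost placement.

Edits are reported in mature-chain coordinates via each reference's
`numbering_offset`, so precursor-form FASTA entries can be used directly.
A substitution where the observed residue could equally be a deamidated
form of the reference residue (D observed over N, E over Q) carries an
explicit note — at such sites sequence-level evidence cannot distinguish a
genuine substitution from deamidation.

With `max_edits = 0` the aligner reduces exactly to leftmost substring
search, which the tests verify against `regexpr()` on random sequences.

## Coverage, triplets, diagnostic sites

Coverage is the union of reference positions where an observed residue was
placed: matches always count, substituted positions count by default
(configurable — whether a substituted position is "characterized" is a
judgment call), deleted reference positions never count. Coverage is
monotone in the alignment set.

Gly-Xaa-Yaa validation checks glycine at every third position over
complete triplets; with no frame given, the frame minimizing violations is
chosen. A non-glycine at a triplet start flags either a genuine
helix-destabilizing mutation or a reference-entry error — in practice a
single inserted residue shifts the frame and produces a cascade of
violations downstream, which is exactly the signature that exposes
erroneous database entries.

Diagnostic sites compare observed residue calls against a panel of
references sharing the mature-chain numbering: positions where the
observation differs from *every* panel member are candidate
sample-diagnostic mutations; positions where panel members disagree among
themselves separate the panel species.

# Mass arithmetic

Monoisotopic residue masses, water 18.010565 Da, proton 1.007276 Da.
Neutral mass and m/z interconvert by $M = z \cdot m/z - z \cdot m_p$.
Modification deltas ship as a TSV resource (deamidation +0.98402,
oxidation +15.99491, and the full variable-modification set used for
damage surveys, including kynurenine, iodination and acetylation);
Trp→oxolactone and Tyr→dopaquinone are set to +13.97926 Da (O − 2H) as a
documented convention. Hydroxyproline is represented as oxidation targeted
at P, not as a 21st residue letter.

Published spectra often encode hydroxyproline counts typographically, so
`infer_mod_counts()` searches over oxidation/deamidation multiplicities
for the smallest combination reaching a printed molecular mass within
tolerance — and reports honestly when no combination does (which happens:
printed masses are not always reachable from the printed sequence with
these two deltas alone).

Agreement tolerances: 0.005 Da for m/z↔mass conversion and 0.01 Da for
sequence-level theoretical masses, reflecting that published values differ
from exact recomputation by up to ~3 mDa.

# The synthetic experiment

The generator produces fully labeled data so every stage is testable
without downloads. Its defaults are the study conditions:

* two samples of 500 endogenous + 500 contaminant records each;
* endogenous per-site N/Q deamidation probability drawn once per sample
  uniformly from [0.35, 0.63]; contaminant probability 0.05 — the
  characteristic ancient-vs-modern contrast;
* elevated endogenous oxidation (M 0.30, P 0.25, W 0.20, Y 0.12, C 0.10)
  against low contaminant rates;
* per-species collagen-like references built from Gly-Xaa-Yaa triplets
  with a proline-enriched Xaa/Yaa pool that also contains K/R (so tryptic
  digestion produces peptides) and N/Q/M (so damage has targets);
* log-normal MS1 intensities (meanlog 16, sdlog 1): typical Orbitrap
  magnitudes with the bulk of identified peptides inside about two orders
  of magnitude, consistent with the tight bootstrap intervals damage
  surveys report;
* scores from a two-component normal mixture (true: mean 90, sd 25;
  noise: mean 25, sd 10; 10% noise) so the score-40 filter is exercised
  rather than vacuous;
* a small multi-kingdom taxonomy (endogenous clade, plants, bacteria,
  nematodes, plus human) with a peptide→species panel whose sharing
  structure (clade-unique / cross-clade non-human / human-shared) is
  drawn per peptide with configurable fractions.

Deamidation is simulated per site as independent Bernoulli draws with no
positional or sequence-context effects, and intensity is independent of
modification state. Real data violate both simplifications (deamidation
has strong sequence-context kinetics; modified and unmodified forms of
one peptide appear as separate features whose intensities are coupled), so
passing tests demonstrate correct *estimation* under the stated model, not
that the model captures deamidation chemistry. Identical config + seed
gives byte-identical outputs.

Problem sizes in the test suite — 100 replicate runs at 500 records per
group for the separation and calibration experiments, 1000 random trees
for the LCA oracle, 200 random sequences for the digestion oracle — were
chosen to make the Monte Carlo noise of each check small relative to its
acceptance margin while keeping the default suite quick to run.

# Known limitations

* The aligner's small-edit model will not place peptides with more than
  `max_edits` differences; it is a characterization tool for
  near-reference chains, not a homology search.
* The conservative contaminant rule depends on both group CIs existing;
  datasets without contaminant peptides leave shared proteins unflagged.
* Percentile bootstrap intervals undercover mildly under heavy intensity
  weighting (see above).
* LCA results are only as specific as the peptide→taxa map; the package
  deliberately does not build such maps from live databases.
* Evidence parsing targets a documented TSV subset of the common
  evidence-table dialect; the dialect object absorbs column-name drift but
  not structural changes.
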