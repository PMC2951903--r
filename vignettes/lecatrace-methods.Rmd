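---
title: "Tracing protein complexes to the last eukaryotic common ancestor"
author: "lecatrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing protein complexes to the last eukaryotic common ancestor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The nuclear pore complex (NPC) is built from roughly thirty nucleoporins
(Nups) organised into subcomplexes: cytoplasmic fibrils, the scaffold,
transmembrane anchoring proteins, the nuclear ring, the central channel
and the nuclear basket. Nups are well characterised in yeasts,
vertebrates and plants, but their distribution across the rest of the
eukaryote tree looked patchy for a long time, which left open whether
the last eukaryotic common ancestor (LECA) already possessed a complex
pore. The same question arises for the related vesicle-coating
machinery (COPI, COPII and the clathrin/adaptin complexes), whose
proposed common origin with the NPC scaffold (the protocoatomer
hypothesis) predicts comparably deep conservation.

`lecatrace` implements this comparative-genomic inference as a tested
pipeline with three stages:

1. **Homolog screening.** Position-specific scoring profiles are built
   from curated seed alignments and run against annotated proteomes;
   candidate hits then pass through the vetting rules that matter for
   this protein family — rejection of candidates whose similarity is
   confined to low-complexity repeat regions, required-motif checks and
   reciprocal best-hit validation — before they become presence calls.
2. **Phylogenetic profiling.** Presence/absence calls are organised in
   a binary components-by-genomes matrix, collapsed to the five
   eukaryote supergroups (Opisthokonts, Amoebozoa, Plantae,
   Chromalveolates, Excavates) by OR over member genomes.
3. **Ancestral reconstruction.** Each component's history is
   reconstructed by Dollo parsimony on rooted supergroup topologies,
   under alternative placements of the eukaryote root, with bounds from
   a fully unresolved (star) topology as the most conservative summary.

## The screening model

The screen emulates a profile-HMM search at desk scale with a
position-specific log-odds model. From a seed alignment, columns with
more than 50% gaps are treated as insert states and dropped; each
remaining match column scores residue $a$ as

$$ s_k(a) = \log_2 \frac{p_k(a)}{q(a)}, \qquad
   p_k(a) = \frac{n_k(a) + w\,q(a)}{n_k + w}, $$

with background $q$ (uniform over the twenty residues by default) and a
fixed-weight pseudocount ($w = 1$ by default) so that every score is
finite. Alignment to a protein uses an affine-gap three-state dynamic
programme (match / insertion / deletion) in two modes: *local* (the
best-scoring segment) and *global* (the full profile against its
best-scoring sequence segment). Scores are in bits. The unknown residue
`X` scores zero (background). Ties are broken by leftmost start, then
shortest interval, so results are reproducible and order-invariant. The
kernel is implemented in C++ with full traceback, and is checked in the
test suite against an independently formulated match-anchored
alignment oracle on small instances.

This engine reproduces the *decision structure* of a profile-HMM
screen — the same inputs and the same accept/reject logic — but its
bit scores are not comparable with any particular HMM package's
E-values; the reproducible surface of a published screen is the
presence/absence calls, not tool-specific statistics. For the same
reason the screening threshold is a configuration knob (absolute bits
or a decoy-score quantile), not a fixed constant.

### Vetting rules

Two repeat classes get operational definitions, since the concepts are
standard but no universal pattern exists:

* **FG repeats** — every occurrence of the FG dipeptide (which covers
  the GLFG and FxFG contexts) expanded by ±2 residues;
* **WD repeats** — every match of the anchor `[LIV]x(6,12)WD`, taken as
  a 40-residue window ending at the aspartate.

A hit whose matched positions lie essentially entirely inside repeat
windows (fraction ≥ 0.9 by default) is rejected as
`repeat_only_similarity`, unless a required motif configured for the
component (for example the SIEGR motif of Rae1) occurs outside the
repeat windows. The rejection cutoff of 0.9 rather than 1.0 reflects
that repeat-confined similarity warrants caution, not automatic
discard; a warn tier at 0.75 is also flagged. FG repeats alone are
never sufficient evidence of NPC membership; WD repeats are ancient and
present in all domains of life, so WD-confined similarity is weak
evidence by the same argument.

Surviving candidates are validated reciprocally: the candidate is
aligned (Smith–Waterman, BLOSUM62, via `Biostrings`) against a labelled
reference set — the training-species sequences shipped with the
profiles — and passes only when its best reference carries the
recruiting component's label, with score ties broken by reference id.
A permissive *rescue* stage covers components missed by the primary
screen: donor sequences from related genomes nominate candidates by
pairwise alignment, and nominees are re-scored with the component's
profile at a lower threshold, then re-enter vetting and reciprocal
validation. With the permissive threshold equal to the primary one the
rescue output is by construction a subset of the screen output.

### The decoy null

The screen's accept decision is made per protein, so the relevant null
statistic is the best score a non-homologous protein attains against
any profile in the set. The benchmark in the test suite therefore
calibrates its threshold as the 99th percentile of the per-decoy
*maximum* score over profiles, computed on 500 shuffled-composition
decoys. At that threshold, with planted homologs spanning 20–50%
substitution, the accepted set's false-discovery proportion must stay
within 5% after vetting and reciprocal validation.

## Presence matrices and the shipped surveys

The central object is a binary components × genomes matrix with
optional per-component annotation (subcomplex or coat complex) and a
provenance note; serialization is a deterministic tab-separated format
(mark = presence, empty = absence, case-insensitive on read). The
package ships plain-text transcriptions of a published nucleoporin
survey (31 Nups × 51 genomes), its genome-to-supergroup taxonomy, a
*Trypanosoma brucei* proteomics control set, a fungal anchoring-Nup
survey (3 × 19) with mitosis phenotypes, and a coatomer survey
(27 × 46) with its own taxonomy — genome codes are scoped per fixture,
because the two surveys reuse two-letter codes for different species.

Two curation notes. First, the published tables print their own
checksums (per-supergroup totals in a bottom row, and totals restated
in the text); where the typography of the source tables conflicted with
those printed totals, the transcription was resolved to satisfy them.
One cell was affected: the amoebozoan (*Dictyostelium*) state printed
against Nup155 is carried on the adjacent Nup188 row, which is the
unique single-cell resolution consistent with all printed totals at
once (per-supergroup counts 31/22/26/25/23, nineteen universal
components, ancestral complements of 26 and 23, and five
opisthokont-confined components). Second, the survey's species key
lists the code "Ol" for *Ostreococcus lucimarinus* while the column
itself is headed "Ot"; the fixture follows the column header.

The coatomer survey discusses an Apm2 adaptin paralog restricted to
Saccharomycetes, but prints no Apm2 row; accordingly Apm2 exists only
in narrative form and not in the fixture matrix.

## Dollo parsimony and root sensitivity

Each component is modelled as gained exactly once (Dollo): the gain is
placed on the edge above the last common ancestor of all present
leaves, and losses are the maximal all-absent clades strictly below it;
the cost is one gain plus the number of losses. A component belongs to
the ancestral (LECA) complement exactly when the gain maps to the root
stem — equivalently, for binary-rooted trees, when it is present on
both sides of the root bipartition. Multifurcating nodes are supported
throughout.

Because the position of the eukaryote root is unresolved, complements
are reported under two published alternatives — Excavates basal, and
the unikont/bikont bipartition \{Opisthokonts, Amoebozoa\} versus the
rest — plus the star topology, which only brackets the complement:
the lower bound is the number of components present in *every*
supergroup, the upper bound the smallest per-supergroup count (with the
witnessing supergroup reported). Root-level results depend only on the
root bipartition; the within-side arrangement (default
`((Plantae,(Chromalveolates,Excavates)),(Opisthokonts,Amoebozoa))` for
the unikont/bikont rooting) matters only for attributing individual
gain and loss events to lineages, and is configurable via custom
Newick topologies.

A root state is flagged *ambiguous* when an unrestricted binary
parsimony mapping (gains and losses both allowed at unit cost,
computed by a Sankoff dynamic programme) attains a cost no greater
than the Dollo cost while assigning the opposite root state — the
"(?)" convention of gain/loss figures. Both the Dollo mapping and the
ambiguity rule are verified in the tests against exhaustive
enumeration over all internal-node state assignments, across every
labelled topology with up to four leaves and random topologies up to
the eight-leaf enumeration limit.

On the shipped nucleoporin survey these rules give an ancestral
complement of 26 components under the unikont/bikont rooting and 23
under the excavate-basal rooting, with star-tree bounds of [19, 22]
(the upper bound witnessed by Amoebozoa, the sparsest supergroup). The
components outside the complement under the unikont/bikont rooting are
the five opisthokont-confined ones (Nup358, Pom121, Pom152, Pom34,
Nup37); the survey's own text counts "four gains in the Opisthokonts",
naming all but Nup358 — the package reports the set it computes and
does not force agreement with that count.

Absence in these matrices conflates genuine loss with missing data
(incomplete annotation, rapid divergence); that caveat is inherited by
every loss edge reported, which is why the root-level statements are
phrased over supergroup presence rather than individual genomes.

## Comparative reports

* **Mitosis association.** The fungal anchoring survey shows Ndc1 and
  Pom152 in all 19 genomes while Pom34 is confined to the 12
  ascomycetes — exactly the genomes with closed mitosis. The package
  reports the 2×2 contingency table, a perfect-association flag, and a
  two-sided exact p-value from the conditional hypergeometric null.
  The exact test is an operationalization added by this package (the
  surveys report the pattern, not a statistic) and is labelled as such
  in the output; it is checked against brute-force enumeration over
  margin-preserving tables and against `fisher.test`.
* **Supergroup-level coatomer differences.** Components (or paralog
  groups, collapsed by OR) entirely absent from at least one
  supergroup. The default paralog grouping merges apl1 with apl2,
  because vertebrate Apl1 arose by duplication from the broadly
  distributed Apl2; with that grouping the coatomer survey shows
  exactly two whole-supergroup absences (Sec16 in Amoebozoa; Sfb3 in
  Chromalveolates and Excavates). Grouping is anti-monotone: merging
  paralogs can only remove flagged absences, never add them.
* **Study comparison and rendered summaries.** Per-supergroup counts
  across named studies over a shared component universe, and a
  deterministic plain-text summary that groups components by
  subcomplex and marks the universal ones.

## The synthetic-data generator

The generator exists so that every stage can be tested without
downloads, with known ground truth. It emulates the generative
assumptions behind the parsimony analysis:

* random rooted binary topologies (uniform sequential attachment);
* single-gain/multiple-loss character evolution — one gain edge per
  component (root stem, or uniform over edges), independent per-branch
  loss with probability `p_loss`, loss absorbing;
* detection noise — presences missed with probability `q`, absences
  miscalled with probability `r`. Noise draws are coupled across
  rates (one uniform per cell), so raising `q` flips a superset of
  cells and noise sweeps are monotone by construction;
* synthetic proteomes — per component a planted homolog (profile
  consensus mutated at a configured substitution fraction, indels
  geometric with mean 2) plus three decoy classes: shuffled-composition
  randoms, FG-repeat-only sequences and WD-repeat-window-only
  sequences.

Every randomized operation derives a labelled substream from the master
seed, so outputs are pure functions of (inputs, seed) and adding a
decoy class does not perturb the simulated tree. Default study
conditions are a 16-leaf tree, 100 components, `p_loss = 0.1`, root
gains and noise-free detection, with 240-residue planted homologs at
30% substitution — values chosen once as representative of a
genome-scale complex survey (tens of components, tens of genomes,
moderate loss, homologs well inside the detectable divergence range).

What the generator does **not** emulate: realistic site-specific
substitution processes, domain shuffling, paralogy and gene
duplication, annotation artefacts correlated across genomes, or
lineage-specific rate variation. Passing tests on synthetic data
therefore demonstrate the correctness of the algorithms under the
stated model, not the field accuracy of any particular screen.

## Numerical and design choices

* Pseudocounts: fixed total weight 1.0 of background frequencies — the
  simplest scheme making all log-odds finite; uniform background by
  default, configurable.
* Gap penalties: 4 bits open, 1 bit extend, per column; chosen so that
  a single indel costs about two average match columns.
* Tie-breaks: score descending, then id lexicographic (hit lists and
  reciprocal validation); leftmost start, then shortest interval
  (alignment intervals). Documented and tested.
* Degenerate inputs: empty seed alignments, all-gap profiles, empty
  phenotype classes after dropping unknowns, unmapped genomes and
  unknown supergroup labels are errors, not silent defaults; an
  all-absent character yields a no-event result rather than an error.
* Exact test: hypergeometric probabilities summed over all tables no
  more probable than the observed one (with the customary relative
  tolerance for floating-point equality).
* Problem sizes in the test suite: the alignment oracle runs on
  instances up to 12×12; parsimony enumeration on all labelled
  topologies to four leaves and random topologies to eight; the
  screen benchmark uses 25 components with 100-column profiles and
  500 decoys; noise sweeps use 200 components on 16 leaves. These
  sizes were chosen so the whole suite documents the claimed
  properties at desk scale.

## Limitations

* Bit scores are engine-specific; only presence/absence decisions are
  comparable across screening tools.
* Dollo parsimony has no branch lengths and no rate model; a
  likelihood-based gene-content model could weigh losses against the
  detection-noise caveat, and is out of scope here.
* The reciprocal validation reference is the shipped labelled training
  set, not a comprehensive protein database, so its verdicts are only
  as good as that set's coverage.
* Translated-sequence (six-frame) rescue searches are not implemented;
  the rescue stage is protein-level only.
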