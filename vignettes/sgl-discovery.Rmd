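---
title: "Discovering embedded single-gene lysis ORFs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering embedded single-gene lysis ORFs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sglscan` finds candidate single-gene lysis (sgl) ORFs in levivirus
(ssRNA phage) genomes without homology search, places them in their
genomic context, and supports the downstream comparative analyses —
codon usage, divergence censuses, conservation mapping and
phylogenetics. This vignette is the package's account of the underlying
procedure: the model and its assumptions, every tunable that matters,
the synthetic-data generator that the test suite is built on, and the
choices we made where the design was genuinely open.

## The screening model

Sgl genes are small, fast-evolving, and usually overprinted on a core
gene in a shifted reading frame, so the screen is purely signal-based.
An ORF (any ATG/GTG/TTG start on the plus strand — leviviruses are
positive-sense, so the reverse strand is never scanned — extended to
the next in-frame stop, reported once at its 5′-most start) becomes a
candidate if it passes three criteria:

| criterion | statistic | default pass | relaxed pass |
|---|---|---|---|
| length | protein length (aa, stop excluded) | ≥ 25 | ≥ 10 |
| Shine–Dalgarno | longest contiguous positional match to `AGGAGG`, spacer 4–16 nt | ≥ 4 | ≥ 3 |
| TMD | max mean Kyte–Doolittle hydropathy, 19-residue window | ≥ 1.6 | ≥ 1.0 |

Assumptions and caveats:

* **The SD score is a surrogate for expert judgement.** We slide the
  6-mer window across all spacers in range and take the longest run of
  positional identities to the anti-SD consensus. It is deliberately
  simple, deterministic and tunable (`criteria_config()`); it does not
  model 16S pairing energetics.
* **The hydropathy window is a surrogate for HMM topology
  prediction.** A 19-residue window at mean KD ≥ 1.6 is the classical
  sliding-window recommendation for membrane-spanning segments. It
  calls a hydrophobic stretch, not a topology; marginal or interfacial
  helices will disagree with HMM-based predictors. Proteins shorter
  than the window are scored with one full-length window and flagged.
* **The length boundary is inclusive** (≥ 25 aa, stop excluded) and
  exposed in the configuration, since "25 codons" conventions differ on
  whether the boundary and the stop are counted.
* Relaxed mode retains candidates failing **at most one** criterion
  *under the relaxed thresholds* and records every missed strict
  criterion in a tag (`short`, `no_RBS`, `no_TMD`, comma-joined). This
  mirrors follow-up screens of near-miss candidates.

## The 18-region context taxonomy

Each candidate interval is assigned to exactly one of 18 regions
relative to the `mat`–`coat`–`rep` architecture: region 1 (5′ UTR),
then for gene *i* ∈ {mat, coat, rep} five regions — overlaps the 5′ end
(6i−4), spans the gene (6i−3), fully embedded (6i−2), overlaps the 3′
end (6i−1) — plus, between consecutive genes, a bridge (6i) and an
intergenic region (6i+1), and finally region 18 (3′ UTR). The anchors
are regions 4/10/16 = embedded in mat/coat/rep; the numbering of the
non-anchor regions follows this arithmetic and is isolated in one rule
table (`classify_region()`), so renumbering is a one-line change.

The classifier is a *total, deterministic* function. The tie-breaks,
needed for real leviviral genomes whose genes abut and overlap: an
interval covering several features classifies as "spans" for the
5′-most gene it fully covers; an interval embedded in two overlapping
genes is assigned to the 3′-most of them; bridges are defined by
boundary crossing, so zero-length intergenic gaps still have a bridge
region. Frame offsets ((start − gene start) mod 3) are reported only
for fully embedded candidates; offset 0 is flagged as a same-frame
anomaly. A genome-pair's sgls are S-class when their region indices
match and D-class otherwise.

## MILC

For a gene with sense-codon counts `o_c`, within-amino-acid
frequencies `f_c`, reference frequencies `g_c`, length `L` (sense
codons) and amino-acid degeneracies `r_a`:

* `M_a = 2 Σ_{c∈a} o_c ln(f_c / g_c)` (0·ln(0/g) = 0; single-codon
  amino acids contribute 0),
* `C = Σ_{a present} (r_a − 1)/L − 0.5`,
* `MILC = (Σ_a M_a)/L − C`.

Zero reference cells for amino acids present in the gene receive a
pseudocount (default 0.5) before normalising — avoiding infinities at
the price that a gene matching a sparse reference exactly no longer
yields Σ M_a = 0. The reference usage is, by default, the concatenation
of all annotated CDS of the same genome (self-reference), because the
analysis compares `mat` against `rep` *within* genomes; an external
reference table can be supplied. Σ M_a ≥ 0 always (it is a scaled
log-likelihood ratio with MLE frequencies), and Σ M_a / L is exactly
invariant under count duplication; both are tested.

## Alignment, dot plots, divergence

All pairwise alignment goes through one affine-gap Gotoh kernel
(compiled): a gap of length k costs `open + extend·(k−1)` with defaults
open 10, extend 1; nucleotides score +5/−4 (EDNAFULL-equivalent),
proteins BLOSUM62. Terminal gaps are penalised (true global); an
end-gap-free mode exists as a flag. The traceback tie-break is
deterministic: diagonal over up (gap in the second sequence) over left.
Local alignment is Smith–Waterman under the same scoring; the empty
alignment (score 0) is a legal result. Scores are verified three ways
in the tests: exhaustive enumeration of alignments on tiny inputs, an
independently coded gap-length-scan DP, and `Biostrings`
`pairwiseAlignment` (whose "gap opening" equals our open − extend).

Dot plots follow dotmatcher semantics: every placement of a
`window`-long diagonal window (default 40) whose summed pairwise score
reaches `threshold` (default 50) contributes one point at the window
midpoint (start + ⌊window/2⌋, 0-based). The scan is plus-strand only.
`mist_matrix()` assembles the all-vs-all grid, computing each unordered
pair once.

The divergence census of a global alignment counts mismatched
both-aligned columns as substitutions and each maximal gap run in
either row as one indel event; substitutions + matches + Σ indel
lengths equals the alignment length by construction. Mutation labels
use the field's lowercase-nucleotide / uppercase-residue convention
(`g15t`, `A52D`); classification is per codon using the full mutant
codon, so double mutations within one codon share an amino-acid label.

## Trees and supports

Distances are p-distances (fraction of differing columns, pairwise gap
deletion), with a Jukes–Cantor option; the cladogram use case needs
topology and supports, not branch-length accuracy. NJ is the canonical
Saitou–Nei agglomeration (via `ape`), with negative branch lengths
clamped to zero and flagged. Bootstrap supports resample alignment
columns with replacement, rebuild the NJ tree per replicate, and count
bipartition recovery on the original tree's internal edges; supports
are percentages and reproducible given the seed.

`clades_at_support(tree, cutoff)` applies a *strict* inequality
(support > 80, > 98 in the analyses) and reports each supported
internal edge as a leaf set, orienting edges by rooting at a designated
outgroup (default: the tree's first tip). We deliberately report *all*
supported edges rather than only set-maximal ones: on a poorly
resolved, saturated backbone a weakly supported spurious superset can
otherwise mask a perfectly supported clade nested inside it. Maximal
filtering is available via `maximal = TRUE`.

The progressive MSA (`progressive_msa()`) is intentionally simple: NJ
guide tree on pairwise global-alignment p-distances, then
profile–profile alignment with mean sum-of-pairs column scores under
the same gap costs, fully deterministic. It is adequate for the
moderately diverged synthetic proteins it is tested on; for real,
deeply diverged Rep alignments an external aligner's output can be
ingested via `read_msa()`.

## The synthetic-genome generator

The generator (`generate_genome()`, `generate_cohort()`) is the ground
truth for the whole test suite, so its design is worth stating
precisely.

**Architecture.** Each genome carries `mat` (390–450 codons), `coat`
(120–140) and `rep` (530–560) in order, with 33–60 nt 5′ UTR, 27–45 nt
intergenic spacers and a 30–80 nt 3′ UTR — a 3.2–3.6 kb genome at the
lower end of the real size range. Host proteins draw amino acids
uniformly and codons from a per-genome, per-amino-acid Dirichlet
(concentration 1), so each genome has its own codon-usage bias.

**Dual-frame planting.** A planted sgl must satisfy, simultaneously,
constraints in two reading frames: the host frame must stay stop-free
while the shifted frame (+1 or +2) acquires an ATG, a stop-free body
with a 19-codon strongly hydrophobic stretch (residues from
{I, V, L, F}, each KD ≥ 2.8, so any threshold ≤ 2.8 is met), a
terminal stop, an upstream `AGGAGG` at spacer 6–8, a *guard stop* in
the sgl frame 5′ of the SD, and no start codon between guard and start
(so the scanner's 5′-most-start rule reports exactly the planted
coordinates). Because every shifted-frame codon straddles exactly one
host-codon boundary, all of these are pairwise constraints between
adjacent host-codon choices, and a small dynamic programme over the 64
codons per position finds an assignment minimising host amino-acid
swaps. `plant_sgl()` exposes this with a swap allowance (default ≤ 10%
of the window) and a conserved-motif mask and errors when infeasible;
`generate_genome()` plants with an unbounded allowance, i.e. the host
protein is *defined after* planting, which is the honest description of
simulating a genome from scratch. Region-12 sgls (bridging coat and
rep) use the same machinery over a codon grid that spans the coat 3′
end, a grid-aligned intergenic segment and the rep 5′ end, with the
hydrophobic stretch placed at the tail so it avoids the rep guard
codon.

**Decoys** violate exactly one criterion by construction — too short
(15–22 codons, SD and TMD intact), an all-pyrimidine SD window (match
0), or an all-hydrophilic body (window KD far below the relaxed
threshold) — and are planted away from the sgls, so the relaxed-mode
tags are unambiguous.

**Why the core genes don't screen in.** Each gene start is shielded by
a pyrimidine-only tract across the whole SD search window plus an
in-frame guard stop, so the core ORFs themselves fail the SD criterion
and the strict truth is exactly the planted set.

**Self-verification.** Random background can still, rarely, produce an
ORF passing all three criteria. The generator therefore runs the strict
and relaxed scans on every genome it builds and re-draws from an
attempt-indexed substream on any collision; outputs remain pure
functions of `(config, seed)`, and the attempt index is recorded in the
truth ledger.

**Divergence simulation.** `mutate_pair()` applies per-site
substitutions and geometric-length indels capped at 12 nt. Two choices
serve identifiability of the edit log after re-alignment: indel events
are drawn at least 24 nt apart (twice the cap), and substitutions never
fall inside indel footprints. Protected windows (planted sgls with
their SD regions) receive no edits at all, and a second interval class
can exclude indels only — cohorts use it for all coding genes, on the
biological ground that coding indels are frameshifts purged by
selection; this also keeps annotation liftover exact. Optional
region-specific substitution multipliers emulate elevated 5′-half
(mat) divergence.

**Cohorts.** `generate_cohort()` emits independents first (so default
tree rooting lands outside the planted structure), then a clade of
members diverged from a hidden ancestor, then S-pairs (diverged copies,
sgl context conserved) and D-pairs: the second member's rep-embedded
sgl is *degraded in place* — start codon removed and the reading frame
interrupted by stops every 20 codons, via the same constraint machinery
in minimal-perturbation mode, so only a handful of bases change — and a
new sgl is planted in `mat`. The degraded copy remains a
locally-alignable remnant at high identity, mirroring how lost lysis
genes stay detectable in relatives.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: RNA secondary structure and its effects
on translation; realistic amino-acid composition and genome-wide codon
bias; SD strength as an energy rather than a string match; TMD calls
from topology models; recombination; sequencing error and partial
contigs (partial-genome flags exist but the generator always emits
complete genomes). Results on real genomes additionally depend on
annotation quality of the core genes.

## Numerical choices and degenerate inputs

* RNA input (`U`) is silently normalised to DNA; lowercase is raised.
  Internal coordinates are 0-based half-open; GFF3 I/O is 1-based
  inclusive (printed base `b` ↔ internal `b−1`).
* A leading GTG/TTG is translated M only under `as_initiator = TRUE`
  (bacterial expression context); trailing stops are stripped and
  flagged; internal stops render `*`.
* `N`-containing codons translate to `X` and are skipped (with a count)
  in codon-usage tables.
* MILC errors on `L = 0`; the pseudocount is configurable.
* Empty local alignments are returned as such, never as errors; NJ
  rejects asymmetric matrices and clamps negative branch lengths;
  all-gap alignment columns score 0 conservation; bootstrap supports of
  unresolvable splits are 0, not NA.
* Exact-agreement tests use tolerance 1e−12 (MILC vs hand computation);
  alignment-score oracles are compared exactly.

## Problem sizes in the test suite

The suite's heavier checks use sizes chosen to exercise the claims
convincingly while keeping a full run to a few minutes: 200 generated
genomes (seeds 1..200) for planted-candidate recovery; 50 random 5 kb
sequences against the brute-force ORF oracle; the complete interval
grid at 3 nt resolution for the region classifier; all sequence pairs
of length ≤ 6 over {A, C} against independent alignment oracles; 50
mutation simulations for the divergence census; bootstrap n = 1000 for
the planted 2v2 split and the 20-genome cohort with its 12-member
clade. `scripts/acceptance.R` re-measures the same quantities from
scratch (150-genome screen) and writes them as JSON.

## Known limitations

* At the divergence-census simulation load (substitution rate 0.05,
  indel rate 0.01), score-optimal re-alignment occasionally converts a
  chance cluster of substitutions into a balanced 1-nt
  insertion/deletion pair, overcounting indel events by two in a few
  percent of simulations; substitution counts stay within ±10%. This is
  inherent alignment ambiguity, not an edit-log defect, and the test
  suite reports it rather than hiding it.
* The SD and TMD scores are deliberately simple surrogates (see above);
  borderline real candidates deserve inspection with dedicated tools.
* The progressive MSA is not a substitute for a production aligner on
  deeply diverged proteins.
* The 18-region numbering beyond the anchored regions 4/10/16 is a
  package convention, kept in a single rule table.
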