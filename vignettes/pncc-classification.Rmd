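---
title: "Block-based classification of NMN deamidases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based classification of NMN deamidases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pncctools)
```

This vignette documents the models, parameters and design decisions behind
`pncctools`. The package operationalizes a fingerprint view of the NMN
deamidase (PncC) family: short conserved sequence blocks, rather than
overall identity, carry the signal for domain architecture, catalytic
competence and lineage membership.

## The block model

A block is a short run of alignment columns with high information content
whose consensus is written in a degenerate grammar: uppercase letters are
majority residues, a trailing `!` marks strict conservation, `[XY]` an
alternative pair, lowercase `c`/`h`/`p` a residue class, and `x` any
residue. The class memberships are a standard physicochemical partition —
charged {D,E,K,R,H}, hydrophobic {A,V,L,I,M,F,W,C,Y}, polar/small
{S,T,N,Q,G} — kept in one constant (`residue_classes()`) so the choice is
auditable; the source figures define the codes but not the membership.

Scanning (`scan_motif`) scores a placement as the fraction of matched
non-wildcard positions; strict positions additionally veto. The default
`min_score = 0.7` admits one mismatch in short blocks while random hits at
that stringency are rare enough not to disturb architecture calls (chance
hits do occur for the shortest patterns; see the chain selection below).
Bold positions in the family's published consensus strings are encoded as
strict; where prose and figure legends disagree on bolding, the prose
reading was kept and the entry's note records the interpretation. An
ambiguous `X` in an input sequence counts as a mismatch at any non-wildcard
position — conservative, because a functionality call should not pass a
residue check it cannot see.

## Conserved-block detection

Column information content is the sequence-logo height basis
R = log2(20) − H, with gaps excluded from the frequencies, columns more
than half gaps scored 0, and an optional small-sample correction
(s−1)/(2·ln2·n) that is off by default so worked examples are exact.
Blocks are maximal runs of columns with R ≥ `min_bits` (default 2.0 bits)
that start and end on a conserved column; up to `max_low_cols` consecutive
sub-threshold columns are tolerated inside a block, and blocks shorter than
`min_len = 3` columns are dropped.

`max_low_cols` defaults to 3 because the canonical catalog itself contains
wildcard runs of up to three columns (M-I and P-IX both contain `xxx`);
wildcard columns are unconserved by definition, so any smaller tolerance
necessarily fragments those blocks regardless of the data. Linkers between
blocks in realistic alignments are many columns long, so this tolerance
does not merge neighboring blocks.

Consensus extraction uses `strict_threshold = 0.95` and
`majority_threshold = 0.6`: a single residue at ≥95% becomes a strict
literal, at ≥60% a plain literal, two residues jointly at ≥60% a bracket
pair, a residue class at ≥60% the class code, else `x`. Detected blocks are
labeled by best positional agreement (per-position Jaccard overlap of
allowed sets over the best gapless offset, normalized by the longer
pattern) against all catalog entries; near-ties resolve in favor of the
candidate that keeps the canonical block order increasing, and blocks
agreeing with nothing above 0.5 stay unlabeled.

## Architecture, functionality, lineage

Blocks matched along a sequence are chained by a longest-increasing-
subsequence selection over one global canonical axis (MocF 1–7, then
interdomain, then CinA 1–9), with total match score breaking length ties.
Joint selection matters: a chance hit of a short pattern far from its
canonical position cannot displace a true block, because it would have to
be ordered against the rest of the chain. The MocF domain is called
present at ≥4 of 7 blocks in order, CinA at ≥5 of 9; the thresholds, and
the N-extension cutoffs of 30/80 residues separating plain single-domain
enzymes from short- and long-extension forms, are this package's
operationalization of the family's qualitative architecture classes
(~160–170 aa single-domain, ~220 aa extended, ~420 aa two-domain) — the
source analysis never states numeric detection criteria, so all are
configurable arguments. A CinA series interrupted by a ≥40-residue spacer
between consecutive chained blocks is called split (the fungal form).

Functionality is a ten-residue checklist at pattern-relative offsets in
the canonical CinA blocks — S31 (P-I), G46/S48 (P-II), Y58/N60/K63
(P-III), S/T105/G106 (P-VI), G120 (P-VII), R145 (P-VIII), single-domain
reference numbering — plus three documented inactivating signatures:
Y58F+N60D with the DTP replacement of P-II (YdeJ-like), deletion of
P-III/P-V/P-VII with a degenerate P-II (YfaY-like), and alanine at the
S31-homologous position of P-I (fungal). All checks passing gives
`active`; a fired signature gives `inactive`; anything else — missing
blocks, an `X` at a key offset — is `indeterminate`. A checklist block
whose match was lost to substitutions is still located by a relaxed scan
between its chained neighbors so its residues can be inspected at the
homologous offsets; signature absence conditions are evaluated only on
chain-consistent matches for the same reason.

Lineage assignment is a decision table: MocF-only → 1.3 (archaeal),
inactive two-domain → 2.2.1.2, inactive single-domain → 2.2.2.2,
short/long extension → 2.2.3.2/2.2.3.3, split → 2.2.3.4. The remaining
active two-domain ({1.1, 1.2, 2.1, 2.2.1.1, 2.2.2.3}) and single-domain
({2.2.2.1, 2.2.3.1}) candidates are scored by lineage-specific variant
fingerprints; since the family distinguishes most of these groups
phylogenetically rather than by sequence fingerprints, ties are broken by
an optional taxonomy hint (Firmicutes → 1.2, Actinobacteria → 2.2.2.3,
Cyanobacteria and relatives → 2.1, Bacteroidetes/Spirochaetes/Thermotogae
→ 1.1, Gamma- vs Alphaproteobacteria separating 2.2.1.1/2.2.2.1 from
2.2.3.1), then by the most similar reference exemplar (3-mer Jaccard
similarity as a cheap placement proxy), else the record is reported
`unassigned` with zero confidence rather than forced. Hints are metadata
only and are never inferred from sequence, so sequence-only runs remain
self-contained. Whether lineages 2.1 and 2.2.1.1 are separable by
fingerprints at all is left open; the classifier reports low confidence
there by construction.

## Phylogeny

Pairwise alignment is a Gotoh affine-gap dynamic program (global and
local), scoring a gap of length k as open + k·extend with BLAST-comparable
defaults (BLOSUM62, 11/1), deterministic traceback preferring diagonal.
Distances from alignments are p-distances (default) or the Poisson
correction −ln(1−p); the default is the simpler model because the source
analysis does not state its correction. Neighbor-joining follows the
Saitou–Nei Q-criterion with standard branch-length formulas, lowest-index
tie-breaking, the three-point resolution of the final triple, and negative
branch estimates clamped to zero with a warning. Bootstrap supports
resample alignment columns with replacement under one seeded stream after
canonicalizing taxon order, so supports are invariant to input order. The
reference analysis ran 1000 bootstrap generations; the analysis driver
uses 200 replicates on panels where supports are already saturated, and
the replicate count is an argument everywhere.

## Kinetics

Initial-rate data only (the assays report initial velocities):
Michaelis–Menten v = kcat·E₀·S/(Km+S) and Hill v = Vmax·Sⁿ/(S₀.₅ⁿ+Sⁿ) are
fitted by Levenberg–Marquardt least squares initialized from the
double-reciprocal and Hill-plot linearizations respectively, with
estimates, asymptotic standard errors and kcat/Km reported. The coupled
glutamate-dehydrogenase assay converts an absorbance slope at 360 nm to a
molar rate through ε = 4320 M⁻¹cm⁻¹, and one unit is 1 µmol NADPH/min;
when the enzyme is given as a mass, kcat uses the 47.32 kDa subunit mass.
Ligand efficiency is the docking score over the heavy-atom count, with
heavy atoms counted from molecular formulas shipped as constants (NMN
C11H15N2O8P → 22; ADP-ribose C15H23N5O14P2 → 36) so no cheminformatics
dependency is needed. LE1 is reported round-half-even to three decimals;
for ADP-ribose the exact quotient −3.27564 therefore prints as −3.276
where the source prints −3.275 (apparent truncation) — the package
documents rather than imitates the truncation.

## The synthetic-data generator

Panels are assembled per lineage from the catalog's variant set: linkers
drawn from a uniform residue background with per-gap length ranges
calibrated so realized lengths land in the family's observed classes
(~165/~210–250/~420/~170 aa), block positions realized from their allowed
sets, strict positions never mutated, and other block positions
substituted at a configurable rate (default 0.05 — typical within-lineage
block variability; 0 gives exact closed-loop panels). Documented
key-residue offsets are also never mutated: a lineage labeled `active`
must by definition conserve its catalytic residues, so noise there would
contradict the truth labels the panels exist to provide. Inactive lineages
carry their signatures by construction, and the fungal lineage inserts a
45–60 residue spacer inside the CinA series. Indels default off; because
all sequences of a lineage share one segment plan, the known-truth
alignment is exact by construction, with linkers right-padded by gaps.
Truth tables record both full and wildcard-trimmed block coordinates —
edge wildcards are unconserved and hence undetectable, so boundary
recovery is defined against the trimmed spans.

What the generator does **not** emulate: substitution-model evolution down
a tree (no among-site rate variation, no correlated substitutions),
realistic linker homology within lineages, indel-driven misalignment, or
compositional bias. Tests passing on these panels therefore demonstrate
that the pipeline's logic is correct under its own stated model, not that
real proteomes will classify with the same accuracy; in real data,
linker-region homology and annotation noise will matter.

## Scale of the shipped analyses

The analysis drivers and tests run at desk scale by design: panels of 20
sequences per lineage, 13-lineage combined panels of 65 sequences,
10-taxon bootstrap trees with 200 replicates, and 100-fit bias studies at
60 seeded replicates. The family-wide analyses they stand in for (hundreds
of database sequences, database distribution percentages) depend on
database snapshots and are out of scope here; the acceptance script and
test suite recompute only quantities that are reproducible from first
principles.

## Known limitations

* The catalog encodes one reading of typographically inconsistent
  consensus strings; entries carry notes where the interpretation was not
  forced. The family names thirteen terminal lineages while its own
  summary counts twelve subgroups; the catalog ships all thirteen labels
  and does not adjudicate.
* Variant sets are incomplete for some blocks in some lineages (e.g. P-V
  is simply absent in 2.2.1.2); the generator omits rather than invents
  variants, as recorded in the truth schema.
* Fingerprint-ambiguous lineage pairs are resolved only via taxonomy hints
  or reference exemplars; sequence-only calls there are honest
  `unassigned`s.
* The motif engine is ungapped by design (no profile HMMs, no
  position-specific scores); sequences with insertions inside a block will
  lose that block rather than match it approximately.
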