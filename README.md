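# pncctools

Molecular classification and enzyme kinetics of NMN deamidases (the PncC
family) in R.

## The problem

NMN deamidase (PncC, EC 3.5.1.42) hydrolyzes nicotinamide mononucleotide
(NMN) to nicotinic acid mononucleotide and ammonia, feeding the
Preiss–Handler route of NAD⁺ salvage in bacteria. The family is widespread
but heterogeneous: enzymes occur as a single catalytic CinA domain
(~160–170 aa), as CinA fused downstream of a MocF domain (~420 aa, the MocF
part being an ADP-ribose pyrophosphatase), as CinA with short or long
N-terminal extensions (~220 aa), as a CinA split in two by an inserted
spacer (fungi), and as catalytically dead versions of the one- and
two-domain forms. Because overall sequence identity is low, the family is
best fingerprinted by short conserved blocks: seven in the MocF domain
(M-I…M-VII), two in the interdomain segment (i-I, i-II) and nine in the
CinA domain (P-I…P-IX), written in a degenerate consensus notation such as

```
M-III  G!G!L!G!P!T!xD!D!xT        P-I  A!E!S!CTGG!
M-IV   Nx[KR]QA  (archaea: R!xK!M!A!xxP!)
```

where `X!` is strictly conserved, `[XY]` an alternative set, `c/h/p` a
residue class and `x` any residue. Documented substitutions inside these
blocks (e.g. Y58F + N60D in block P-III, single-domain reference numbering)
predict loss of deamidase activity.

`pncctools` implements this fingerprint system end to end, for anyone who
wants to classify PncC-like sequences or re-derive the family's block
structure and kinetics from scratch:

* a parser/scanner for the block-consensus grammar (`parse_pattern`,
  `scan_motif`) and the full curated block catalog with per-lineage
  variants and active-site key residues (`load_catalog`);
* sequence-logo information content, conserved-block detection and
  consensus extraction on multiple alignments (`column_information`,
  `detect_blocks`, `consensus_string`, `label_blocks`);
* domain-architecture calling, active/inactive prediction from the
  ten-residue active-site checklist plus inactivating signatures, and
  lineage assignment over the family's thirteen named lineages
  (`call_architecture`, `call_functionality`, `assign_lineage`,
  `classify_sequences`);
* affine-gap Needleman–Wunsch/Smith–Waterman alignment, p/Poisson
  distances, neighbor-joining and bootstrap supports (`pairwise_align`,
  `msa_distance`, `nj_tree`, `bootstrap_support`);
* Michaelis–Menten and Hill kinetics for the coupled
  glutamate-dehydrogenase assay, v = kcat·E₀·S/(Km+S) and
  v = Vmax·Sⁿ/(S₀.₅ⁿ+Sⁿ), fitted by nonlinear least squares
  (`fit_mm`, `fit_hill`), absorbance-to-rate conversion
  (ε₃₆₀ = 4320 M⁻¹cm⁻¹) and ligand-efficiency arithmetic
  (`ligand_efficiency`);
* a seeded synthetic-data generator producing labeled per-lineage panels,
  known-truth alignments and noisy rate tables (`simulate_lineage_panel`,
  `simulate_panel`, `generate_truth_alignment`, `simulate_rates`), so the
  whole pipeline is testable without any downloads.

## Worked example

Classify a small synthetic panel of single-domain enzymes:

```r
library(pncctools)
pan <- simulate_lineage_panel("2.2.3.1", n = 3, seed = 1)
classify_sequences(pan$sequences)
#>   sequence_id length architecture functionality    lineage confidence
#> 1  2_2_3_1_01    160    CINA_ONLY        active unassigned          0
#> 2  2_2_3_1_02    159    CINA_ONLY        active unassigned          0
#> 3  2_2_3_1_03    160    CINA_ONLY        active unassigned          0
```

Each sequence is recognized as a plain single CinA domain with all ten
active-site residues intact. The lineage stays `unassigned` because active
single-domain enzymes occur in two lineages that differ only in their
phylogenetic placement; passing `taxonomy = c(...)` hints (here
Alphaproteobacteria → 2.2.3.1) resolves the tie.

Refit the enzyme's kinetic constants from noisy synthetic initial rates
(`analysis/05_kinetics.R` prints):

```
MM refit: Km = 0.185 +/- 0.004 mM, kcat = 0.385 +/- 0.003 s^-1, kcat/Km = 2.08 mM^-1 s^-1
Hill refit: S0.5 = 6.09 uM, nH = 2.47 +/- 0.05
NMN: LE1 = -5.548; ADP-ribose: LE1 = -3.276
```

i.e. the generating constants (Km 0.18 mM, kcat 0.38 s⁻¹; S₀.₅ 6 µM,
nH 2.6) are recovered within their published uncertainties, and the ligand
efficiency of NMN (MolDock score −122.053 over 22 heavy atoms) is −5.548.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end on
synthetic data and write their tables under `results/`:

1. `01_simulate_panels.R` — labeled per-lineage panels and a combined
   13-lineage panel;
2. `02_conserved_blocks.R` — information content, block detection and
   labeling (recovers exactly M-I…M-VII and P-I…P-IX);
3. `03_classify_panel.R` — full classification with confusion matrices
   (diagonal at zero noise; ≥95% recovery at 5% substitution noise);
4. `04_phylogeny.R` — p-distances, NJ tree, bootstrap supports;
5. `05_kinetics.R` — Michaelis–Menten/Hill refits, assay unit conversion,
   ligand efficiencies.

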