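---
title: "Methods: annotating and classifying cyanophage and cyanobacterial sHSPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and classifying cyanophage and cyanobacterial sHSPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoshsp)
```

## The biological problem

Small heat shock proteins (sHSPs) are 12–42 kDa oligomeric chaperones built
around a conserved ~90-residue α-crystallin domain (ACD), a β-sandwich of
strands β2–β9, flanked by a variable N-terminal arm and a short C-terminal
extension. Marine cyanophages — myoviruses infecting *Synechococcus* and
*Prochlorococcus* — carry their own sHSP genes, and these viral sHSPs have
recognizable sequence features: a 16-residue signature,
`P-P-[YF]-N-[ILV]-[IV]-x(9)-[EQ]`, in the β2/β3 region of the ACD; an A-G
doublet with an L/aromatic context otherwise typical of bacterial class A
(and animal) sHSPs; a conserved β7 arginine that can form a salt bridge
with acidic residues of the partner monomer's L57 loop (reference columns
109–121, most plausibly column 117); and, in many of them, a classical
C-terminal anchoring module (CAM) `L-X-[ILV]` in the extension. Their
cyanobacterial hosts instead carry a P-G doublet (the plant / bacterial
class B marker) and frequently a "triple" CAM, three hydrophobic residues
`[IV]-X-[ILV]-X-[ILV]`, instead of the classical pair. This package turns
those observations into a reusable, tested pipeline: pattern scanning,
architecture delimitation, motif detection, rule-based classification, and
a distance phylogeny restricted to the ACD + C-terminal extension.

## Pattern engine

PROSITE-style patterns are parsed into an element list (fixed residue,
residue class, fixed-length wildcard run `x(n)`); ranges `x(a,b)` and
anchors are deliberately unsupported — the grammar is the smallest one
that covers the signature. Scanning reports *all* matches, including
overlapping ones, so downstream rules never lose evidence; `X` in a
sequence matches only wildcard positions, the conservative treatment of
ambiguity. The classifier records which region a signature hit falls in
but does not require it to lie in β2/β3; the requirement is not part of
the signature's definition, and on diverged sequences the profile-mapped
strand coordinates are approximate.

## Architecture delimitation

The ACD locator is an ungapped log-odds position-specific scoring matrix
(PSSM), not a profile HMM: it is deterministic, fast, exactly testable
against closed forms, and sufficient for a domain that the family aligns
without internal indels at this scale. The score of residue $a$ in column
$j$ is

$$ s_j(a) = \log \frac{(c_{j,a} + \kappa\, b_a)/(N_j + \kappa)}{b_a}, $$

with pseudocount weight $\kappa$ (default 1) and background $b$ (default
uniform over the 20 amino acids, so a uniformly occupied column scores
exactly zero). Columns with ≥ 50 % gaps are dropped. The full 92-column
profile is slid along the sequence; the best-scoring placement (ties →
leftmost) is the ACD, everything before it the N-arm, everything after it
the C-terminal extension, so the three regions always partition the
sequence. Strand intervals (β2–β9), the L57 loop and the β7-arginine
column are *data*, shipped as a reference-map fixture in
reference-alignment coordinates and projected through the window offset;
"residues 109–121" are treated as reference-alignment columns, and the
packaged synthetic reference is laid out (54-column arm, ACD columns
55–146) so that the L57 loop occupies exactly columns 109–121 and the
acidic-partner column is 117. The packaged profile and map are labelled
`*_synthetic` because they are built from the simulator's templates; a
profile calibrated on real cyanophage sequences can be swapped in as a
plain FASTA/TSV pair without code changes.

## Motif detection

All finders are exhaustive window enumerations with explicit coordinates:

* **CAMs** are searched only in the C-terminal extension, where they are
  biologically meaningful (they dock into the β4/β8 groove of the
  neighbouring dimer). Kinds: classical `L-X-[ILV]` (the Abstract-style
  `L-X-I/V` is subsumed), the non-classical pairs `A-X-P`, `L-X-G`,
  `L-X-A`, and the cyanobacterial triple `[IV]-X-[ILV]-X-[ILV]`. Overlaps
  are reported and a triple never suppresses the pairs inside it.
* **Doublets** A-G and P-G are searched in the ACD plus 10 flanking
  residues on each side — the doublet's exact position is not fixed a
  priori, so a permissive window is used and the hit's region recorded,
  letting downstream rules tighten later. Context flags mark a preceding L
  and a following F/Y/W.
* **β7 residue**: the residue at the mapped β7-arginine column, with
  `is_R`, `is_basic`, `is_N` flags (covering the lysine and asparagine
  exceptions seen among real phages).
* **Acidic partners**: every D/E in the mapped L57 interval, each tagged
  with its reference column and an `at_117` flag.

## Classification cascade

First match wins: (1) signature hit → `cyanophage_like`; (2) triple CAM
*and* P-G → `cyanobacterial_like`; (3) A-G → `bacterial_class_A_like`;
(4) P-G → `class_B_plant_like`; (5) `unclassified`. The signature leads
because it is the only marker specific to one group; doublets are shared
across kingdoms. A sequence carrying both doublets resolves to the A-G
rule — a documented tie-break, not a biological claim — and the class-A
label is explicitly "class A / animal-type", since the aromatic-flanked
A-G context occurs in animal sHSPs too. Every result carries the hits
that fired the rule, so calls are auditable.

## Alignment and phylogeny

Pairwise alignment is global Needleman–Wunsch with affine gaps (BLOSUM62,
gap open 10, extension 0.5 — configurable; no parameters are prescribed by
the underlying observations). Multiple alignment is delegated to MAFFT
with fixed deterministic options. For phylogeny, only the ACD +
C-terminal-extension columns are used: a column is kept when ≥ 50 % of
rows place an in-region residue there, and arm residues inside kept
columns are masked to gaps — an explicit, testable rule for a step that is
otherwise often done by eye. Distances are Poisson-corrected
$d = -\ln(1-p)$ with $p$ the mismatch fraction over shared ungapped
columns; saturated pairs ($p \ge 0.95$) are capped at $d = 10$. Trees are
BioNJ (variance-weighted neighbour joining); negative branch lengths are
clamped to zero (the deficit is *not* re-assigned to the sibling — a
simplification that cannot affect additive inputs, on which NJ is exact).
Monophyly uses the unrooted convention: a set is monophyletic iff some
edge bipartition separates exactly that set, so a set and its complement
give the same answer. Likelihood trees, aLRT supports and branch
collapsing are out of scope.

## The simulator and what it does (not) show

`simulate_family()` generates labelled families from four 160-residue
class templates sharing one layout — arm 1–54 ending in the conserved
double proline, ACD 55–146, extension 147–160 — with the class markers
planted at fixed coordinates and roughly half of the non-marker core
positions differing between classes, mimicking deep between-class
divergence. Each class evolves from its template down a Yule subtree
(birth rate 1); the four subtrees hang off a fixed backbone so every class
is a planted clade. Along each branch every site substitutes with
probability μ (default 0.05) to a uniformly drawn different residue;
motif columns substitute with probability ρ·μ (default ρ = 0.1),
modelling purifying selection on the markers. Indels are off by default so
that planted coordinates stay exact; the uniform substitution model means
Poisson distances are systematically biased but monotone, which is all
topology recovery needs. The simulator does *not* emulate realistic
residue composition, rate heterogeneity, empirical exchangeabilities or
indel processes — passing its benchmarks demonstrates the correctness of
the machinery, not performance on real proteins.

Because the default simulator output is indel-free, its columns are
homologous by construction; replicate-heavy benchmarks therefore use the
records directly as an alignment (`run_pipeline(aligner = "none")`), while
MAFFT remains the default for any other input. Benchmark sizes — a
4 × 50 family for classification and ACD recovery, 100 replicate 4 × 6
families for clade monophyly, 100 random 6–12-taxon additive matrices for
BioNJ — were chosen as the smallest sets that give stable rates.

## Known limitations

* Marker erosion compounds along the tree: with per-branch motif
  substitution probability ρμ, a leaf ~9 edges below its class root loses
  at least one of the seven constrained signature positions a few percent
  of the time each, so even at ρ = 0.1 a noticeable minority of
  cyanophage-class leaves lose the signature and fall through to the A-G
  rule. Label recovery at the default benchmark is therefore high but not
  perfect — the cascade classifies by presence/absence and has no
  error-tolerant matching.
* The packaged profile and reference map are synthetic; coordinates on
  real sequences (e.g. the β7 column) need calibration against fetched
  catalog sequences, for which the network-gated `fetch_catalog_sequences()`
  is provided.
* The ungapped PSSM cannot model internal indels in the ACD; sequences
  with such indels will still get a single best window, possibly shifted.
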