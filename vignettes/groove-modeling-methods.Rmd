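---
title: "Methods: homology modeling of HLA peptide-binding grooves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology modeling of HLA peptide-binding grooves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its modeling procedure:
the assumptions it rests on, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the test
suite does and does not establish.

## The modeling problem and its central assumption

HLA molecules fall into two architectures: class I (a heavy chain whose
α1+α2 domains form the peptide-binding groove, plus the invariant
β2-microglobulin) and class II (an αβ dimer whose α1 and β1 domains
form the groove). Across alleles the groove's fold — a β-sheet floor
flanked by two long helices — is strongly conserved, while sequence
differences concentrate in the pocket-lining residues. The package
therefore models the *groove first*: template selection, backbone
inheritance and validation all operate on the binding-site residues by
default, and whole-chain modeling (`scope = "all"`) exists mainly so
the two strategies can be compared by the leave-one-out harness.

The second structural regularity the package leans on is that peptides
bound to class II grooves adopt nearly the same extended backbone: a
conserved core of eight consecutive positions spanning the P1, P4 and
P6 anchor residues. This is what makes *threading by registration*
sound: a query peptide is slid along the template peptide backbone and
only the offset — never the conformation — is searched.

## Pipeline stages and their parameters

### Template selection

The query is globally aligned to each candidate's groove chain(s) with
the Needleman–Wunsch algorithm under BLOSUM62, gap open 10, gap extend
1 (the standard protein defaults; both configurable). Percent identity
is computed over aligned columns where neither side is a gap. The
denominator convention was an open choice — common alternatives divide
by the full alignment length — and the gap-free-column convention was
chosen because it is the most widespread and does not penalise terminal
overhangs when a full-length query is compared against a groove-only
template. A whole-chain identity mode exists alongside the default
binding-site mode.

Two determinism choices worth recording:

* **Symmetric alignments.** Distinct optimal tracebacks for (a, b) and
  (b, a) can differ in their gap placement and hence in identity. The
  package canonicalises the pair order lexicographically before
  aligning and swaps the result back, so `identity(a, b)` equals
  `identity(b, a)` exactly and self-identity is exactly 100.
* **Template ties** are broken by better (smaller) crystallographic
  resolution, then more recent deposition date, then pdb id.

### Binding-site definition

Class I: heavy-chain author residues 1–180 (α1+α2). Class II: α-chain
1–84 and β-chain 1–90 (α1+β1). These are the canonical domain
boundaries; they are data, not code — `binding_site_definition()`
accepts arbitrary ranges per chain role, inclusive, in author
numbering.

### Chain classification

Roles are assigned by deterministic residue-count rules (class I heavy
chain 260–300, β2-microglobulin 95–105, peptide 8–25, class II groove
chains 150–230, leftover long chains are T-cell receptor chains once a
groove is found). Of the two class II groove chains the shorter is
taken as α — true of the DR/DQ/DP crystal constructs this tool targets,
but a heuristic; database metadata can state roles explicitly
(`roles = "A=class2_alpha;..."`), which bypasses the rules entirely and
is what the synthetic fixtures do.

### Segment-matching construction

Aligned residues inherit the template backbone verbatim. Unresolved
segments (query insertions, template residues lacking backbone) are
rebuilt with ideal bond lengths and angles in torsion space:

* Candidate (φ, ψ) pairs are mined from the template structures
  (fragment length `segment_length`, default 6 residues) and pooled
  with canonical secondary-structure and turn values.
* Combinations are enumerated (capped at 4096, sampled beyond that),
  and the best few are refined by derivative-free minimisation of the
  anchor mismatch — the squared distance between the predicted and
  actual N and CA of the right anchor residue.
* The peptide bond torsion ω is allowed to deviate from trans during
  closure, under a quadratic penalty (weight 3·10⁻⁴ per deg²). This is
  deliberate: tight bulges — e.g. an insertion between two template
  residues that are directly bonded — are geometrically unreachable
  with rigid ideal geometry, and the subsequent relaxation re-idealises
  the strain. A closure whose joining-bond length error still exceeds
  1 Å raises an "unclosable" error reporting the gap.
* Terminal segments (one anchor) are grown with extended-chain
  torsions; in binding-site scope, query overhangs beyond the template
  groove are trimmed instead of modeled.

Side chains: identical aligned residues copy template coordinates
verbatim; substituted or rebuilt residues are placed from a rotamer
grid (staggered χ values −60°/60°/180°, aromatic χ₂ ±90°) minimising a
soft clash score (quadratic penalty inside 2.9 Å); ties keep the first
rotamer, and the best rotamer is accepted even if clashed (relaxation
deals with the rest).

### Relaxation

A deliberately simple, fully deterministic energy: harmonic bond
restraints (k = 100 kcal/mol/Å²) on the covalent structure, soft-sphere
repulsion (k = 25 kcal/mol/Å²) between atoms more than three bonds
apart that approach closer than 2.8 Å (2.6 Å for N/O pairs, which may
hydrogen-bond), and harmonic tethers (default `tether_force_constant`
10 kcal/mol/Å²) anchoring every non-hydrogen atom to its pre-relaxation
position. Steepest descent with a backtracking line search guarantees
non-increasing energy; the step limit is `relaxation_steps` (default
200). The tether default is a compromise: strong enough that a
clash-free inherited backbone essentially does not move (the
self-modeling tests bound the drift), weak enough that 1 Å steric
overlaps resolve beyond 1.8 Å separation.

This relaxation is the package's geometry-regularisation model, not a
molecular-mechanics force field: its energies mean nothing outside the
minimisation and are never reported or compared.

### Candidate generation and the hydration score

`n_candidates` models (default 10) are built per query. Candidate 0 is
unperturbed; later candidates jitter the closure torsion starts (σ =
8°) and the chosen rotamer χ angles (σ = 4°) under per-candidate seeds
derived as `seed + index`, which makes every coordinate reproducible
and candidate 0 independent of `n_candidates`. Each relaxed candidate
is scored by an atomic-solvation hydration score: Σᵢ σᵢ·SASAᵢ with
σ(C) = +16, σ(S) = +21, σ(N/O) = −6, σ(carboxylate O) = −24,
σ(charged N) = −50 cal/(mol·Å²) — exposed apolar surface is penalised,
exposed polar surface rewarded — and the minimum-score candidate is
kept. SASA uses Shrake–Rupley-style sampling with a deterministic
Fibonacci lattice of 960 points per atom and a 1.4 Å water probe; an
isolated atom recovers 4π(r+probe)² exactly because every lattice point
is exposed.

### Peptide threading and complex ranking

All |T|−|Q|+1 gapless registrations of the query peptide along the
template peptide are built (gapless because the conserved core makes
internal indels in the groove-bound span implausible). Per
registration: backbone copied from the template peptide at aligned
positions, side chains placed against the groove, then tethered
relaxation — jointly over groove and peptide by default; a
`peptide_only` mode holds the groove fixed (which of the two the
original strategy used is unknowable from the outside; joint relaxation
was chosen as the default because the groove also adapts in reality).
The interface score is buried-surface based:
S(complex) − S(groove) − S(peptide) − w·(contact pairs within 4 Å),
w = 0.02. Non-interacting partners score exactly 0 (SASA additivity);
burying apolar surface drives the score negative. Only the arg-min over
registrations is meaningful, and that is all the pipeline uses.

The conserved 8-residue core defaults to template-peptide positions
2–9, putting P1, P4 and P6 at positions 3, 6 and 8 and leaving one
flanking position before P1; the window start is configurable
(`core_start`). Peptide termini protruding from the groove are built
but excluded from core RMSD statistics.

### Validation machinery

Superposition is the Kabsch algorithm (SVD with reflection correction);
RMSD is always computed over non-hydrogen atoms, with the superposition
fitted on the same atom set the RMSD is reported over. Atom pairing
matches by (chain role, author residue number, atom name) and reports
unmatched atoms plus a coverage fraction, so models with missing
residues are compared honestly. The leave-one-out harness excludes only
the target itself from the template pool ("all structures of the same
class except the identical one"); redundancy filtering beyond that is
left to the user's database curation, since any non-redundancy
criterion would be a guess.

The bound-peptide conservation statistic superimposes each peptide's
core main-chain atoms (N, CA, C, O — 32 atoms) onto the first peptide
in pdb-id order and reports the per-position median RMSD across
peptides; the reference peptide contributes no self-comparison, and an
even count of comparisons takes the mean of the two middle values. The
choice of reference is arbitrary but deterministic; medians are robust
to it.

## The synthetic fixtures: what they do and do not show

`make_fixture()` builds geometric scaffolds: ideal helices (φ = −57°,
ψ = −47°), ideal strands (−139°, 135°), extended peptides (−120°,
130°), and miniature grooves — two helical walls over a two-strand
floor with an extended peptide placed above the floor, rigid pieces
separated to at least 3.2 Å so the starting geometry is clash-free, and
chain roles pre-assigned. The default mini-groove uses a 270-residue
groove chain so it also exercises the length-based classifier; tests
that build models use 24–40-residue versions for speed (the problem
sizes in the test suite and acceptance script — 3-entry databases,
40-residue grooves, 1–3 candidates, 100–150 relaxation steps — were
chosen as the smallest sizes that still exercise every code path).

These fixtures emulate the *topology* of a groove (secondary-structure
elements in the right arrangement, a bound extended peptide, realistic
bond geometry) and none of its *physics*: no packing cores, no real
pocket shapes, no evolutionary sequence variation. Tests passing on
them establish the machinery — exact backbone inheritance, closure
quality against brute-force oracles, clash resolution, superposition
optimality, registration accounting, determinism — not the accuracy of
models of real alleles. Accuracy on real structures is what
`scripts/fetch_benchmark.R` measures, and it requires downloading the
benchmark crystal structures.

## Degenerate inputs and edge behaviour

* Superposition requires ≥ 3 non-collinear atoms; collinear sets are
  rejected rather than silently returning an arbitrary rotation.
* Alignment rejects non-amino-acid letters with the offending position;
  `X` is accepted and scored 0 against everything.
* Altloc policy: only 'A' or blank conformers are kept; hydrogens,
  deuteriums and waters are dropped at parse time. All downstream
  metrics are defined over non-hydrogen atoms.
* A structure parsing to zero atoms, an empty binding-site selection,
  an empty template pool, a peptide longer than its template, and a
  closure beyond geometric reach each raise a specific error rather
  than degrading.
* Database entries missing from the metadata map are kept with allele
  "unknown" plus a warning; duplicate PDB ids are a hard error.

## Known limitations

* The relaxation and the two scores are internal rankings with no
  claim of thermodynamic meaning; binding affinities are out of scope.
* β2-microglobulin and T-cell receptors are classified and carried
  through the database but not modeled; groove models cover the groove
  chains only (β2m modeling is off by design — it is invariant and
  irrelevant to the binding site).
* Rotamer placement uses an idealised χ grid, not a backbone-dependent
  rotamer library; buried substitutions in tight cores will be cruder
  than a dedicated side-chain packer.
* The class II α/β length heuristic can misassign engineered constructs
  with unusual chain lengths; explicit role metadata is the escape
  hatch.
* No multiple-sequence alignment, profile scoring, or loop database
  beyond fragments mined from the chosen template set.
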