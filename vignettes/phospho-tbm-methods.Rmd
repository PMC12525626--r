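---
title: "Models and methods behind phosphoTBM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphoTBM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoTBM)
```

# Scope

`phosphoTBM` studies one regulatory hypothesis: that phosphorylation of
serine/threonine at position 8 of the tankyrase-binding motif (TBM)
strengthens effector binding to tankyrase's ankyrin repeat clusters
(ARCs), through the same salt-bridge contact (to TNKS2 K604) that an
acidic position-8 residue makes. The package provides the
computational stages of that analysis — motif discovery, phosphosite
cross-referencing, enrichment, kinase preference, equilibrium binding
quantification, and structural readouts — plus a seeded generator that
builds every input with known ground truth. This vignette records the
models, the tunable parameters, the numerical decisions, and what the
synthetic tests do and do not establish.

# The motif model and the tankyrase targeting score

A TBM octapeptide follows the consensus
R-x-x-[small hydrophobic or G]-[D/E]-G-[no P]-[D/E], numbered 1–8. We
represent it as a position weight matrix over the 20 amino acids. The
original peptide-array-derived matrix is not published as numbers, so
the default PSSM is a documented design choice rather than a
reproduction:

* at each scored position, 0.97 of the probability mass is split evenly
  over the consensus residue(s) and 0.03 over the remaining allowed
  residues;
* absolute constraints get zero weight: only glycine at position 6,
  no proline at position 7, and no basic residue (H/K/R) at position 8,
  where basic residues are the least preferred;
* positions 2 and 3 are wildcards with uniform weights and are excluded
  from scoring;
* position 4's "small hydrophobic" set is {A, C, G, I, L, M, P, S, T,
  V}.

The tankyrase targeting score (TTS) of an octapeptide is the geometric
mean, over scored positions, of `w(p, aa) / max(w(p, ·))`. This
normalisation makes 1.0 mean "best residue at every scored position"
and 0 mean "a forbidden residue somewhere", and keeps the conventional
candidate threshold of 0.385 usable: a perfect consensus with a
serine/threonine/tyrosine at position 8 scores

```{r}
tts_score("RGEPEGGS")   # MDC1 TBM1
```

just above the threshold, while a motif additionally degraded at an
anchor position falls below it. Whether the original score used a
geometric mean, a sum of log-odds, or another normalisation is not
stated anywhere we could verify; we treat the 0.385 cutoff as defined
*on this scale* and expose both the PSSM (TSV, 8 rows x 20 amino
acids) and the threshold as user inputs. Zeroing basic residues at
position 8 follows the operational definition of the default matrix
(mass on D/E, residual on non-basic residues); it means basic-8
windows are never candidates, consistent with their strong
disfavouring in binding data.

Two coordinate conventions: all residue coordinates are 1-based and
inclusive, and motif positions are numbered 1–8. The MDC1 TBM1
octapeptide RGEPEGGS is reported with both 947- and 948-based
numbering in different places; since the phosphoserine sits at residue
955 and the motif has eight residues, start 948 is the only consistent
reading and is what the package's examples use.

The ambiguity code X scores zero at scored positions — an unknown
residue cannot support a candidate call. Disorder filtering
(`filter_by_disorder`) takes externally supplied per-residue scores
(disorder prediction itself is out of scope) and keeps matches whose
mean over the eight motif residues clears a threshold; proteins with
no disorder track pass through, flagged, rather than being silently
dropped.

# Phosphosite cross-referencing

Events are joined to motifs by protein identifier and offset: an event
at residue r flags motif position `r - start + 1` when that lies in
1..8. Duplicate events (PhosphoSitePlus-style aggregation of multiple
studies) are collapsed before counting. An event whose reported
residue type contradicts the motif sequence at the mapped position is
skipped with a warning — it usually indicates an isoform/numbering
mismatch, and silently keeping it would corrupt the arm assignment.
Events on proteins without any motif are ignored: the analysis runs
motif → modification, not the reverse.

Because it is ambiguous whether published census numbers count motifs
or host proteins, `census_by_arm()` reports both tallies, plus the
deduplicated pS8 ∪ pT8 host-protein list that feeds enrichment.

# Enrichment

Over-representation uses the one-sided hypergeometric upper tail,
computed by summing exact log point masses with log-sum-exp — stable
down to the very small p-values the display filter cares about — and
Benjamini–Hochberg FDR across all tested terms (via `p.adjust`). The
population defaults to all proteins in the annotation table; fold
enrichment is exactly `(k·N)/(n·K)`. The reporting filter keeps terms
with `-log10(p) > 4` (strict, so p = 1e-4 is excluded) and
`fold >= 4` (inclusive, "at least fourfold"). No term-size minimum is
applied by default because none is stated for the original analysis;
it is a parameter. Annotations are taken as given — no ontology-graph
propagation.

# Kinase preference

Kinase matrices cover relative positions −5..+4 around the
phosphoacceptor (position 0 excluded). The printed MDC1 query spans
five residues upstream and six downstream of S955; the final
overhanging residue is ignored, matching the −5..+4 convention of the
substrate-specificity atlas this emulates. Scores are additive:
`sum(log2 w)` over in-range positions; truncated flanks at protein
termini are skipped, not padded, so terminal sites are scored on the
evidence that exists. Phospho-residues in flanks score as their
unmodified letter unless a matrix provides phospho columns. Ranks are
dense and 1-based, with alphabetical listing inside ties, so rankings
are a deterministic total order. The published 303-kinase matrix set
is not shipped (licensing); the package reads a long-format TSV of any
matrix collection.

# The binding model

Fluorescence polarization is computed as
`FP = 1000·(F∥ − F⊥)/(F∥ + F⊥)` (mP), baseline-corrected per replicate
group by subtracting the mean of that experiment's no-protein wells.
ΔFP titrations are fit with the one-site total binding model

$$\Delta FP(x) = \frac{B_{max}\, x}{K_d + x} + NS \cdot x$$

with the constant background fixed at zero — baseline correction has
already removed it — and x the total ARC concentration (no
ligand-depletion correction, the standard analysis when the tracer
concentration is far below Kd; a documented limitation at
sub-micromolar Kd). Whether the original Prism fits constrained
NS ≥ 0 or included a background constant is not stated, so both are
exposed as toggles (`constrain_ns`, `include_background`) with
defaults off.

Numerical decisions:

* Kd is fitted as log(Kd), which keeps the trajectory positive without
  an explicit constraint.
* Optimisation is Levenberg–Marquardt (`minpack.lm::nls.lm` on the
  residual function directly — the formula-interface wrapper refuses
  zero-residual data, which our noise-free recovery tests exercise).
* Multi-start: the requested start, a data-driven heuristic (Kd at the
  concentration nearest half-maximal ΔFP, Bmax at the maximum ΔFP,
  NS 0), and ±10-fold Kd shifts; the lowest-RSS solution wins. This
  makes recovery insensitive to poor initialisation.
* Standard errors come from the Jacobian-based covariance
  `s²(JᵀJ)⁻¹` at the optimum, with SE(Kd) by the delta method from
  SE(log Kd).
* Identifiability: when the data are (close to) a pure nonspecific
  line, Kd is meaningless. The fit flags `kd_identifiable = FALSE`
  when SE(Kd) ≥ 10·Kd or Bmax does not exceed twice its own SE.
* `fold_change(kd_ref, kd_var)` is a plain ratio (> 1 = affinity
  gain); the label helper rounds to two significant figures.

`simulate_titration()` uses a 12-point, 2-fold dilution series from
200 µM by default — the grid a plate titration would use — and
requires a seed whenever noise is drawn.

# Structural readouts

Superposition is the SVD-based Kabsch algorithm with the determinant
sign correction (proper rotations only); the test suite checks it
against an independently implemented quaternion (Horn) method to
1e-9 Å. `ca_displacement()` superposes two complexes on a shared
selection (for ARC–peptide pairs: the ARC Cα atoms, residues present
in both models) and reports the Euclidean distance of a probe atom —
e.g. the position-8 Cα shift that accommodates the phosphate
(~1.3 Å). Residue correspondence between different peptides is by TBM
position index, not deposited residue number, and is the caller's
responsibility via the selection arguments; for the deposited
ARC4 complexes the relevant chains are B/D and D/H respectively.

Contact censuses are heavy-atom only (hydrogens are dropped on
reading, and the highest-occupancy alternate conformer is kept):
salt-bridge mode pairs charged-group N/O atoms (Lys NZ, Arg
NE/NH1/NH2, His ND1/NE2, Asp/Glu carboxylate O, phosphate O1P/O2P/O3P)
within 4.0 Å by default; H-bond mode pairs any N/O within 3.5 Å. The
distance criterion behind "compatible with hydrogen bonding" is not
standardised, so the cutoff is an argument; 3.5 Å between heavy
donor/acceptor atoms is the conventional default.

Conservation mapping writes percent identity into the B-factor column
and emits the display ramp: red at ≥ 95% identity, linear red→white
over (90, 95), white at ≤ 90%. Per-residue identity comes from a user
supplied alignment (computing alignments is out of scope); identity
excludes the reference from the denominator and counts gaps as
mismatches — neither convention is universal, so both are toggles with
these defaults.

# The synthetic generator: what it emulates, what it does not

`synthetic_spec()` fixes the study conditions for all generated
fixtures; every generator is deterministic per seed. Defaults:

* **Proteome**: 600 proteins of length 400, i.i.d. uniform residues,
  with 43 planted consensus octapeptides whose position-8 composition
  (31 S, 7 T, 5 Y) is a one-tenth-scale version of the proteome-wide
  phospho-census. The 600-protein population keeps the planted hosts a
  small fraction (~6%) of the background, the regime in which genuine
  term enrichment can express fold values above the display filter —
  a few dozen hosts against a population of a few dozen would cap fold
  enrichment near 1 regardless of the biology. Backgrounds are
  redrawn (rejection sampling) until scanning recovers exactly the
  planted set, so ground truth is exact, not probabilistic.
* **Phospho-events**: background S/T/Y phosphorylation at rate 0.01;
  planted position-8 events with probability 1. Arm-count truth is
  tallied from the events actually emitted.
* **Annotations**: one planted term annotating phospho-8 host proteins
  with probability 0.9 (background membership 0.05) plus ten decoy
  terms at uniform 0.2 membership.
* **Titrations**: the MDC1 Kd pair (4.5 and 1.7 µM) with Bmax 150 mP,
  NS 0.1 mP/µM and 3 mP Gaussian noise — typical plate-reader
  amplitudes.
* **Toy structures**: an ideal Cα helix (2.3 Å radius, 100°/residue,
  1.5 Å rise) duplicated under a random rigid transform with a
  controlled 1.3 Å local shift at one probe residue.

What the generator does *not* emulate: real amino-acid composition
(uniform by default; configurable), linkage between motifs and protein
families, the full phosphosite schema (study counts, species),
annotation-term hierarchies, correlated FP noise, or crystallographic
artefacts (alternate conformations, missing atoms). Passing the
generator-backed tests therefore demonstrates that the *pipeline
arithmetic* is correct under known ground truth — it does not validate
biological conclusions on real databases. In particular, the
proteome-scale census numbers (311/77/54 sites, 388 host proteins),
the specific enriched terms and the ATM/ATR kinase ranks depend on
dated external releases (phosphosite database, annotation release,
kinase matrix atlas) and deposited structures, none of which are
shipped; the package reproduces them only given those inputs.

# Problem sizes in the shipped tests

The test suite and acceptance checks run at desk scale by choice:
random-sequence scanning oracles use 200–300-residue sequences;
hypergeometric enumeration oracles cover populations up to N = 60; the
noisy Kd-recovery study uses 200 simulations of 12-point titrations at
5% Bmax noise (median relative error must stay below 15%); the
synthetic census uses the 600-protein proteome above. These sizes make
the full suite run in seconds while leaving every algorithmic branch
exercised.

# Known limitations

* The default PSSM is a principled stand-in, not the original
  peptide-array matrix; absolute TTS values are comparable only within
  one matrix.
* The binding model fits total protein concentration (no ligand
  depletion) and a single site; avidity across multiple ARCs and
  competition formats are out of scope.
* Enrichment treats annotations as flat sets; no ontology propagation.
* Structure tools assume a user-supplied residue correspondence; they
  do no sequence alignment of their own.
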