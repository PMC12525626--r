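# phosphoTBM

Phospho-regulated recruitment of effector proteins to tankyrase: an R
toolkit for motif scanning, phosphosite cross-referencing, enrichment,
binding-affinity fitting and structural readouts.

## The scientific problem

Tankyrase (TNKS/TNKS2) recruits its effectors through a degenerate
octapeptide **tankyrase-binding motif (TBM)** with the consensus

```
R - x - x - [small hydrophobic or G] - [D/E] - G - [no P] - [D/E]
    1   2   3          4                 5      6     7       8
```

that docks onto the ankyrin repeat clusters (ARCs) of tankyrase. An
acidic residue at motif position 8 strengthens binding through a salt
bridge to a conserved ARC lysine (K604 in TNKS2 ARC4) — and
phosphorylation of a serine or threonine at position 8 mimics and
amplifies this effect, turning TBM phosphorylation into a candidate
switch for effector recruitment. `phosphoTBM` implements the
computational pipeline around that hypothesis, for structural
bioinformaticians and biochemists who want to scan proteomes for
phospho-regulatable TBMs and quantify the affinity gains.

## What the package computes

- **Motif scanning** (`build_default_pssm`, `tts_score`,
  `scan_proteome`, `filter_by_disorder`). Every 8-residue window is
  scored with a PSSM-based *tankyrase targeting score*:
  the geometric mean over scored positions of
  `w(position, aa) / max w(position, ·)`, so a perfect consensus scores
  1 and any forbidden residue (e.g. non-Gly at position 6) scores 0.
  Candidates are kept at TTS >= 0.385.
- **Phosphosite cross-referencing** (`map_events_to_motifs`,
  `census_by_arm`). Motif hits are joined with a phosphosite table,
  events are mapped to motif positions 1–8, and position-8 hits are
  split into pS8/pT8/pY8 arms.
- **Term over-representation** (`hypergeom_upper_tail`, `enrich`,
  `display_filter`). One-sided hypergeometric test computed in log
  space, fold enrichment `(k/n)/(K/N)`, Benjamini–Hochberg FDR, and the
  reporting filter `-log10 p > 4` and `fold >= 4`.
- **Kinase preference** (`make_site_window`, `score_window`,
  `rank_kinases`). Additive log2 scoring of a −5..+4
  phosphoacceptor-centred window against kinase PSSMs, with dense
  descending ranks.
- **Binding affinity** (`baseline_correct`, `fit_one_site_total`,
  `fold_change`). Fluorescence polarization titrations
  (FP = 1000·(F∥ − F⊥)/(F∥ + F⊥), baseline-corrected to ΔFP) are fit
  with the one-site total-binding model
  `ΔFP(x) = Bmax·x/(Kd + x) + NS·x`
  by Levenberg–Marquardt least squares (Kd on the log scale), yielding
  Kd with standard errors of the fit and affinity fold changes.
- **Structure readouts** (`kabsch_superpose`, `ca_displacement`,
  `contact_census`, `conservation_to_structure`). SVD-based Kabsch
  superposition, probe-atom displacement between superposed complexes,
  salt-bridge / heavy-atom H-bond censuses, and mapping of per-residue
  conservation (from `percent_identity_per_reference_residue`) into the
  B-factor channel with a red-to-white colour ramp.
- **Synthetic data** (`synthetic_spec`, `make_proteome`,
  `make_phospho_table`, `make_term_annotations`, `make_toy_structures`,
  `simulate_dataset`). Seeded generators that plant motifs,
  phospho-events, an enriched term, titrations and toy structures with
  exact ground truth.
- **Pipeline** (`run_pipeline`). Scan → cross-reference → census →
  enrichment → display filter from one (YAML) configuration, with
  per-stage TSVs, a log and a JSON manifest of parameters, input
  checksums and row counts.

## Worked example

```r
library(phosphoTBM)

# scan a fragment carrying the MDC1 TBM1 octapeptide
recs <- data.frame(id = "MDC1", sequence = "AAAARGEPEGGSAAAA")
(hits <- scan_proteome(recs))
#>   protein_id start end octapeptide       tts pos8_class
#> 1       MDC1     5  12    RGEPEGGS 0.4004498          S

# cross-reference with a phospho-event on the position-8 serine
events <- data.frame(protein_id = "MDC1", residue_number = 12L,
                     residue_type = "S", modification = "phospho")
xref <- map_events_to_motifs(hits, events)
census_by_arm(xref)
#> Position-8 phospho-census
#>   motifs:   pS8=1  pT8=0  pY8=0
#>   proteins: pS8=1  pT8=0  pY8=0
#>   pS8 u pT8 host proteins: 1

# fit a noisy titration of the phospho-peptide (true Kd 1.7 uM)
tt <- simulate_titration(kd = 1.7, bmax = 150, ns = 0.1,
                         noise_sd = 3, seed = 42)
fit_one_site_total(tt)
#> One-site total-binding fit (12 points)
#>   Kd   = 1.513 +/- 0.097 uM
#>   Bmax = 148.4 +/- 2.6 mP
#>   NS   = 0.1234 +/- 0.022 mP/uM
#>   RSS  = 90.75; converged: TRUE
```

The TTS of 0.40 clears the 0.385 candidate threshold (an octapeptide
with a phospho-acceptor rather than an acidic residue at position 8
scores well below the perfect-consensus value of 1). The fitted Kd of
1.51 µM recovers the generating value within the noise of a single
12-point series; against a non-phospho reference Kd of 4.5 µM that is a
~3-fold affinity gain (`fold_change(4.5, 1.51)` ≈ 2.97).

A full synthetic analysis runs in two lines:

```r
simulate_dataset(synthetic_spec(seed = 1), "demo_data")
res <- run_pipeline(list(fasta = "demo_data/proteome.fasta",
                         phospho = "demo_data/phospho.tsv",
                         annotations = "demo_data/annotations.tsv",
                         output_dir = "demo_run"))
```

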