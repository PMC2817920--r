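---
title: "Screening iron complexes of natural products by the aqueous stability factor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening iron complexes of natural products by the aqueous stability factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asfscreen)
```

## The screening problem

Large oxygen- and nitrogen-rich natural products — discodermolide,
kahalalide F, halichondrin B and their relatives — can chelate iron(II/III)
through Fe–O and Fe–N bonds, much as a siderophore does. Because such a
ligand offers more candidate donor atoms than the six octahedral
coordination sites iron provides, the metal can bind through *different*
donor subsets, and each choice of shell changes the complex's energy, dipole
moment, geometry and therefore its solubility. A ligand whose accessible
complexes span a range of polarities is *polarity adaptive*: it can present
a polar face to an aqueous environment and a less polar one to a membrane.

`asfscreen` implements the descriptor-based screening pipeline for this
setting: enumerate candidate shells, score each complex, filter out
non-covalent geometries, rank, classify polarity, and relate scores to
activity data.

## The score

Each candidate complex is summarized by the **aqueous stability factor**

$$\mathrm{ASF} = \frac{E \, L}{D \, Z} \qquad [\mathrm{J\,m/Debye}]$$

with $E$ the complex energy (J, on the scale of the semi-empirical
calculation that produced it), $L$ the mean of the six Fe–O/Fe–N/Fe–OH$_2$
bond lengths converted from Å to meters ($\times 10^{-10}$ — the printed
reference ASF values verify only under this conversion, so it is
hard-coded), $D$ the dipole moment (Debye) and $Z$ the complex charge
(+1 throughout the reference tables; the parameter is exposed but only
$Z=+1$ is validated against reference values). Lower — or negative, since a
negative energy marks a stabilized complex — ASF is better: a small energy
and a large dipole both favor a stable, water-soluble complex.
`rank_complexes()` therefore sorts ascending by signed ASF by default; a
`"magnitude"` policy is available for users who prefer $|\mathrm{ASF}|$,
since the source material calls smaller ASF more stable without addressing
sign explicitly.

Energies are treated as an opaque "as-printed joules" scale and never
converted: the reference tables label them inconsistently (joules vs
joules/mol), and the score verifies against the printed numbers as-is.

## Filters

Two covalency rules, both strict inequalities and both configurable through
`asf_filter_config()`:

* mean bond length > 2.7 Å → discarded (`abl_gt_max`);
* any single bond > 2.9 Å → considered close to lacking covalency,
  discarded (`bond_gt_max`).

`score_complexes()` still computes ASF for failing rows and records the
verdict separately, because the reference tables themselves contain
rule-violating rows and replicating them requires scoring them.

## Shell enumeration and the conformer count

`identify_donors()` labels every O and N atom in an SDF/MOL structure in
file atom order per element ("O1"…, "N1"…); published figure numberings
cannot be recovered programmatically, so a JSON label map can override the
labels. `enumerate_shells()` produces all $\binom{n}{6}$ six-donor subsets
and, with an aqua ligand allowed on the sixth site, all $\binom{n}{5}$
five-donor subsets, in deterministic lexicographic order. All O and N atoms
count as donors — the reference tables mix ether, hydroxyl, carbonyl and
amide sites without distinction — and chemically motivated exclusions are
left to the label map.

An optional geometry prefilter drops subsets whose maximum donor–donor
distance exceeds a span bound (default 8.0 Å when enabled, off by default:
six donors bound at ≤2.9 Å must fit a ~5.8 Å-diameter sphere, so 8.0 Å is
deliberately permissive on raw, un-relaxed coordinates).

Since a full enumeration grows combinatorially while only on the order of
fifty structures per coordination mode are practical to push through a
quantum-chemistry stage, `cap_shells()` makes the cap explicit, with either
a deterministic first-$k$ rule or a seeded random sample — the selection
rule behind published ~50-complex ensembles is unstated, so reproducibility
demands declaring one.

`count_conformers(n)` returns the rotamer bound $3^n$ (three staggered
rotamers per rotatable single bond) in exact integer arithmetic — as a
numeric while exactly representable in a double ($n \le 33$), as a decimal
string beyond.

## The polarity ladder

The dipole-to-volume ratio D/V (Debye/Å³) is used as a solubility proxy and
matched against a packaged ladder of eight solvents running from water
(0.090) to hexane (0.00). `classify_polarity()` reports the nearest solvent
(ties resolve to the more polar) and a band:

| band | D/V |
|---|---|
| water-like | ≥ 0.06 |
| alcohol-range | 0.02–0.06 |
| low-polarity | 0.005–0.02 |
| nonpolar | < 0.005 |

The boundaries interpolate the verbal anchors used with the ladder
(~0.005 for low-polarity solvents, 0.04–0.045 for methanol/ethanol
territory, 0.090 for water); no closed band definition exists in the source
material, so they are config-overridable. An ensemble whose minimum and
maximum D/V fall in different bands is flagged *polarity adaptive* — a
two-band operationalization chosen by this package and labeled as such,
since no quantitative criterion is established.

`hydration_increment()` compares a dry and an aqua ensemble componentwise;
the area and volume increments are expressed in "water equivalents" against
36.4 Å² and 19.4 Å³ — the single-water reference values used in the
hydration context, which differ slightly from the ladder's 19.24 Å³ water
volume entry.

## Trendlines and the activity correlation

`fit_relation()` fits the five trendline families seen in descriptor-score
scatter plots: linear, quadratic, logarithmic, exponential and power.
Exponential and power fits are ordinary least squares on log-transformed
data with $R^2$ reported on the transformed scale — the spreadsheet
trendline convention the published coefficients follow. A constant response
is defined to give slope 0 and $R^2 = 0$; zero variance in $x$ is an error;
residuals below $\sqrt{\varepsilon}$ of the total sum of squares snap
$R^2$ to exactly 1 so exact-recovery checks are stable.

`sorted_log_correlation()` implements the rank-pairing procedure used to
relate computed scores to GI50 activity: log10 both series, sort each
descending *independently*, truncate to the shorter length (the truncation
rule is this package's choice and is flagged in the output), pair by rank
and fit a quadratic. Pairing independently sorted lists destroys sample
identity — the fit compares distribution shapes, not per-sample association
— so the returned object carries that methodological caveat, and negative
ASF values (no logarithm) are excluded with a reported count. The published
figure-level regression coefficients are not replication targets: the
underlying ~50-complex data sets were never printed, so the machinery is
validated on synthetic data with known generating laws instead.

## Packaged reference tables and known errata

`load_fixture("table1")`…`"table8"` return the printed reference tables
bit-identically. Three rows of the halichondrin six-donor table are
internally inconsistent as printed and are excluded from exact replication
(`replicate_table()` flags them): one row prints an average bond length
(2.194 Å) incompatible with its own distances, one prints D/V 0.09596 where
dipole/volume gives ~0.0149, and one prints only five distances (stored
as-is and flagged `incomplete` rather than inventing a sixth). A handful of
further rows print averages a few 10⁻³ Å off the mean of their own
distances; for those, `replicate_table()` reproduces the printed ASF from
the printed average, which is evidently the value the formula was applied
to. Similarly, the printed 1-Propanol D/V (0.020) is a truncation of
1.59/77.37 = 0.0205 rather than a rounding; the solvent-ladder tests treat
that row accordingly.

## The synthetic and mock descriptor providers

The quantum-chemistry stage that produces real descriptors (a semi-empirical
PM3 calculation in external software) is out of scope; two stand-ins let the
full pipeline run and be tested without it.

`generate_descriptors()` draws seeded stochastic descriptor tables whose
*marginal* ranges match the reference tables: bond lengths uniform
1.85–2.80 Å, dipoles uniform 7–37 D, energies normal (mean 1.2 × 10⁶ J,
sd 6 × 10⁵, truncated at zero), volumes 640–1570 Å³, areas 650–1590 Å²,
molar masses 600–1600 g/mol (the min–max envelopes of the printed tables),
charge +1. Aqua records get a +4.97 D dipole shift — the reported hydrated
(13.36 D) minus dry (8.39 D) ensemble difference. Joint correlations
between descriptors are deliberately not modeled, so passing tests show the
machinery is correct on realistic ranges, not that the generator reproduces
real physics.

`mock_descriptors()` is deterministic geometry plumbing: a pseudo-iron at
the donor centroid, bond distances clipped to 1.85–3.2 Å, dipole
proportional to the unresolved vector sum of unit centroid→donor directions,
energy proportional to mean squared bond-length strain around 2.1 Å, and
bounding-sphere area/volume. An aqua site contributes an idealized 2.1 Å
bond and no dipole term. These functional forms are declared non-physical;
they exist so enumeration → scoring → ranking has structured, reproducible
inputs.

## Numerical choices and test scales

* Replication tolerances: ±5 × 10⁻⁴ Å (ABL), ±5 × 10⁻⁴ D/Å³ (D/V), 1 %
  relative (ASF, printed to 2–5 significant figures), with a 10⁻¹²
  epsilon so deviations sitting exactly on a tolerance count as inside it.
* Enumeration correctness is checked against an independent recursive
  subset generator for 6–12 donors; larger donor counts only change
  $\binom{n}{k}$, not the code path.
* Property-style checks use fixed seeds; the dipole-shift check uses
  n = 1000 (standard error of the mean difference ≈ 0.55 D, so the ±1.7 D
  band is a 3σ sampling allowance around +4.97 D).
* The packaged toy structure used for pipeline-closure tests has 9 donors
  (210 shells), small enough that the full enumerate → mock → score → rank
  chain runs in well under a second.

## Limitations

* Descriptors are inputs: the package computes no energies, dipoles, areas
  or volumes from structure (beyond the declared-non-physical mock), and
  parses no quantum-chemistry output files.
* No 3D complex construction, force-field minimization, or stereochemistry.
* The polarity ladder is a heuristic nearest-neighbor match, not a
  solubility model (no logS/logP).
* The rank-paired activity correlation inherits the methodological caveat
  above and should be read as a distribution-shape comparison.

## A worked run

```{r example}
results <- score_complexes(load_fixture("table2"))
rank_complexes(results, k = 3)[, c("rank", "complex_id", "asf", "dv")]

polarity_range(score_complexes(load_fixture("table5")))
```
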