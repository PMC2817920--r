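# asfscreen

Descriptor-based screening of iron(II/III) complexes of large oxygen- and
nitrogen-rich natural products (discodermolide, kahalalide F,
halichondrin B and the like), for computational and medicinal chemists
asking: *through which of its many O/N donor atoms would this ligand bind
iron, and which of those complexes would be stable and water-soluble?*

Such a ligand offers more donors than iron's six octahedral sites, so the
metal can bind through different donor subsets — and each shell choice
shifts the complex's dipole moment, geometry and solubility. A ligand whose
accessible complexes span a range of polarities is *polarity adaptive*.

## The score

Each candidate complex, summarized by its physical descriptors (energy `E`
in J, dipole moment `D` in Debye, the six coordination bond lengths in Å,
surface area, volume, charge `Z`), is ranked by the **aqueous stability
factor**

```
ASF = E · L / (D · Z)      [J·m/Debye]
```

where `L` is the mean coordination bond length converted Å → m. Smaller (or
negative, for a negative complex energy) is better: a small energy and a
large dipole both favor a stable, water-soluble complex. Around the score
the package provides:

* **covalency filters** — mean bond length > 2.7 Å or any single bond
  > 2.9 Å discards a candidate;
* **shell enumeration** — all 6-donor subsets of a structure's O/N atoms,
  plus 5-donor + aqua shells, with an explicit per-mode cap;
* **polarity classification** — the dipole/volume ratio D/V matched against
  a packaged eight-solvent ladder (water 0.090 … hexane 0.00 Debye/Å³);
* **trendline fits** (linear/quadratic/logarithmic/exponential/power, with
  broom-style `tidy()`/`glance()` and `autoplot()` methods) and a
  rank-paired log–log correlation of ASF against GI50 activity data;
* **packaged reference tables** (`load_fixture("table1")` …
  `"table8"`) of previously computed complexes, used as exact replication
  oracles in the test suite;
* a **seeded synthetic descriptor generator** and a deterministic geometric
  mock standing in for the semi-empirical quantum-chemistry stage, so the
  whole pipeline runs and is testable without external QM software.

## Worked example

```r
library(asfscreen)

results <- score_complexes(load_fixture("table2"))   # Fe-discodermolide
rank_complexes(results, k = 3)[, c("rank", "complex_id", "donors",
                                   "asf", "abl_A", "dv")]
#>    rank complex_id donors                  asf abl_A     dv
#> 1     1 Dis-07     O1;O3;O4;O6;O8;N1 0.0000134  1.95 0.0144
#> 2     2 Dis-10     O1;O2;O3;O6;O8;N1 0.0000153  2.07 0.0165
#> 3     3 Dis-08     O1;O3;O4;O7;O8;N1 0.0000159  2.14 0.0230
```

The best shell (`O1,O3,O4,O6,O8,N1`, ASF 1.34 × 10⁻⁵ J·m/Debye) combines
the shortest average bond length (1.95 Å, strongly covalent) with a modest
energy — the most stable, physiologically soluble candidate of the ten.

```r
polarity_range(score_complexes(load_fixture("table5")))  # aqua complexes
#>   min_dv max_dv   span min_band     max_band      adaptive
#> 1 0.0174 0.0405 0.0231 low-polarity alcohol-range TRUE
```

The hydrated discodermolide ensemble spans D/V 0.0174–0.0405: its least
polar members sit in octanol-like territory while the most polar approach
methanol (0.038), so the ligand is flagged polarity adaptive — by shifting
which donors bind iron it can adapt its solubility.

```r
classify_polarity(0.0405)
#>       dv nearest_solvent band
#> 1 0.0405 Methanol        alcohol-range
```

A full pipeline run (enumerate → mock/synthetic descriptors → score → rank
→ polarity → trends) is available as `run_asf_pipeline()` or from the shell
via the thin `exec/asf` script
(`asf score table2.csv --rank 10 --out results.csv`).

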