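# mockqc

Quality control of mock-community **positive controls** in 16S rRNA gene
amplicon sequencing studies.

Every microbiota profiling run should carry a mock community — a
laboratory-assembled mixture of known members at known proportions —
through the same wet-lab and bioinformatic workflow as the study samples.
If the mock comes back looking like its theoretical composition, the
workflow is behaving; if not, the discrepancies (taxon-specific bias,
contamination, artifact ASVs) are visible in a sample whose truth is
known. `mockqc` automates that comparison for dada2-style ASV tables,
where amplicon sequence variants are identified by their DNA sequences
themselves. Only bacterial and archaeal 16S references are supported;
eukaryotic mock members are simply omitted from the reference panel.

## What it computes

For each ASV sequence *q* and each expected species *s*, a word-presence
naive-Bayes log-score over the distinct k-mers (default k = 8) of *q*:

```
score(s) = Σ_w log P(w | s),   P(w | s) = (m_s(w) + p_w) / 2
p_w = (n_w + 0.5) / (N + 1)
```

where `m_s(w)` is 1 iff k-mer *w* occurs in species *s*'s reference
sequences, `n_w` is the number of the *N* species containing *w*, and
`p_w` is the word prior. Each ASV is scored in 100 bootstrap rounds, each
subsampling 1/8 of its k-mers with replacement; the **confidence** is the
plurality vote fraction, and calls below 0.60 — or ASVs sharing no k-mer
with any reference — are reported as **Unknown**.

Counts are then aggregated by assigned species, converted to percent
relative abundance, and each sample is compared to the theoretical
composition by **Spearman's rank correlation** (midrank ties, Pearson on
the rank vectors; the Unknown fraction is excluded from the correlation
vector and reported as its own contamination diagnostic).

A synthetic-data module generates reference panels, theoretical
compositions and ASV tables — including a D0–D8 dilution series whose
contamination fraction rises with dilution — so the entire pipeline can be
exercised and tested without any vendor data. `mockqc` ships **no**
vendor sequences or percentages; for a real mock (e.g. an 8-species
ZymoBIOMICS-style standard) supply the vendor's reference FASTA and
expected percents (see `inst/extdata/mock_config_template.yaml`).

## Worked example

Simulate a dilution series and run the full report:

```sh
MOCKQC=$(Rscript -e 'cat(system.file("scripts/mockqc.R", package="mockqc"))')
Rscript -e 'library(mockqc);
  write_simulation(simulate_mock_experiment(simulation_config(rng_seed=42)), "demo/sim")'
Rscript $MOCKQC report \
  --asv-table demo/sim/asv_table.tsv --reference demo/sim/reference.fasta \
  --species-map demo/sim/species_map.tsv --theoretical demo/sim/theoretical.tsv \
  --out-dir demo/results --plots-dir demo/results --seed 1
```

which prints:

```
mockqc run summary (mock: mock)
samples: D0, D1, D2, D3, D4, D5, D6, D7, D8
theoretical species: 8
per-sample agreement:
  D0           rho=0.976190   unknown=  1.017%
  D1           rho=1.000000   unknown= 11.735%
  D2           rho=0.976190   unknown= 21.060%
  D3           rho=1.000000   unknown= 29.537%
  D4           rho=1.000000   unknown= 37.125%
  D5           rho=0.976190   unknown= 43.675%
  D6           rho=0.976190   unknown= 49.849%
  D7           rho=1.000000   unknown= 55.489%
  D8           rho=0.976190   unknown= 60.120%
```

Reading: rho stays at or near 1 — the ranking of the 8 expected species
survives dilution — while the Unknown fraction climbs from ~1% to ~60%,
tracking the simulated contamination schedule: exactly the signature of a
diluted mock overwhelmed by background reads. The occasional 0.976 is one
adjacent rank swap between two species whose expected percents differ by
only 0.1 points, which multinomial sampling noise at 10^5 reads can flip.

`demo/results/` then holds the three result tables
(`asv_assignments.tsv`, `species_profiles.tsv`, `correlation_table.tsv`)
and four SVG diagnostics: stacked composition bars (observed + theoretical),
per-sample rho, per-taxon bias panels, and the Unknown staircase.

The same pipeline is available in R: `simulate_mock_experiment()`,
`build_training_set()`, `run_mock_check()`, `report_bundle()`.

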