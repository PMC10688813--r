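---
title: "Assessing mock-community positive controls with mockqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing mock-community positive controls with mockqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockqc)
```

## The problem

A mock community is a positive control: a mixture of microbial cells or
DNA whose membership and proportions are known by construction. Carried
through DNA extraction, PCR, sequencing and denoising alongside real
samples, it lets a lab ask the one question real samples cannot answer —
*did the workflow reproduce a known truth?* Deviations decompose into two
diagnostics: taxon-specific bias (an expected species consistently over-
or under-represented, e.g. from extraction efficiency differences between
Gram-positive and Gram-negative cells or primer preference) and the mass
of reads that match *no* expected member, which flags reagent
contamination, cross-talk, or artifact ASVs. `mockqc` computes both from
a dada2-style ASV table in which variants are named by their sequences.

The workflow is: build a taxonomic training set from the mock's expected
reference 16S sequences; classify every ASV to an expected species or
"Unknown"; aggregate counts to species and convert to percent; compare
each sample to the theoretical composition with Spearman's rho; plot.

## The classifier

The assignment problem here is far easier than open-world taxonomy: the
candidate set is tiny (a handful of species, known in advance) and the
only other answer that matters is "none of them". We use a word-presence
naive-Bayes model with bootstrap confidence, the scheme family
popularized by the RDP classifier. For a query with distinct k-mer set
$W$ and species $s$:

$$\mathrm{score}(s) = \sum_{w \in W} \log \frac{m_s(w) + p_w}{2},
\qquad p_w = \frac{n_w + 1/2}{N + 1},$$

where $m_s(w) \in \{0,1\}$ records whether $w$ occurs in any reference of
$s$, $n_w$ is the number of the $N$ species containing $w$, and $p_w$ is
a shrinkage prior: a k-mer shared by many species carries little evidence
either way, while a k-mer private to one species rewards it strongly and
penalizes the rest. Duplicate k-mers contribute once (word *presence*,
not counts — at full-length-16S scale nearly all k-mers are unique within
a sequence anyway).

Confidence comes from 100 bootstrap rounds, each drawing
$\lceil n/8 \rceil$ of the $n$ distinct query k-mers with replacement and
voting for the top-scoring species; the reported confidence is the
plurality fraction, and calls below the threshold become "Unknown".

Three guards shape the edge cases:

* **Zero-evidence guard.** If *no* query k-mer occurs in *any* species
  index, the ASV is "Unknown" with confidence 0 before any bootstrapping.
  Without it, every bootstrap round would end in an exact tie and the
  tie-break would elect a spuriously confident winner.
* **Deterministic tie-break.** Exact score ties go to the
  lexicographically smallest species label — deterministic and
  seed-independent.
* **Per-ASV RNG substreams.** Each ASV's bootstrap stream is keyed by
  (seed, ASV index), so results are identical whether ASVs are classified
  singly, in table order, or in any other order.

### Parameters

| parameter | default | rationale |
|---|---|---|
| `k` (word size, nt) | 8 | classifier-family convention; 4^8 = 65,536 words makes chance sharing between unrelated full-length 16S references rare but non-zero; configurable 4–12 |
| `n_bootstraps` | 100 | vote fractions resolved to 0.01; more adds runtime, not discrimination |
| `subsample_fraction` | 1/8 | each round sees ~190 of ~1,490 k-mers of a 1,500-nt query: enough signal to be right, little enough that a marginal query produces split votes |
| `confidence_threshold` | 0.60 | a plurality barely above coin-flip ambiguity; the mock setting is closed-world, so borderline calls should fall to "Unknown" rather than inflate an expected species |

K-mers are taken from the forward strand only: dada2 output is
orientation-consistent with the references. `both_strands = TRUE` unions
in reverse-complement k-mers for tables where that guarantee fails.

This module is a self-contained, testable contract — it does not attempt
to numerically reproduce any external classifier's output, and agreement
with other tools is at the level of the workflow, not the scores.

## The comparison

Observed percents over the theoretical species are rank-correlated with
the expected percents using midrank (average) ranks and Pearson
correlation of the rank vectors. The explicit midrank route, rather than
the classical $6\sum d^2$ shortcut, is used because mock profiles
routinely contain ties — typically zeros for species wiped out by a
failed extraction. If either rank vector is constant, rho is undefined
and reported as `NA`, never silently propagated.

Two deliberate choices:

* **Unknown is excluded from the correlation vector.** The theoretical
  table has no Unknown entry; pairing it with an imputed 0 would reward
  contaminated samples. Its mass is reported separately
  (`unknown_percent`), which is the more interpretable diagnostic anyway.
* **No renormalization after exclusion.** Spearman is rank-based, so
  rescaling the observed vector is a no-op; we skip it and document that
  fact to preempt confusion.

Species observed but absent from the theoretical table are folded into
Unknown (with a warning): by definition they are not expected. Zero-depth
samples are dropped with a warning instead of failing the run. Fewer than
3 theoretical species is an error — a rank correlation over 2 points is
meaningless. The supplied theoretical table must sum to exactly 100
(within 1e-6); it is *not* renormalized, so transcription mistakes in a
vendor table surface immediately. The table is also assumed to be on the
same scale as sequencing output — no 16S copy-number or genomic-abundance
conversion is applied.

## The synthetic data generator

The generator exists so that every pipeline property is testable without
any vendor data, and its defaults mirror the demonstration design the
package targets: an 8-species bacterial mock sequenced to 10^5 reads per
sample, with a 9-sample dilution series (D0–D8) in which contamination
grows with dilution.

* **References**: i.i.d. uniform-random ACGT sequences of 1,500 nt
  (full-length-16S-like). Pairwise k-mer Jaccard similarity < 0.05 is
  enforced by regeneration, guaranteeing classifier separability.
* **Theoretical percents**: normalized Gamma(5,1) draws (Dirichlet-like),
  rounded to one decimal with the largest component absorbing the
  rounding residue, redrawn until all values are distinct and ≥ 1%. The
  rounding is done in integer tenths, so the sum is exactly 100.
* **ASV variants**: per species, the reference plus substitution-mutated
  copies at a per-base error rate (default 0.02, so ~30 substitutions on
  1,500 nt). Substitution-only — no indels — which exercises k-mer
  classification while keeping lengths fixed.
* **Contaminants**: sequences built by a base-by-base walk that never
  closes a k-mer present in the panel, making them k-mer-disjoint from
  every reference. This makes the "Unknown" ground truth unambiguous;
  whole-sequence rejection sampling would essentially never terminate at
  this length. Phylogenetic realism of contaminants is a non-goal.
* **Counts**: one multinomial draw of size `depth` per sample; variant
  $i$ of species $s$ has probability
  $(1-c)\,(\text{expected}_s/100)/n_{\text{variants}(s)}$ and the
  contaminant pool shares $c$ equally. `exact_counts = TRUE` replaces the
  draw with `round(depth * p)`, a noise-free surface on which the
  pipeline must recover rho = 1 and Unknown = 0 exactly.
* **Dilution schedule**: $c_i = 1 - (1 - c_0)\,g^i$ with $c_0 = 0.01$
  and $g$ chosen so that $c_8 = 0.6$ — strictly increasing, spanning
  "nearly clean" to "majority contaminant", the qualitative signature of
  diluting a mock standard. The real-world mechanism (fixed background
  contaminant load against shrinking input biomass) is modeled only in
  this monotone form.

What the generator does **not** emulate: PCR chimeras and bias, indel
errors, phylogenetically related contaminants, between-species k-mer
sharing at real-16S levels (real species share conserved regions;
synthetic panels are nearly disjoint), or copy-number effects. Passing
tests therefore demonstrate the pipeline's correctness and its behavior
under the stated noise model — not classifier performance on closely
related real taxa, which is bounded by the training-set references the
user supplies.

## Numerical and design notes

* All percents are reported on the 0–100 scale; profiles sum to 100
  within 1e-9 per sample.
* TSV outputs render 6 decimal places; FASTA/TSV round-trips are exact
  for integers and within 1e-6 for reals.
* The ASV table orientation is fixed (rows = ASVs, columns = samples);
  the reader never auto-detects orientation, avoiding silent transposes
  of dada2's `seqtab` (which is the other way around).
* `N` is permitted in ASV sequences; k-mer windows containing it are
  skipped. IUPAC ambiguity codes in references are likewise skipped, not
  expanded.
* Plots are views: every number drawn comes from the same objects the
  TSVs are written from. SVG (cairo) is the canonical plot format because
  its output is byte-deterministic, making reports diffable; sample order
  in all plots is input order (D0→D8 reads naturally), never sorted by
  score.
* The whole pipeline — simulation included — is deterministic given the
  seeds; the test suite verifies byte-identical reruns.

Test problem sizes: unit and property tests run on 5-species, 300-nt
panels at depth 2×10^4 (the smallest sizes at which every property is
still exercised); end-to-end acceptance properties run at the full
default design (8 species, 1,500 nt, depth 10^5, 20-seed replication for
the monotonicity and recovery properties).

## Limitations

* Species-level assignment only; no ranked lineages, no genus rollup.
* Closed-world by design: the classifier can only say "one of the
  expected species" or "Unknown"; it is not a general taxonomic
  classifier and is not intended to match one numerically.
* No distance-based composition comparisons (Bray–Curtis, Aitchison) and
  no significance testing on rho; with n_taxa around 8, rho's sampling
  distribution is too coarse for p-values to add insight.
* No multi-batch statistics; each run is assessed independently.
* Bacteria and archaea only.
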