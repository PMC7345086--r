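---
title: "A GC-richness chronology of the genetic code: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A GC-richness chronology of the genetic code: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonchron)
```

## The model

The working hypothesis is that primordial RNA was GC-biased, so the first
codons to be assigned were GC-rich and the order of codon assignment can
be read, at least on a global scale, from codon nucleotide composition.
`codonchron` turns that reading into a deterministic procedure with two
rules:

1. **Composition rule.** For each amino acid or stop entry, the codon
   block with the highest-priority GC key decides the group. The key
   scores G/C occupancy at the middle base, then the first (5′) base,
   then the wobble base; the middle base dominates because it varies
   least within a codon family and contributes most to codon–anticodon
   recognition. Entries whose best codon is G/C at both middle and first
   positions are *GC-rich*; G/C at the middle only, *middle*; A/U at the
   middle of every codon, *AU-rich*.
2. **Degeneracy rule.** Within a group, an entry with more codons is
   placed earlier: a heavily degenerate wobble position means fewer
   competitors took those codons, suggesting earlier assignment. Entries
   with equal scores share a column and are read as the same period.

Multi-block amino acids (Arg, Ser, Leu) are classified by their best
block — Arg enters the GC-rich group through CGN even though AGA/AGG are
AU-heavier; the AGR pair is plausibly a later addition. The result on
the standard code:

```{r}
ord <- chrono_arrange(load_standard_code())
ord
```

### Design choices in the ordering

Several points were genuinely open and are fixed here as package policy:

* **Total codon count, not wobble-only degeneracy**, is the within-group
  score (`tie_rule = "total-codons"`). Counting only wobble variants
  within one codon box gives Arg, Gly, Pro and Ala four each and cannot
  isolate Arg at the head of the GC-rich group, while total count (6 vs
  4) reproduces the published within-group orders everywhere: Arg before
  the Ala/Gly/Pro column; Ser(6) > Thr(4) > Cys(2) > Trp(1) in the
  middle group; Leu(6) > Val(4) > Ile(3) > the 2-codon column > Met(1)
  in the AU-rich group. The wobble-only variant remains available as a
  sensitivity switch.
* **UAA and UAG form one merged 2-codon stop entry** in the AU-rich
  group (`stops = "merged"`, default), mirroring their joint late
  arrival; UGA is always its own 1-codon entry in the middle group.
  `stops = "split"` yields three 1-codon entries instead (the split UAA
  and UAG then share the final column with Met).
* **In-column ties flatten alphabetically, stops last.** Within a
  column the composition rules genuinely cannot order entries — the
  boundaries are subjective at that resolution — but downstream
  statistics need a total order, so the tie-break is deterministic and
  documented rather than meaningful. In particular, the prose order of
  the published 2-codon AU-rich list is not assumed to be a ranking; the
  column stays a tie.
* **Met is an ordinary 1-codon entry**; its start-codon role is
  annotation, not position.

## aaRS zones and the clustering statistic

Overlaying the synthetase classes (11 class I, 10 class II, Lys charged
by both; the noncanonical SepRS route for Cys is kept as an annotation
outside the counts) on the flattened order produces maximal same-class
runs:

```{r}
cseq <- overlay_classes(ord, load_aars_classes())
detect_runs(cseq)
```

The zonal claim — one early class II zone, one class I zone, then a
mixed tail — is visual in origin, so the package adds a statistic: the
number of runs over the effective sequence, compared against random
label permutations. The test is one-sided (clustering = fewer runs) with
the add-one correction, so p can never be exactly zero. Dual-class
(Lys) and stop positions are excluded from the effective sequence by
default; excluding them is the most conservative choice because any rule
that lets Lys join a neighboring run can only merge runs and inflate
the apparent clustering. `dual_policy = "either"` and `"own"` implement
the alternatives. Default 10,000 permutations; the seed is a mandatory
argument and is recorded in the result.

UGA's placement is annotated separately by `preluca_boundary()`: it
reports the nearest class II-only run before UGA and the class I-only
run at or after it, and whether UGA falls in the transition region
between the end of the early class II zone and the end of the first
class I zone. On the standard inputs UGA sits two positions after the
class II zone, inside the Cys–Ile class I zone, consistent with the
first stop codon marking the changeover between the two synthetase
eras.

## Chronology comparison

The two published chronologies shipped with the package are transcribed
as printed, with parenthesized groups as shared ranks. The GC-derived
chronology uses the column index as the rank so its ties are preserved,
restricted to amino acids (published chronologies do not rank stop
codons). Kendall's tau-b is the headline statistic because both sides
contain ties; it is computed by explicit concordant/discordant pair
counting with the tie-corrected denominator, and Spearman's rho on
mid-ranks is reported alongside. With 20 amino acids the exact pair
count is trivial; the test suite checks it against an independent
sign-product oracle and against `stats::cor(method = "kendall")`.

```{r}
chr <- packaged_chronologies(ord)
kendall_tau_b(chr$gc_order, chr$trifonov_n6prime)
kendall_tau_b(chr$gc_order, chr$trifonov_consensus)
```

The abundance check (`abundance_vs_gc()`) correlates prebiotic
abundance-range midpoints with GC-order rank over the amino acids a
panel reports (16 in panel (a), 6 in panel (b)). It is reported
descriptively with no threshold: the scientific claim it probes is a
*negative* one — that abundance did not drive codon assignment — and a
weak correlation is the expected outcome, not a failure. Midpoints are
derived on demand; the stored table keeps only the printed ranges, and
unreported amino acids carry an explicit marker rather than an imputed
value.

## The bridge-peptide simulator

The simulator is the package's synthetic-data generator: it emulates the
qualitative mechanism by which a short Arg/Asp-bearing peptide (the
bridge peptide, prototype Arg-Gly-Gly-Ala-Asp) could bias aminoacylation
toward Arg on GC-rich RNAs and thereby close a positive feedback loop.
Each cycle:

1. **Aminoacylation.** Every uncharged RNA is charged. With probability
   `min(1, β · n_BP/n_RNA · gc_fraction)` it receives Arg (BP-mediated);
   otherwise an amino acid is drawn from the chemical-code weights. At
   β = 0 the model reduces exactly to abundance-proportional sampling.
2. **HDP formation.** Charged RNAs are shuffled into groups of uniform
   random size (2–6 by default); each group becomes one peptide and its
   RNAs return uncharged. Leftovers below the minimum length stay
   charged.
3. **Selection and turnover.** Peptides survive with probability
   `base_survival` (× `survival_bonus` if they satisfy the BP motif,
   capped at 1); RNAs survive with `base_survival + gc_slope ·
   (gc_fraction − 0.5)` clamped to [0, 1]; the RNA pool is replenished
   to its nominal size from the synthesis distribution.

All rates and functional forms are free parameters — the mechanism is
stated qualitatively in the literature with no measured rates — and the
defaults are desk-scale choices that make the feedback visible without
saturating it: 1,000 RNAs of 20 bases at p(GC) = 0.7, β = 5, survival
0.8 with a 1.25× BP bonus (BPs at the default therefore survive with
probability 1 and accumulate; the feedback contrast is read against the
β = 0 control run under identical settings, which shares this
accumulation), GC slope 0.2, five seeded BPs, 200 cycles. Chemical-code
weights default to the panel (a) abundance midpoints with a 0.005 floor
for unreported amino acids, avoiding structural zeros. The BP motif
requires at least one Arg and one Asp in a peptide of length ≥ 3; an
Arg-only variant is a switch.

Two distinct Arg fractions are recorded per cycle: `arg_fraction` is the
share of Arg among residues incorporated *that cycle* — the quantity the
chemical-code null applies to — while `pool_arg_fraction` is the share
in the surviving peptide pool, which is survival-biased toward
BP-containing peptides and exceeds the null even at β = 0.

What the simulator does **not** model: sequence-specific BP–RNA binding
(binding is reduced to the scalar GC fraction; arginine-rich-motif-like
recognition is an extension point), thermodynamic hybridization, codon
emergence, or any spatial structure. Passing its property tests
therefore shows that the implemented feedback loop behaves as designed —
not that the mechanism operated prebiotically.

## Numerical and testing choices

* Determinism: every stochastic entry point takes a seed; identical
  seeds give identical trajectories and p-values. The full-report
  driver uses `seed` for the permutation test and `seed + 1` for the
  simulation so the two streams are independent.
* Degenerate inputs: single-label sequences make the clustering
  statistic undefined (error, not NA); all-tied rankings make tau-b's
  denominator zero (warned, reported as 0); an order lacking UGA errors
  in the boundary annotation, and UGA in first position returns a
  degenerate note instead of a verdict.
* The test suite checks the Monte-Carlo permutation p against exact
  enumeration on sequences short enough to enumerate (≤ 10 positions,
  ≤ 252 arrangements) within three standard errors, and tau-b against
  oracles on rankings of up to 8 items. Simulator property tests run at
  reduced scale (300–2,000 RNAs, 20–60 cycles, 5–20 seeds) — large
  enough for the tested expectations' standard errors, small enough to
  keep the suite fast; the acceptance script uses 400 RNAs × 60 cycles
  × 20 paired seeds for the feedback contrast.

## Limitations

The chronology is relative and global: within-column order is
undecidable from composition, and the package deliberately refuses to
rank it. The Trp/Tyr placement runs against synthetase phylogenies that
date TyrRS before TrpRS — explicable if UGG was originally a stop codon
reassigned late, but the statistics here are computed on the order as
produced, with no correction. Alternative (e.g. mitochondrial) codes are
out of scope; the loader validates specifically the universal code, and
supporting other tables would require relaxing its stop-set and
family-count invariants.
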