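# codonchron

Tools for a chronological reading of the universal genetic code. The
package orders the 64 codons and their cognate amino acids from GC-rich
(inferred early) to AU-rich (inferred late), overlays the aminoacyl-tRNA
synthetase (aaRS) class I/II partition to expose its zonal structure,
compares the resulting chronology against published amino-acid
chronologies with tie-aware rank statistics, and simulates the
bridge-peptide (BP) feedback mechanism proposed to drive early codon
assignment in a GC-biased RNA–peptide world.

It is aimed at researchers in molecular evolution and origin-of-life
studies who want the arrangement, the zonal statistics and the simulator
as reproducible, testable code rather than a figure.

## The method

Two rules order the code. For each amino acid (or stop entry), take its
highest-priority codon block and score G/C occupancy positionally, with
the middle base dominating the first (5′) base:

1. entries whose best codon has G/C at both the middle and first position
   form the **GC-rich** group; G/C at the middle position only, the
   **middle** group; A/U at the middle position of every codon, the
   **AU-rich** group;
2. within a group, entries with more codons rank earlier (the wobble
   position was contested less), ties sharing a column — read as the same
   inferred period.

On the standard code this yields the arrangement

```
Arg | Ala,Gly,Pro | Ser | Thr | Cys | Trp,UGA | Leu | Val | Ile |
Asn,Asp,Gln,Glu,His,Lys,Phe,Tyr,UAA/UAG | Met
```

Overlaying aaRS classes (11 amino acids class I, 10 class II, Lys both)
gives maximal same-class runs; zonal clustering is quantified by a
one-sided permutation test on the number of runs, p = (1 + #{permuted
runs ≤ observed}) / (B + 1). Chronologies are compared with Kendall's
tau-b (tie-corrected; Spearman's rho on mid-ranks alongside). The BP
simulator cycles aminoacylation (chemical-code sampling vs BP-mediated
Arg charging with probability min(1, β·n_BP/n·GC)), random
hybridization-dependent peptide assembly, and stability-weighted
survival.

## Worked example

```r
library(codonchron)

code <- load_standard_code()
ord  <- chrono_arrange(code)
seq  <- overlay_classes(ord, load_aars_classes())
detect_runs(seq)
#> Zonal partition (7 runs, dual policy exclude):
#>   I    Arg
#>   II   Ala,Gly,Pro,Ser,Thr
#>   I    Cys,Trp,Leu,Val,Ile
#>   II   Asn,Asp
#>   I    Gln,Glu
#>   II   His,Phe
#>   I    Tyr,Met

clustering_pvalue(seq, n_permutations = 10000, seed = 1)
#> Clustering permutation test: 7 runs over 19 positions; p = 0.07569
#> (10000 permutations, seed 1)

chr <- packaged_chronologies(ord)
kendall_tau_b(chr$gc_order, chr$trifonov_n6prime)
#> Rank comparison gc_order vs trifonov_n6prime (n = 20): tau_b = 0.630, rho = 0.773
kendall_tau_b(chr$gc_order, chr$trifonov_consensus)
#> Rank comparison gc_order vs trifonov_consensus (n = 20): tau_b = 0.407, rho = 0.514
```

The run table reads: a solitary class I zone (Arg) precedes an
uninterrupted class II zone (Gly, Ala, Pro, Ser, Thr), then a class I
zone (Cys, Trp, Leu, Val, Ile), after which the classes mix; with 7 runs
over 19 effective positions the permutation test puts the probability of
clustering this strong under random labeling at about 0.08. The GC-derived
order correlates more strongly with the thermostability-based N6′
chronology (tau-b = 0.63) than with the consensus chronology
(tau-b = 0.41).

```r
traj <- run_simulation(sim_config(seed = 1))
tail(traj, 1)
#>     cycle n_peptides n_bp bp_fraction arg_fraction pool_arg_fraction mean_gc pool_size
#> 201   200       1341  354       0.264        0.994             0.851   0.713      1000
```

With the default β = 5 the bridge-peptide fraction of the peptide pool
self-amplifies (≈ 0.26 at cycle 200 vs ≈ 0.15 for the β = 0 control) and
Arg dominates incorporation, the positive feedback the mechanism
predicts.

`run_full_report(out_dir = "report", seed = 1)` runs the whole pipeline
and writes TSV tables, a JSON statistics file and a run manifest.

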