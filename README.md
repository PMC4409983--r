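# lncevo

Discovery and comparative-conservation analysis of long non-coding RNAs
(lncRNAs), built for the *Anopheles*-style setting: a well-annotated
reference genome (e.g. *An. gambiae*), RNA-seq transcript models from two
independent assemblers, and a multiple whole-genome alignment across a
genus of related species with a dated phylogeny.

The package answers three questions, end to end:

1. **Which assembled transcripts are novel genes, and which of those are
   lncRNAs?** Dual-assembler support → locus class codes against the
   reference annotation (I = intronic, U = intergenic, X = antisense
   exonic) → 200-nt cutoff → coding/non-coding classification.
2. **How conserved is each gene across the genus?** Alignable
   presence/absence per species, and a per-gene rate-scaling test against
   the neutral substitution model fitted on four-fold degenerate sites.
3. **Which lncRNAs carry conserved RNA secondary structures, and do
   structures outlive or die faster than the underlying sequence?**
   A windowed structure-conservation screen, per-species retention counts,
   and a divergence regression with an ANCOVA slope comparison.

## The statistics at the core

**Coding potential** is a phylogenetic likelihood ratio in decibans,

  S = 10·log10 [ P(A | MG94×HKY, τ) / P(A | HKY85, τ) ],

computed by Felsenstein pruning over the 61 sense codons (coding model,
nonsynonymous/synonymous ratio ω = 0.2 by default) versus the neutral
HKY85 model (π, κ, tree scale fitted on four-fold degenerate third
positions of the reference annotation). S = +10 means the alignment is ten
times more likely under coding evolution; the classification cascade uses
the printed thresholds: CODING requires peptide > 100 aa and S > +10,
LNCRNA requires max peptide < 50 aa, ORF < 35% of the transcript,
S < −10, and no protein-domain hit; everything else is AMBIGUOUS.

**Conservation** of a gene is a likelihood-ratio test of the rate
multiplier r on all branches: H0: r = 1 vs H1: r ∈ (0, 1], with
Λ = 2(ℓ1 − ℓ0) referred to the boundary mixture ½χ²₁ + ½δ₀, i.e.
p = ½·P(χ²₁ ≥ Λ). Classes are compared on −log10 p by two-sided
Mann–Whitney U.

**Structure conservation** combines a minimum-free-energy z-score against
mononucleotide shuffles with a structure conservation index (consensus
fold energy over mean individual energies, with covariation bonus and
mismatch penalty) through a logistic map onto [0, 1]; windows above 0.5
are high-confidence, and the weights are re-calibrated at run time on
synthetic labeled windows under the study's own tree. Folding is a
maximum-score nested-pairing dynamic program (GC = 3, AU = 2, GU = 1,
loop ≥ 4) in C++.

All of this runs on a fully synthetic, seeded study bundle
(`generate_study()`) with recorded ground truth — genome FASTA, reference
GTF, two noisy assembler GTFs, MAF alignment, Newick tree, root-age and
domain tables — so every claim the test suite makes is checked against
truth the generator wrote down.

## Worked example

```r
library(lncevo)

study <- generate_study(seed = 1, out_dir = "study")   # ~200 kb, 8 species
cfg <- pipeline_config(
  genome = study$paths$genome, reference_gtf = study$paths$reference_gtf,
  assembler_a = study$paths$assembler_a, assembler_b = study$paths$assembler_b,
  maf = study$paths$maf, tree = study$paths$tree,
  root_ages = study$paths$root_ages, domains = study$paths$domains,
  out_dir = "out", seed = 1)
res <- run_all(cfg)

res$discover$stage_counts
#>               stage count
#> 1       assembler_a    65
#> 2       assembler_b    67
#> 3 supported_by_both    61
#> 4         class_IUX    61
#> 5     length_filter    61

table(res$classify$table$label)
#> AMBIGUOUS    CODING    LNCRNA
#>        22        13        26
```

The bundle planted 15 coding, 30 lncRNA and 15 deliberately ambiguous
transcripts (plus 8 duplicate-pair members); assembler noise drops a few
before classification, and genes ablated down to one or two close species
carry no signal and stay AMBIGUOUS — the table above is the cascade's
honest output, not the planted counts. Conservation separates the classes
as the models dictate (novel coding genes evolve under strong purifying
selection in this world, lncRNAs neutrally):

```r
res$conserve$class_compare$class_summary
#>       class  n    mean    ci_lo   ci_hi     # mean -log10 p, t-based 95% CI
#> 1 AMBIGUOUS 22  0.1446 -0.04344  0.3327
#> 2    CODING 13 68.6444 40.01346 97.2754
#> 3    LNCRNA 26  0.1501 -0.04559  0.3458

res$structure$species_counts
#>   species n_regions n_structures
#> 1     sp1        26           11
#> 2     sp2        25           10
#> 3     sp3        25           10
#> 4     sp4        24            9
#> 5     sp5        24            9
#> 6     sp6        23            8
#> 7     sp7        23            8

res$structure$divergence$ancova_p
#> [1] 1
```

The screen finds 24 high-confidence structure loci (the bundle plants 15
hairpin-bearing lncRNAs; the remainder are chance calls on neutral
windows). Alignable regions decline with divergence time only through
lineage ablation; retained structures start from a lower baseline and
decline monotonically as compensatory structures are lost on distal
branches. At this desk scale the two regression slopes are statistically
indistinguishable (the ANCOVA interaction is far from significance —
consistent with the genus-scale observation that the slope contrast,
while visible, does not reach significance).

Every stage writes TSV/BED/JSON reports under `out/`, each embedding the
configuration, its hash, the seed and the package version, so identical
configurations reproduce byte-identical reports.

A command-line front end is installed as `exec/lncevo`
(`lncevo simulate --seed 1 --out study`, then
`lncevo all --config config.json`).

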