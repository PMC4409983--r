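---
title: "Models and methods behind lncevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lncevo` implements a desk-scale pipeline for discovering long non-coding
RNAs (lncRNAs) from dual-assembler transcript calls and for characterizing
their evolutionary conservation across a genus-level species tree — the
kind of analysis done for the malaria mosquito *Anopheles gambiae* against
its congeners. This vignette explains the models, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The discovery cascade

Transcript models from two independent assemblers are intersected: a call
survives when some call from the other assembler overlaps it exonically by
at least 1 nt on a compatible strand (equal, or either unknown). "Support"
is not a published definition, so the overlap rule is configurable
(`min_overlap`, optional reciprocal fraction). Survivors are classified
against the reference annotation with the precedence **OTHER > X > I > U**:

* same-strand exonic overlap with an annotated transcript — `OTHER`
  (putative isoform, excluded downstream);
* opposite-strand exonic overlap — `X` (antisense);
* span contained in a single annotated intron, either strand — `I`;
* no span overlap at all — `U` (intergenic);
* remaining partial span overlaps — `OTHER`.

Exonic overlap with an unknown-strand participant cannot be called
antisense with confidence and falls to `OTHER`. A 200-nt spliced-length
cutoff is applied *inclusively* (a 200-nt transcript passes): the printed
descriptions conflict between "longer than 200" and "a cutoff of 200", and
the operational sentence wins; the bound is configurable (`min_len`).

Single-exon calls on opposite strands whose overlap covers at least half of
their combined span are reported as likely complementary-strand duplicate
calls — the failure mode of strand inference for unspliced transcripts.
"50% total overlap" is read as overlap / union-span; a reciprocal-fraction
variant is available.

## Coding potential as a likelihood ratio

The published analysis used an external codon-substitution-frequency
scanner. `lncevo` re-implements coding potential as a *defined* phylogenetic
likelihood ratio so that the printed classification thresholds carry over:

$$ S = 10 \log_{10} \frac{P(A \mid \text{MG94}\times\text{HKY},\ \tau)}
                          {P(A \mid \text{HKY85},\ \tau)} \quad\text{decibans}, $$

where $A$ is the reference-anchored alignment of the candidate region and
$\tau$ the scaled species tree. A score of +10 means the alignment is ten
times more likely under coding evolution. Both likelihoods are computed by
Felsenstein pruning with per-column rescaling; gaps and `N` are missing
data (partial-likelihood vectors of one), and species codons containing a
stop are treated as missing under the 61-state sense-codon space. Codons
whose *reference* codon is a stop are excluded from both likelihoods and
contribute 0 decibans.

The neutral HKY85 model (base frequencies $\pi$, transition/transversion
ratio $\kappa$, tree scale $\rho$) is fitted by maximum likelihood on
third positions of four-fold degenerate codons extracted from the reference
CDS annotation — the standard neutral proxy. The coding model is
MG94$\times$HKY sharing $\pi$ and $\kappa$, with the
nonsynonymous/synonymous ratio fixed at $\omega = 0.2$ by default
(configurable): a value comfortably below 1 captures purifying selection
on amino acids without asserting the near-invariance of $\omega = 0.01$.

**Branch-length convention.** A codon spans three sites, so codon branch
lengths must be longer than nucleotide ones — but the naive factor 3 leaves
the two models on different clocks once $\omega \ne 1$. `lncevo` instead
multiplies branch lengths by the factor that makes third positions of
four-fold codons evolve at exactly the neutral rate under the codon model
(`bl_mult`, ≈3 at $\omega = 1$). Anchoring both models on the same
synonymous clock means the likelihood ratio responds to codon *structure*,
not to an arbitrary rate offset; it also keeps the neutral fit unbiased
when reference CDS alignments are simulated under the codon model.

Three scanning modes mirror the published usage: per-codon six-frame
profiles over the transcript ±50 bp (browser-track export as bedGraph),
per-exon best frame, and per-gene best ATG-to-stop ORF
(`score_per_gene`, argmax of the score over enumerated ORFs).

**Which score classifies a transcript.** The classification evidence
(`transcript_evidence`) deliberately scores the *maximum-peptide* ORF, not
the best-*scoring* one. A non-coding transcript contains dozens of short
spurious ORFs; maximizing a noisy likelihood ratio over them inflates the
per-gene score (an extreme-value artifact) severely enough to erase the
negative-score signature of neutral transcripts. Tying the score to the
same ORF whose length and fraction enter the evidence makes the tuple
coherent and restores the intended behavior; `score_per_gene` retains the
argmax contract for users who want it.

Labels use the printed thresholds, all strict, boundaries falling to
`AMBIGUOUS`:

* `CODING`: peptide > 100 aa **and** score > +10 db;
* `LNCRNA`: max peptide < 50 aa, ORF < 35% of transcript length,
  score < −10 db, and no protein-domain hit (domain table consumed as TSV,
  hits at e ≤ 10⁻⁵ by default);
* otherwise `AMBIGUOUS` — emitted explicitly, never dropped.

## Per-gene conservation

Conservation is tested per gene by rate scaling: H₀ fixes the rate
multiplier $r = 1$ (neutral), H₁ frees $r \in (0, 1]$; $\hat r$ comes from
bounded 1-D maximization (tolerance 10⁻⁶) of the pooled column
log-likelihood, and $\Lambda = 2(\ell_1 - \ell_0)$ is referred to the
boundary mixture $\tfrac12\chi^2_1 + \tfrac12\delta_0$, the standard null
for a parameter at the edge of its space, giving
$p = \tfrac12 P(\chi^2_1 \ge \Lambda)$. The published analysis scored
conservation per nucleotide and summarized per gene; pooling columns into
one per-gene test is a documented surrogate matching how the per-gene
−log₁₀ p values are actually used (class-wise comparison by two-sided
Mann–Whitney U with normal approximation and tie correction, plus t-based
95% CIs of class means). Acceleration ($r > 1$) is out of scope: only
conservation is reported.

"Alignable presence" of a species over a gene is non-gap coverage of the
exonic reference positions at ≥ 10% (`min_cov`, boundary inclusive) — a
deliberately tolerant operationalization of an undefined published notion,
robust to fragmented alignment blocks while excluding 1-nt contacts.

## The structure screen

The published screen used an SVM-based structure classifier after
realignment; `lncevo` substitutes a *defined* score with the same 0.5
decision threshold. Folding is a maximum-score nested-pairing dynamic
program (pair scores GC = 3, AU = 2, GU = 1; minimum loop of 3 unpaired
positions; deterministic traceback preferring the smallest left index,
then the largest partner), implemented in C++; "energy" is the negated
pair-score sum, dimensionless. Two features are combined:

* **MFE z-score** — the observed fold energy standardized against
  mononucleotide shuffles (seeded; ≥ 30, default 100; dinucleotide
  content sensitivity is acknowledged, mononucleotide is the default for
  speed and simplicity).
* **SCI** — consensus fold energy over the mean of individual row
  energies. The consensus column-pair score is the per-row mean where a
  pairable row contributes its pair score, a row with two bases that
  *cannot* pair contributes −3 (`mismatch_penalty`), gapped rows 0, plus a
  covariation bonus equal to the *fraction* of row pairs showing a
  compensatory double substitution. Both refinements are forced by the
  score's own contract: without the mismatch penalty any alignment of
  foldable sequences drifts to SCI ≈ 1 (the "unrelated rows ⇒ SCI ≈ 0"
  behavior is unattainable), and an unnormalized per-row-pair bonus grows
  quadratically with the number of species.

The combined score is $\sigma(w_0 + w_1(-\bar z) + w_2\,\mathrm{SCI})$
with defaults $(-4, 1.5, 3)$, monotone in both features. Because the
feature scales depend on tree depth and window length, the pipeline
re-calibrates $(w_0, w_1, w_2)$ at run time by logistic regression on
synthetic labeled windows generated under the study's own tree: conserved
compensatory hairpins against *both* negative flavours — independently
shuffled rows and aligned neutral windows. The second flavour matters:
phylogenetically correlated neutral rows keep residual consensus signal
that shuffles destroy, and a classifier calibrated on shuffles alone
over-calls aligned neutral windows. Calibration is part of the method, not
a tuning afterthought.
Windows of 120 nt with stride 40 are scanned (both configurable);
overlapping high-confidence windows merge into maximal loci whose score is
the best window score. A species *retains* a locus when it is alignable
there and the two-row (reference + species) sub-alignment still scores
above threshold — pairwise retention, since the published figure does not
state whether intervening lineages must also retain the structure.

Divergence rates are compared by ordinary least squares of retained counts
against root age (million years, supplied as a TSV) per group — conserved
genomic regions versus conserved structures — with an ANCOVA F-test
(1, n−4 df) of the age-by-group interaction. An exact equal-slope fit has
numerically zero residuals; the implementation returns p = 1 there rather
than an unstable 0/0 F ratio.

## The synthetic world

`generate_study()` emits every input the pipeline consumes, with recorded
truth. The stated world: an 8-species ladder (reference + five ingroups at
0.02–0.35 substitutions/site + two outgroups at 0.55/0.75, emulating a
sibling-complex-to-distant-congener gradient with root ages 0.5–100 My); a
200-kb chromosome; 12 reference protein-coding genes (three CDS exons,
ATG-to-stop, MG94 with $\omega = 0.05$ — the four-fold-site substrate for
the neutral fit); and 60 novel transcripts: 15 coding (150 codons,
$\omega = 0.1$, forced intact start/stop), 15 structured lncRNAs (neutral
flanks around a 120-nt compensatory hairpin window, stem 25 bp, structure
lost on non-reference branches at rate 1.5 per substitution/site — the
reference lineage is protected because these are reference-anchored
structures), 15 unstructured neutral lncRNAs (including 5 intronic and 4
antisense placements), and 15 neutral transcripts with a planted mid-length
(55–95 aa) ORF that the cascade must leave ambiguous. Four
complementary-strand duplicate pairs and per-assembler noise (5% drops,
3-nt boundary jitter, 3 spurious calls) complete the calls; a quarter of
the novel genes lose alignability in all species beyond a sampled depth
(the ablation truth table).

lncRNA-class reference sequences are rejection-sampled so that no frame
carries an ATG-anchored peptide above 45 aa — without this, random 480-nt
sequences frequently contain ≥50-aa ORFs and the generating label would be
incoherent with the cascade's own definition.

What the generator does *not* emulate, and what a green test therefore does
not establish: insertions/deletions (alignment columns map 1:1 to reference
positions, so alignability is binary by construction), sequencing/assembly
error beyond boundary jitter and drops, isoforms, expression levels
(FPKM is exercised on explicit counts only), dinucleotide composition
biases, and real secondary-structure thermodynamics (the Nussinov-style
surrogate has no stacking or loop energies).

## Numerical choices and degenerate inputs

* Likelihood underflow is handled by per-column rescaling inside pruning;
  transition matrices come from the symmetrized spectral decomposition of
  the reversible generators, with negative round-off clipped and rows
  renormalized.
* The neutral fit maximizes over $(\log\kappa, \log\rho)$ by Nelder–Mead
  (relative tolerance 10⁻¹⁰); only the product of scale and branch length
  is identifiable, which the test suite checks by doubling the tree.
* Alignments with no informative non-reference species score 0 decibans
  with a warning (and `conservation_test` flags the gene untestable).
* Simulation uses exact matrix exponentials — no time discretization — so
  the calibration tests measure the statistics, not integrator error.
* Seeds: every stochastic entry point takes a `seed` and restores the
  caller's RNG state; derived seeds stay below 2³¹.

## Known limitations

The coding-potential surrogate shares the ±10 deciban thresholds with the
published tool but not its empirically trained substitution matrices; real
scores and these scores agree in sign conventions, not in scale guarantees.
The per-gene conservation test pools sites and cannot see short conserved
elements inside long neutral genes. The structure screen scores the input
alignment as given (no realignment step, hence no "delta" parameter).
Published genome-scale headline counts are functions of hundreds of
millions of reads and 21 real assemblies and are deliberately not
reproduced at desk scale; the test suite asserts properties (oracle
equivalence, statistical calibration, truth recovery), not those counts.
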