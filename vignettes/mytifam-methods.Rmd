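---
title: "Methods: comparative genomics of a hypervariable AMP gene family"
author: "mytifam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of a hypervariable AMP gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mytifam` re-implements, as a tested and reusable pipeline, the comparative
analysis of a multi-copy, hypervariable antimicrobial-peptide (AMP) gene
family across individual genome assemblies — the situation exemplified by
the myticins of *Mytilus galloprovincialis*, where resequenced individuals
each carry a partially overlapping, largely private repertoire of gene
variants. The stages are: locus mining by translated local alignment,
variant dereplication and classification, identity clustering with codon
consensus, presence/absence variation (PAV), mature-peptide biophysics,
per-site selection testing, promoter motif discovery, and
expression/RNA-editing assessment. A synthetic gene-family generator with
full ground truth lets every stage be validated without external data.

# The synthetic gene family

The generator (`simulate_family()`) is a first-class module, not a test
fixture: its defaults define the study conditions the pipeline is validated
under.

* **Reference mature peptide.** A synthetic 42-residue peptide
  (`reference_mature_peptide()`) with the hallmarks of a CS-alpha-beta AMP:
  eight cysteines at fixed positions, a C-terminal arginine (the propeptide
  cleavage signal), and a slightly cationic residue balance (4 K, 3 R, 2 H
  against 1 D, 1 E). With the default pKa set this composition puts the pI
  near 7.7 and the net charge at pH 7.4 near +1.6 — inside the narrow pI
  7–8 / charge −2..+4 bands reported for myticin mature peptides. The
  peptide is synthetic by construction and is labelled as such; it stands
  in for a real query peptide that we do not redistribute.
* **Family structure.** Ten ancestral genes diverge from the
  back-translated reference by a per-site substitution proposal rate of
  0.15 per ancestral branch (realised pairwise divergence ≈ 15–35%,
  comfortably beyond the 5% clustering radius). Each of 16 individuals
  carries each gene with probability 0.6 (PAV), plus Poisson(0.5) private
  duplicates; within-gene variation uses proposal rate 0.01 (≈ 1–3%
  realised). These sizes mirror a published 16-genome study design in which
  each individual carried on the order of a dozen variants, many private.
* **Substitution process.** Mutations are proposed per nucleotide position
  and accepted per codon: synonymous proposals always, nonsynonymous with
  probability min(1, ω) for the site's ω; for ω > 1 an extra
  nonsynonymous-only proposal round at rate `rate × (ω − 1)` makes the
  realised dN/dS equal ω in expectation. STOP-creating proposals are always
  rejected; ω = 0 freezes a codon entirely (the eight cysteines). By
  default nonsynonymous changes also preserve the residue's charge class
  (basic/acidic/thiol/neutral): real myticins diversify strongly while
  keeping their electrostatic profile nearly constant, and without this
  constraint the synthetic family's pI drifts far outside the observed
  band. The flag (`charge_conserve`) can be turned off, as is done for the
  selection-test simulations where charge drift is irrelevant.
* **Classes.** Each planted copy is conventional, a pseudogene (one
  non-cysteine codon replaced by an in-frame STOP; probability 0.08) or a
  Cys1/Cys5-loss variant (both codons set to serine; probability 0.12),
  emulating the published conventional / pseudogene / "pseudomyticin"
  partition.
* **Geometry.** Each copy sits on its own 3-kb contig of i.i.d. uniform
  background, promoter (500 bp) immediately upstream, on a random strand;
  two pure-background decoy contigs per individual challenge the miner's
  precision. Coordinates are 0-based half-open on the forward strand
  throughout. An optional `tandem_fraction` knob appends copies to the
  previous copy's contig, because the number of tandem vs dispersed loci in
  the real locus is not known; the default keeps loci dispersed.
* **Promoters.** Two ordered motifs (20 bp distal, 10 bp TATA-like
  proximal) are planted at fixed TSS-relative offsets with ±3 bp jitter,
  emulating the serial, positionally conserved promoter architecture of the
  real family.
* **Transcripts and reads.** Expressed copies (probability 0.7) yield one
  transcript contig equal to the exon-3 CDS, optionally with per-base
  substitution edits recorded in the truth table. Reads are exact
  substrings (random strand) with no error model — quality scores,
  diploidy and recombination are out of scope.

What the generator does **not** emulate: assembly fragmentation and errors,
introns in the mined exon (an optional GT–AG mode exists for splice-scan
testing but the default plants the exon intronless), sequencing error,
allele/paralog ambiguity. Passing tests therefore demonstrate correctness
of the analysis logic under clean assemblies, not robustness to assembly
artefacts.

# Mining

`translated_search()` aligns the query peptide against all six reading
frames of every contig with Smith–Waterman (BLOSUM62, gap open 11, extend
1), the standard scoring of translated BLAST searches. STOP codons
translate to `*`, which BLOSUM62 scores −4 against residues — a strong but
not fatal penalty, so pseudogenes are still found. Raw-score thresholds
replace E-values: with small assemblies and a synthetic decoy validation
the Karlin–Altschul calibration adds nothing; the default `score_min = 60`
leaves zero background hits on decoy contigs across 50 seeded trials while
recovering every planted copy. An identity ≥ 40% filter replaces the
published studies' manual curation of raw hits.

Hits are mapped back to forward-strand nucleotide intervals, overlapping
hits reduced to the best-scoring one, and `extract_locus()` extends the
aligned span to the full query projection. When the local alignment opened
a gap (which can happen spuriously at ~60% identity), the extension is
re-anchored by scoring every frame-consistent gapless placement between the
two end anchors — valid because the family model is substitution-only; for
indel-bearing families the aligner's own ends are kept. The promoter is
the 500 bp immediately upstream on the sense strand, truncated and flagged
at contig edges.

# Catalog

Dereplication merges exact-identical CDSs with the union of their carriers;
ids are assigned by (length desc, lexicographic) so the catalog is
order-independent. Classification applies the STOP test first (a
STOP-bearing Cys-loss sequence is a pseudogene), then inspects the eight
reference cysteine columns after global alignment to the reference: 8/8
present → conventional, exactly {1,5} missing → pseudomyticin, anything
else → atypical. The fourth class covers cysteine patterns outside the
published three-way partition and is counted separately.

Clustering is greedy incremental at 0.95 identity, the
CD-HIT-style rule: variants processed by (length desc, lexicographic), each
joining the *best*-identity representative at or above the threshold
(best-representative rather than first-above-threshold, for order
stability). Identity is identical positions / alignment length on a
codon-aware global alignment, terminal gaps excluded and internal gaps
included — the closest deterministic reading of CD-HIT's convention; the
published run's exact denominator is unknown, so equivalence is not
claimed. Consensus is per-codon-column strict plurality; any tie (2–2 or
1–1–1–1) yields an ambiguous `NNN` codon shown as `X`, and consensus STOPs
render `*`.

The multiple alignment is progressive: average-linkage guide tree on 6-mer
Jaccard distances, then profile merges with codon-aware Needleman–Wunsch
(nucleotide match 2 / mismatch −1, codon gap open −5 and −3 per additional
codon), so gaps always span whole codons.

# Biophysics

Net charge is the Henderson–Hasselbalch sum over ionizable groups; the pI
solver bisects the strictly decreasing charge curve on pH 0–14 until the
bracket is below 1e−4 pH units, which both zeroes the charge to the 1e−3
tolerance and pins the root to ±0.01 against a 0.001-step grid oracle. Two
pKa calibrations ship (`IPC_protein`, the default, and `IPC_peptide`);
which one the original study used is not stated, so reproduced pI bands
carry a ±0.3 tolerance for set drift. Cysteines are treated as free
thiols — the real peptides are disulfide-bonded, and masking the bonded
cysteines would raise the computed pI; this is a documented knob rather
than a default because generic pI calculators do the same. Sliding-window
pI uses 15-residue windows with free termini (the simplest reading of a
windowed pI profile); `X` contributes no charge and 110 Da to mass. Mature
boundaries come from global alignment to the reference mature peptide,
ending at its conserved C-terminal arginine; a missing arginine warns and
falls back to the aligned column.

# Trees and selection

Distances are Jukes–Cantor with pairwise deletion — the substitution model
the original study selected by information criterion — and trees are
neighbor-joining (via `ape`), with negative branch estimates clamped to
zero. A Bayesian MCMC tree would add nothing here: the tree is descriptive
and feeds the counting test, which needs a deterministic desk-scale
topology. This is a documented method substitution.

The per-site test is SLAC-style counting: Nei–Gojobori site counts (N, S;
STOP-creating mutations excluded from the denominator) and path counts
(averaged over minimal mutation paths avoiding STOPs) on substitution
events reconstructed by two-pass Fitch parsimony per nucleotide site, with
uppass ties resolved toward the parent state. Each codon column is tested
two-tailed against its own expected nonsynonymous fraction q = N/(N+S)
with `p = min(1, 2·min(tails))` — simple and conservative; columns with no
events are neutral at p = 1. On a 60-sequence star-phylogeny simulation
with ω = 5 at three sites and ω = 0.05 at eight sites (substitution rate
0.12/position — chosen once from power pilots so purifying sites accumulate
the ≥ 3–5 synonymous events the discrete test needs), the test recovers
3/3 diversifying and 7/8 purifying sites at p < 0.1, with a ~1% site-level
false-positive rate under neutrality (bounded at 15% in the acceptance
checks). Exact reproduction of any published per-method site count is not
claimed — the published methods themselves disagreed on it.

# Promoter motifs

`discover_motifs()` is ungapped EM under a ZOOPS model: 0-order background
estimated from the input, pseudocount 0.01, convergence at log-likelihood
change < 1e−4 or 200 iterations. Width runs over the coarse grid {6, 8,
10, 15, 20, 25, 30} (a continuous width optimisation buys little at desk
scale and costs determinism); each width is seeded from the most enriched
exact w-mers plus random windows, with short EM passes for every seed and
full refinement of the best. Width selection maximises
`sites × (IC − w·bias)` where bias is twice the small-sample entropy bias
3/(2·ln2·n) bits per column — an uncorrected per-column criterion ties
between a motif and its own sub-motif, and a total-IC criterion always
prefers wider windows whose flanks carry pure sampling noise. Discovered
sites are masked before the next motif.

Match significance follows the MAST convention: per motif, the best-hit
p-value from the exact distribution of the integer-scaled log-odds score
under the background (dynamic-programming convolution over columns), then
the product-of-p-values formula `P = x·Σ (−ln x)^k/k!`. Genome scanning
reports windows on both strands whose log-odds score reaches 70% of the
min–max-normalised score range — our reading of a "70% accuracy" scan
threshold, documented as an interpretation. Positional conservation is the
SD of occurrence offsets measured from the promoter's TSS end, flagged
conserved at ≤ 10 bp.

# Expression and RNA editing

A cluster counts as expressed in a transcriptome when its consensus reaches
**strictly** greater than 95% identity (identical positions / query length,
best local alignment, both strands) to some contig; contigs between the
70% family floor and 95% against *every* cluster are novel-cluster
candidates. A contig at exactly 95% is neither — the published wording
(">95% identity" expressed, ">5% divergence" novel) leaves the boundary
open, and we log such cases rather than guess. Whether the published
screen applied the threshold at nucleotide or peptide level is ambiguous;
the implementation applies it to whichever sequence is supplied.

Editing candidates combine (a) direct genome/transcript comparison with
(b) corroboration by exact-match read coverage: a read contributes coverage
only where it matches the transcript perfectly over its full length, so a
genomic read set leaves exactly the edited positions uncovered. The
published visual inspection of mapping tracks is replaced by the explicit
zero-coverage-interval report.

# Numerical and design notes

* All stage randomness derives from one integer seed through a fixed
  integer schedule; every stage is byte-identical across re-runs.
* Ambiguous or gapped codons are ignored column-wise in the selection test;
  saturated JC pairs (p ≥ 0.75) are flagged and capped for NJ input.
* Degenerate inputs fail loudly: empty peptides, peptides without
  ionizable groups of both signs, clusters absent from the alignment,
  read lengths exceeding the template.
* Problem sizes in the test-suite: the reference-scale run uses the full
  16-individual defaults; multi-seed recovery loops use 3–6 individuals
  and 4–5 genes per seed, 50 seeds for mining/classification/PAV, 20 for
  motif recovery (width grid restricted to {8, 10, 15}), 50 neutral
  selection replicates at 30 sequences. These sizes were chosen to keep a
  full validation run in the minutes range on one CPU while leaving the
  binomial margins of the recovery checks intact.

# Known limitations

* The miner assumes substitution-dominated divergence when re-anchoring
  gapped hits; families with common coding indels should rely on the raw
  alignment ends instead.
* Only the mature-peptide exon is modelled; full four-exon gene
  reconstruction, signal-peptide prediction and E-value statistics are out
  of scope.
* Greedy clustering at 95% cannot and does not distinguish divergent
  alleles from paralogs; cluster counts are operational, not gene counts.
* The expression screen is qualitative (present/absent); no quantitative
  expression is attempted.
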