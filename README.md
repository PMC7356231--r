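# mytifam

Comparative genomics of hypervariable antimicrobial-peptide (AMP) gene
families across individual genome assemblies.

## The problem

Some invertebrate AMP families — the myticins of the Mediterranean mussel
are the canonical case — are multi-copy, hypervariable, and subject to
pervasive presence/absence variation (PAV): each resequenced individual
carries a partially overlapping, largely private repertoire of gene
variants. Characterising such a family means answering, for a set of
individual assemblies: which loci exist, which variants are intact genes
versus pseudogenes or cysteine-loss forms, how variants group into
clusters, how presence varies across individuals, what the mature peptides
look like biophysically, which codon sites are under diversifying or
purifying selection, what regulatory architecture the promoters share, and
whether the variation is genomic or produced by RNA editing.

`mytifam` implements that entire workflow as composable R functions, and
ships a synthetic gene-family generator with a complete ground-truth table
so every stage can be validated end to end without any external data.

## Methods at a glance

* **Mining** — six-frame translated Smith–Waterman (BLOSUM62, gap 11/1)
  of a mature-peptide query against each assembly; exon CDS and 500-bp
  promoter extraction with strand handling (`translated_search`,
  `extract_locus`, `mine_genomes`).
* **Catalog** — exact dereplication; classification by ORF integrity and
  the 8-cysteine array (conventional / pseudogene / pseudomyticin /
  atypical); greedy incremental clustering at 95% identity with codon
  consensus (`X` for ambiguous codons); PAV matrices and statistics
  (`dereplicate`, `classify_variants`, `cluster_greedy`, `build_pav`).
* **Biophysics** — Henderson–Hasselbalch net charge
  Q(pH) = Σ_basic 1/(1+10^(pH−pKa)) − Σ_acidic 1/(1+10^(pKa−pH)),
  pI by bisection of the monotone charge curve, 15-residue sliding-window
  pI profiles, with IPC pKa sets (`net_charge`, `isoelectric_point`,
  `sliding_pi`).
* **Selection** — Jukes–Cantor distances, neighbor-joining tree, and a
  SLAC-style counting test: Nei–Gojobori site/path counts on Fitch
  parsimony events, two-tailed binomial test per codon column against
  q = N/(N+S) at p < 0.1 (`jc_matrix`, `nj_tree`, `site_selection`).
* **Promoters** — ungapped motif discovery (widths 6–30) by EM under a
  ZOOPS model; MAST-style combined match p-values from exact score
  distributions; 70%-accuracy genome scans; positional-conservation
  statistics (`discover_motifs`, `combined_match_pvalue`, `pwm_scan`).
* **Expression / editing** — cluster expression evidence at >95% local
  identity against transcriptomes, novel-cluster candidates at >5%
  divergence, exact-match read coverage and zero-coverage intervals for
  RNA-editing candidates (`expression_evidence`, `perfect_coverage`,
  `edit_candidates`).

## Worked example

```r
library(mytifam)

# a 16-individual synthetic study with full ground truth
fam  <- simulate_family(family_params(seed = 1))
loci <- mine_genomes(fam$genomes, reference_mature_peptide())
v    <- classify_variants(dereplicate(loci))
table(v$class)
#>  conventional    pseudogene pseudomyticin
#>            59             6            11

cl <- cluster_greedy(v, 0.95)
nrow(cl$clusters)
#> [1] 16
st <- pav_stats(build_pav(v, names(fam$genomes), cl$assignment)$variant)
st$mean_per_individual
#> [1] 5.5

pis <- sapply(v$peptide[v$class == "conventional"], isoelectric_point)
round(range(pis), 2)
#> [1] 7.34 7.94
```

88 planted copies are mined back with recall and precision 1.0 and
dereplicate to 76 variants: 59 intact ("conventional") peptides, 6
STOP-interrupted pseudogenes and 11 Cys1/Cys5-loss variants
("pseudomyticins"), grouping into 16 clusters of ≥95% identity. Each
individual carries on average 5.5 variants, most of them private — the PAV
signature. All intact mature peptides fall in the narrow pI 7.3–7.9 band
characteristic of the emulated family.

The full pipeline (adds selection, motifs, expression and a JSON run
report) is one call:

```r
report <- run_pipeline(run_config(params = family_params(seed = 1),
                                  out_dir = "mytifam_out", seed = 1))
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --seed 1 --out out/`.

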