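---
title: "Detecting and dating mitochondrial plastid DNA, and what it does to barcoding markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating mitochondrial plastid DNA, and what it does to barcoding markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastoflux)
```

## The problem

Plant mitochondrial genomes routinely acquire large fragments of the plastid
genome (mitochondrial plastid DNA, MTPT). Because the transferred copies
evolve at the much slower mitochondrial substitution rate, they stay nearly
identical to their plastid sources for millions of years. A PCR marker
designed against a plastid barcoding locus can therefore co-amplify the
conserved mitochondrial copy of the same locus — the "barcoding paradox" —
and a genotype read off the gel may describe the wrong genome, or even
suggest the wrong species. For herbal commodities authenticated by plastid
barcodes this is not academic: a single mis-read marker can condemn a
genuine product.

`plastoflux` implements the complete inference chain around this phenomenon:

1. **MTPT detection** — seed-and-extend local alignment between a
   mitochondrial and a plastid genome with identity/length/E-value filters
   and tRNA/rRNA masking (`find_mtpt_segments()`), plus multi-species
   aggregation onto a reference backbone (`project_to_backbone()`).
2. **Dating** — codon-aware alignment, Nei–Gojobori (NG86) synonymous
   distance, and molecular-clock dating of the species split and of the
   plastid-to-mitochondrion transfer (`ks_ng86()`, `divergence_time()`,
   `flux_time()`).
3. **Marker evaluation** — plastid variant calling, the marker-design
   filters, in-silico PCR against both organelle genomes, and read-depth
   copy-fraction estimation (`design_markers()`, `in_silico_pcr()`,
   `copy_fraction()`).
4. **Authentication rules** — the positive versus negative multi-marker
   decision framework and its power / false-positive tradeoff
   (`classify()`, `evaluate_rules()`).
5. **A synthetic-data generator** — annotated organelle genomes with MTPTs
   planted in a common ancestor and evolved under a two-rate clock, so every
   stage above is testable without any downloaded data
   (`simulate_flux_scenario()`).

## The simulator defines the study conditions

`flux_scenario()` fixes a species pair: an MTPT insertion in the common
ancestor `t_flux` years ago (default 10 My), a species split `t_split`
years ago (default 2 My), and synonymous rates of `2e-9` (plastid) and
`0.6e-9` (mitochondrion) substitutions per site per year — the conventional
organelle clocks. The default transferred fraction is 0.35 of the plastid,
inserted as 5 contiguous blocks with sizes drawn log-uniform between 0.3
and 20 kb; multi-fragment transfers of roughly this extent are what
organelle assemblies of perennial herbs show, but no fragment-size law is
established, so the block layout is a modeling choice, not an estimate.

Mutation model: within CDS only synonymous substitutions occur, drawn as a
Poisson number of events with mean `rate × years × S` (where `S` is the
NG86 synonymous site count) and placed proportional to per-position
synonymous opportunity. This makes the realized divergence directly
comparable to `rate × years` on exactly the scale the estimator measures —
the point of the simulator is to validate the Ks chain, not to model
selection. Intergenic sequence evolves under a Jukes–Cantor process at 3×
the synonymous rate, a neutral proxy that keeps non-coding identity
comparable to coding identity so the scanner's identity threshold is
exercised meaningfully. There is no InDel process by default; InDels are
planted explicitly where marker tests need them.

What the simulator does **not** reproduce: multi-chromosomal mitochondrial
structure (one chromosome stands in for the recombining set), rate
heterogeneity across genes, selection, InDel accumulation in MTPTs, and
read-level sequencing error (allele depths are drawn binomially at the
site level). Passing tests therefore demonstrate correctness of the
inference chain under a clean neutral model, not robustness to assembly
artifacts or recombination.

## The homology scan

`find_mtpt_segments()` uses exact 11-bp seeds, ungapped X-drop extension
(X = 20) along each diagonal, and greedy chaining of near-diagonal HSPs,
with +1/−2 match/mismatch and −5/−2 affine gaps — a conventional
nucleotide-search parameterization. The biological thresholds sit on top:
identity > 70%, aligned length ≥ 30 bp, Karlin–Altschul E-value ≤ 1e-10
(λ = 1.33, K = 0.621 for the +1/−2 scheme). The thresholds are the
scientific contract; the search parameters are exposed in `scan_params()`
so the two can be varied independently.

Masking: plastid tRNA/rRNA genes are conserved across both organelle
compartments and are excluded. "Excluded" is made operational as: a segment
whose plastid span is more than half masked is dropped; a segment partially
overlapping the mask is trimmed to the unmasked part and re-filtered.

Gene-frequency counting on a backbone: a species "carries" a gene as MTPT
when its merged segment coverage overlaps at least 50% of the gene span —
the paper-scale survey counts ("found in more than 20 species", "more than
10") leave the overlap rule open, and reciprocal half-span overlap is the
package's choice.

Numerical notes: coordinates are 0-based half-open internally, converted
only at the GFF3 boundary (1-based inclusive). Scores are integers;
identity is matches / aligned length; HSP chaining merges same-strand hits
whose diagonals differ by ≤ 100 bp across gaps of ≤ 300 bp when the merged
score beats both parts. Ties in segment ordering resolve by leftmost
plastid start.

## Ks estimation and dating

`codon_align()` aligns translations globally (BLOSUM62, affine 10/1 —
immaterial for near-identical organelle genes, and configurable) and
back-projects to nucleotides so gaps are codon multiples;
`trim_alignment()` removes every gapped codon column and all stop-codon
columns. `ks_ng86()` then counts synonymous sites (per-position fraction of
non-stop changes that are synonymous) and synonymous differences (averaged
over all minimal substitution paths, stop-passing paths excluded), applies
the Jukes–Cantor correction `Ks = −(3/4)·ln(1 − (4/3)·pS)`, and flags
saturation when `pS ≥ 3/4` or no synonymous sites exist. This counting
estimator replaces likelihood machinery deliberately: it is exactly
testable against path enumeration over all 3,721 ordered sense-codon pairs,
and at the Ks range relevant here (≤ 0.13) counting and ML estimates agree
closely.

Dating: `divergence_time()` is `Ks / 2λ`. For the plastid-versus-MTPT
comparison the two copies evolve at *different* rates after insertion, so
`flux_time()` defaults to the rate-sum clock `Ks / (λ_pt + λ_mt)`; the
single-compartment readings (`2pt`, `2mt`) are options because the
convention is genuinely ambiguous in the field.

`ks_mode()` reads a multi-gene Ks distribution with a Gaussian KDE
(Silverman bandwidth, 5e-4 grid, ties toward the smaller mode). For
*small* gene sets the per-gene synonymous difference is a small Poisson
count, the Ks distribution is nearly discrete, and its mode is biased low
(the mode of Poisson(1.8) is 1); `date_species_pair()` therefore summarizes
per-gene Ks by the mean by default, with the mode available as an option
for large samples.

Problem sizes: the recovery analyses in the test suite use a 60 kb plastid
with 50 genes of 300 codons and 35% transferred fraction, ten replicate
scenarios — large enough that mean-Ks dating has a few-percent standard
error, small enough to run in minutes on one CPU.

## Marker rules and the paradox

`call_variants()` compares two plastid genomes by anchored alignment
(collinear unique 25-mer chain; inter-anchor slices aligned exactly),
rejecting inputs whose anchored fraction falls below 50% as non-homologous.
The design filters mirror practice: sites with minor-allele read support
above 3% in either accession are discarded as promiscuous (they flag
co-mapping MTPT reads; the boundary 3% itself is retained — the rule is
strictly "more than"); InDels must exceed 20 bp to become codominant
markers; a SNP is dropped when any other variant lies within 150 bp (the
spacing reading of the design rule — amplicon length is a separate 100–150
bp constraint); primers are unique 20-mers with 40–60% GC. `in_silico_pcr()`
binds primers with up to 2 mismatches but an exact 3′ terminal trimer —
a permissive model of lab PCR, with no thermodynamics. A marker is
`PARADOX` when a mitochondrial product is predicted or its plastid amplicon
overlaps an MTPT segment, else `SAFE`.

`copy_fraction()` turns diagnostic-site allele depths into organelle copy
fractions; integer percentages use largest-remainder rounding so they
always sum to 100. `band_visibility()` is a deliberately minimal
`copies × 2^cycles ≥ threshold` model of why MTPT bands appear only at
high cycle numbers: a template at 12% of the plastid copy number needs
about `log2(88/12) ≈ 3` extra cycles to reach the same product mass.

## Authentication rules

With multiple markers and heterogeneous wild material, two decision rules
bracket the options: call a sample genuine if *any* marker shows the target
allele (positive rule), or counterfeit if *any* marker shows an off-type
allele (negative rule). The negative rule's counterfeit set always contains
the positive rule's — so it has higher detection power and a higher
false-positive rate, and the choice between them is a policy decision about
which error is worse. Missing calls are ignored by default (a strict mode
counts them as off-type); a locus showing both alleles counts as both
present.

## Known limitations

- The scanner is a heuristic: a true homology below ~90% identity and
  shorter than ~50 bp may lack an exact 11-mer seed and be missed, exactly
  as for any seeded search at these parameters.
- Coverage fractions from a re-implemented search will approximate but not
  reproduce numbers obtained with a specific BLASTN build, whose internal
  parameters are not public in the relevant reports.
- Dating assumes the two-rate clock with known rates; rate uncertainty is
  not propagated.
- `in_silico_pcr()` and `band_visibility()` are intentionally coarse; they
  predict which products can form, not yields or melting behavior.
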