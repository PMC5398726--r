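---
title: "Methods and design of venomkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of venomkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomkit)
```

`venomkit` analyses the secreted-protein (venom) repertoire of activated
entomopathogenic nematode infective juveniles. This vignette documents the
models behind each component, the parameters that matter, the synthetic-data
generator that stands in for sequencing and mass-spectrometry data, and the
design decisions taken where the underlying conventions were genuinely open.

## Proteome handling

Proteomes arrive as amino-acid FASTA. Gene–protein correspondence is not
standardised across nematode genome projects, so the header rule is a
configurable function; the default takes the first whitespace-delimited token
as the protein id and strips a trailing `.t<N>`/`.p<N>` isoform suffix to get
the gene id. Before orthology analysis each proteome is reduced to its
longest isoform per gene (`longest_isoform_filter()`); length ties keep the
lexicographically smallest protein id so the filter is deterministic and
idempotent. Non-standard residues (B, Z, U, X, `*`) are retained in sequences
but never act as cleavage sites, and they have no entry in the mass table —
a peptide containing one is an explicit error rather than a silent guess.

## emPAI abundance model

The exponentially modified protein abundance index treats the fraction of a
protein's theoretically observable peptides that were actually observed as a
log-scale proxy for molar abundance:

$$\mathrm{emPAI}_i = 10^{N_{obs,i}/N_{obsbl,i}} - 1,\qquad
\text{molar fraction}_i = \frac{\mathrm{emPAI}_i}{\sum_j \mathrm{emPAI}_j}.$$

*Digestion.* The trypsin/Lys-C mix is modelled as cleavage C-terminal to K or
R. The classical "no cleavage before proline" exception is applied to R only:
Lys-C does cleave K–P bonds, so suppressing K–P would undercount observable
peptides. This is a convention choice, not a documented protocol detail, and
it is toggleable (`proline_exception` in `digestion_config()`). Defaults of
at most 2 missed cleavages and a 6-residue minimum mirror the common database
search settings for this instrument class.

*Observability.* A peptide is observable if some allowed precursor charge
$z \in [2, 6]$ places it inside the 300–1800 m/z survey scan, i.e. its
neutral monoisotopic mass lies in
$[\mathrm{mz_{min}} z_{min} - z_{min} m_p,\ \mathrm{mz_{max}} z_{max} - z_{max} m_p]$
with $m_p = 1.00728$ Da. Masses are monoisotopic with fixed
carbamidomethyl-C (+57.02146 Da), reflecting iodoacetamide alkylation;
variable modifications are ignored for counting — they would shift a handful
of peptides across the window boundary but the window spans ~600–10,800 Da,
so the effect on $N_{obsbl}$ is marginal.

*Counting.* $N_{obs}$ counts **distinct peptide sequences** per protein by
default; parent-ion multiplicity is ignored, matching the index's original
definition (an `"ions"` mode is available). Peptides shared between proteins
credit every protein that lists them — no parsimony inference is attempted,
so paralog-rich families can have correlated emPAI scores.

## Conservation categorisation

Orthology clusters are consumed in the OrthoMCL "groups" dialect
(`cluster_id: species|protein …`). Three decisions make the analysis a
well-defined partition:

1. **Precedence.** A cluster containing at least one vertebrate-parasitic
   (distant-group) protein is *distant-conserved*; otherwise at least one
   congener (sister-group) protein makes it *sister-conserved*; otherwise it
   is *focal-specific*. The three categories are usually presented as
   exclusive pie slices without a stated precedence; distant > sister >
   specific is the only ordering that makes "conserved with a vertebrate
   parasite" mean what it says.
2. **Outgroups.** *Heterorhabditis bacteriophora* is an entomopathogen but
   not a congener and not vertebrate-parasitic; it is placed in an `other`
   group whose members never change a cluster's category. The species-group
   assignment is configuration (`species_groups()`), not code.
3. **Singletons.** Venom proteins absent from every cluster become singleton
   focal-specific clusters (`augment_singletons()`), so category counts sum
   exactly to the venom size.

The emPAI-weighted breakdown (`venom_molar_breakdown()`) reports the three
molar percentages and, because "specific to the genus" may pool the sister
and focal slices, also the pooled genus-specific percentage as an attribute —
both readings are available without recomputation. Cluster ranking ties are
broken by cluster id.

## Family coverage

Domain hits are thresholded at $E \le 10^{-6}$. Coverage is reported as
`round(100 · n_venom / n_genome)` with *round half up*: of the published
family table this convention reproduces 10 of 11 rows from their printed
counts; the one exception (14/85 printed as 17% where the quotient is 16.47%)
appears to be an upstream rounding artefact and is deliberately not
reproduced. The statistic mixes a gene-level denominator (genes whose
products carry the domain) with a protein-level numerator (venom proteins
carrying it), as conventionally reported; `venom_level = "gene"` forces
gene-level counting on both sides. Pfam accession version suffixes are
stripped before aggregation so re-annotations against newer releases still
pool correctly.

## Expression integration

All transforms are explicit, composable matrix operations:

- `log_transform()` is $\log_2(x+1)$.
- `remove_batch_means()` shifts each batch's per-gene mean onto the gene's
  grand mean. This equals regressing out a batch indicator with no other
  covariates; it exactly removes any batch-constant additive (log-scale)
  offset, which the synthetic generator verifies to $<10^{-9}$.
  A batch correction that protects biological covariates is out of scope —
  with conditions nested in batches (the usual failure mode here), any such
  model would be confounded anyway.
- `quantile_normalize()` maps every sample onto the row-wise mean of sorted
  columns, with ties given the mean of the reference values at tied ranks
  (implemented via `limma::normalizeQuantiles(ties = TRUE)`; the package's
  tests assert the definitional property — sorted columns identical to
  1e-9 — independently of that library).
- `sample_correlation_clusters()` uses Spearman correlation over genes and
  seeded k-means with 50 restarts on the correlation rows; `k` is a required
  user input. `sample_pca()` is centred, unscaled PCA over samples.
- `de_threshold_filter()` applies FDR < 0.05 and fold change > 2, read
  strictly: $|\log_2 FC| > 1$. The DE test itself (negative-binomial
  machinery) is consumed, not reimplemented.
- `overlap_stats()` reports the shared percentage relative to the **union**
  of the two DE sets, matching how shared venom genes are conventionally
  quoted (135 of 210 upregulated = 64%; 65 of 88 downregulated = 74%).
- `proximity_groups()` chains genes whose ordinal positions on the same
  scaffold differ by ≤ 10 (single-linkage transitive closure), per scaffold.
  Ordinal gene distance is used because "within 10 genes" has no base-pair
  meaning; per-scaffold application is the only choice under which the
  chaining is well defined. Singletons are not groups.
- `rna_protein_correlation()` is Spearman's rho over the top 100 proteins by
  emPAI, paired to their genes' expression.

## Dosimetry

The measured per-worm rate is treated as an *input*, not recomputed from the
approximate bulk figures (100 µg from ~2 million worms gives 0.05 ng/worm,
whereas the replicate-level measured value is 0.061 ng/worm/3 h — both are
representable). Extrapolation is linear in time and reported at 2 decimals,
half-up (0.061 ng/3 h → 0.49 ng/24 h); worm-equivalents round to the nearest
integer (10 ng ÷ 0.49 → 20). Activation time courses are summarised as mean
proportions with standard errors across replicates using the sample standard
deviation ($n-1$); a single replicate reports SE = 0 by convention.

## The synthetic-data generator

Every generator is driven by one `synthetic_design()` object and a master
seed; identical seeds give byte-identical files, and each generator emits a
machine-readable truth object for exact recovery assertions. The default
design keeps the headline counts of a real activated-IJ venom study — 472
venom proteins, 321 venom orthology clusters, 28,313 focal genes, a
five-condition activation time course with the two late in-vivo conditions in
a second processing batch — with `scale = "test"` shrinking gene counts
(3,000 focal genes, 250 per comparison species) and sequence lengths
(80–300 aa) for fast runs while preserving every count that a reported
percentage depends on. The test suite and the acceptance script use the test
scale throughout; at those sizes the whole suite runs in seconds.

Noise models, chosen as minimal standard forms since none are dictated by the
data being emulated: log-normal molar abundances (meanlog 0, sdlog 1.2);
peptide detection as independent Bernoulli draws per observable peptide with
a logistic link on standardised log abundance (slope 1.5), which makes
emPAI's rank recovery of planted abundance a genuine statistical property
rather than a tautology; negative-binomial counts (dispersion 0.1) around
log-normal baselines with planted log2 fold changes drawn from [1.2, 3.5] and
a +0.8 log2 batch offset. Category proportions plant the published 43%
distant-conserved slice; the 57% remainder's split between sister-conserved
and focal-specific is not published and is fixed once at 22%/35% so all three
slices are populated. The Venn design plants 135 shared of 210 upregulated
and 65 shared of 88 downregulated venom genes (per-method unique counts
38/37 and 12/11, chosen to complete the unions, which are not separately
published). The proximity design plants 79 of 178 query genes in 31 groups
(18 pairs, 9 triplets, 4 quadruplets — mean 2.55, consistent with the
published mean of 2.54 and all groups < 6), isolated from each other by more
than the 10-gene window on a densely indexed scaffold.

What the generator does **not** emulate: real spectra (peptide
misassignment, FDR structure among PSMs), shared-peptide ambiguity between
paralogs, count overdispersion that varies with expression, library-size
differences between samples, and correlated gene programs. Passing
planted-truth tests therefore demonstrates correctness of the computations
and recoverability under the stated noise models, not robustness to every
pathology of real MS or RNA-seq data.

## Numerical conventions and degenerate inputs

Half-up rounding everywhere a printed percentage or dose is produced
(`round_half_up()`), because that is the convention the published tables
follow; base R's banker's rounding would flip several of them. Validation
errors (not warnings) for: duplicate protein ids, empty sequences, residues
without masses, proteins observed but with zero observable peptides, venom
proteins missing from clusters or gene maps, negative E-values or expression
values, zero-worm replicates, and empty set overlaps. All-zero emPAI
catalogues cannot be normalised and error. k-means and all generators take
explicit seeds; nothing in the package draws from an unseeded RNG.

## Known limitations

- emPAI is a coarse abundance proxy; absolute per-protein values are not
  validated against any external measurement, only rank recovery on
  synthetic data.
- The conservation analysis inherits whatever the upstream clustering got
  wrong; the package validates format and partition logic, not homology.
- Batch-mean centering removes real biology if conditions are fully
  confounded with batches; the correction is intended for technical offsets
  on top of a shared design.
- Proximity grouping uses ordinal gene indices, so unannotated genes between
  two venom genes shrink their apparent distance.
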