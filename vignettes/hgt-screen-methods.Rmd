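---
title: "Screening fungal genomes for bacterially derived genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening fungal genomes for bacterially derived genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtcensus)
```

## The problem

Some fungi — most prominently *Basidiobolus*, a symbiont of the amphibian
gut — carry far more secondary-metabolism (SM) core genes (non-ribosomal
peptide synthetases, polyketide synthases, terpene cyclases) than their
phylogenetic position predicts. A leading explanation is horizontal gene
transfer (HGT) from gut-cohabiting bacteria. Claims of fungal HGT are easy
to get wrong: a "bacterial" gene in an assembly may equally be a
contaminant scaffold or a mis-assembled region. `hgtcensus` implements a
conservative three-stage screen for bacterially derived genes, the
compositional evidence used to corroborate it, and the SM census that the
resulting HGT set is cross-tabulated against.

## The screen

For every predicted protein, homology hits against a mixed fungal/bacterial
database (BLAST outfmt-6 plus a subject-to-taxonomy map) are reduced to a
per-gene call at an e-value cutoff of `1e-10`:

1. **Taxonomy screen.** A gene is an HGT *candidate* only if it has at
   least one passing bacterial hit and *no* passing fungal hit. Any passing
   fungal hit vetoes candidacy; so does any passing hit from another
   non-bacterial superkingdom (archaea, non-fungal eukaryotes, viruses),
   since candidacy requires hits to bacteria *only*. The donor taxon is the
   taxonomy group of the single best (minimum e-value, then maximum
   bitscore) bacterial hit; the ten best hit taxa are retained for
   reporting but do not affect the call.
2. **Coverage z-score filter.** For each candidate,
   $z = (\bar d_{\mathrm{gene}} - \bar d_{\mathrm{scaffold}}) /
   \mathrm{SD}(d_{\mathrm{scaffold}})$,
   with per-base read depths $d$; candidates with $|z| \ge 2$ are removed
   as likely assembly artifacts. Scaffold statistics include the gene's own
   bases ("mean coverage of the harboring scaffold" is read literally), and
   the SD is the population (denominator $n$) SD; a `sd_type` switch gives
   the sample convention, which shrinks $|z|$ by $\sqrt{(n-1)/n}$ and never
   changes a decision on scaffolds more than a few dozen bases long. Gene
   depth is averaged over the full genomic span, introns included — depth
   is genomic, not transcriptomic. A scaffold with zero depth variance
   yields $z = 0$ with a warning: uniform coverage cannot indicate
   deviation.
3. **Genomic-context filter.** A candidate is kept only if at least one
   fungal-called gene lies somewhere upstream or downstream on the same
   scaffold. Genes on scaffolds consisting entirely of bacterial-called
   genes — the signature of a contaminant scaffold — and sole genes of
   their scaffold are removed.

The two filters examine disjoint evidence (depth vs. neighborhood), so
they commute; the screen reports a funnel of counts (genes, bacterial-only,
coverage-pass, context-pass) after each stage.

Boundary decisions worth stating: removal at the coverage filter is
$|z| \ge 2$ (strict retention), consistent with every retained z-score in
the published per-gene table (all $|z| < 1.1$); e-value ties at the best
hit break by bitscore, then input order.

## Compositional evidence

Bacterially derived genes are expected to be intron-poor and, at least
transiently, compositionally distinct. The package computes:

- **GC content** with `N` bases excluded from numerator and denominator,
  compared across three cohorts (HGT candidates, fungal genes sharing
  scaffolds with them, all fungal genes) by one-way ANOVA and Tukey HSD.
- **Intron statistics**: intron count and normalized intron length (total
  intron nt over the gene-model *span*, not the CDS — "gene model length"
  is read as the genomic span), compared by Kruskal–Wallis.
- **5-mer and codon-usage profiles**, each divided by the full CDS length
  (so codon vectors sum to exactly 1/3), decomposed by covariance PCA.
  Columns are centered but not scaled — after length normalization the
  features are on a common scale; a `scale.` switch is provided. Group
  structure in PC space is tested by permuting labels of the distance
  between group centroids in the first two components.

The test statistics are computed from the classical formulas (sum-of-squares
decomposition; studentized-range p-values via `ptukey`; rank sums with the
$\sum(t^3-t)$ tie correction), and the test suite cross-checks each against
the corresponding base-R implementation on random inputs. The codon-usage
index is raw in-frame counts per unit length; relative synonymous codon
usage (RSCU) would weight codons by amino-acid family and is deliberately
not used, since the downstream PCA already operates on length-normalized
counts.

Numerical conventions for the PCA: components with singular values below
$10^{-12}$ of the largest are truncated; each component's sign is fixed so
its largest-magnitude loading entry is positive; reconstruction
(`scores %*% t(loadings) + center`) is exact to $10^{-8}$, which the tests
assert.

## The synthetic genome

Because the original assemblies, read sets and databases are external, the
package ships a generator (`simulate_genome()`, `simulate_coverage()`,
`emit_blast_hits()`) whose defaults *are* the study conditions:

| parameter | default | meaning |
|---|---|---|
| `fungal_gc` / `hgt_gc` | 0.4865 / 0.4911 | class mean GC of CDS |
| `gene_gc_sd` | 0.035 | between-gene GC spread around the class mean |
| `fungal_intronless_fraction` | 0.36 | fungal genes with zero introns |
| `hgt_intronless_fraction` | 0.61 | transferred genes with zero introns |
| `intron_lambda` | 3.0 | Poisson mean of the non-zero intron component |
| `n_scaffolds` x `genes_per_scaffold` | 20 x 10 | 200 genes |
| `hgt_fraction` | 0.05 | planting probability per normal-scaffold gene |
| `contaminant_scaffold_fraction` | 0.05 | one contaminant scaffold |
| `n_deviant_genes` | 2 | planted "errant assembly" genes |
| `mean_depth` | 50 | Poisson per-base depth |
| `contaminant_depth_multiplier` / `deviant_depth_multiplier` | 5 / 5 | depth scaling |
| `donor_weights` | 0.45/0.2/0.2/0.15 | Proteobacteria/Firmicutes/Actinobacteria/Bacteroidetes |

Intron counts are drawn from a zero-inflated Poisson: the inflation mass is
solved from the configured intronless fraction and $\lambda$ is fixed at 3,
which places the fungal median at 2 and the transferred-gene median at 0 —
the only constraints the study states. CDS sequences carry a fixed `ATG`
start and `TAA` stop, with internal bases drawn i.i.d. at a per-gene GC
target adjusted so the expected gene GC equals the class target exactly;
per-gene targets are jittered with SD `gene_gc_sd`, the gene-to-gene GC
heterogeneity one sees in real fungal genomes. Without that heterogeneity
the class GC shift of 0.0046 — a tiny effect against realistic within-class
spread — would dominate the k-mer PCA and spuriously separate the classes.

Truth labels are `fungal`, `hgt` (bacterial-origin genes in fungal
context), `contaminant` (all genes of contaminant scaffolds, uniformly
depth-scaled, bacterial-only hits), and `deviant` (fungal-context genes
with locally scaled depth and bacterial-only hits). The three bacterial-like
classes exercise the three screen rules independently: on noise-free
defaults the final set equals the planted `hgt` set exactly, contaminants
fall to the context filter (their scaffold-relative z is near 0, because
the whole scaffold is scaled), and deviants fall to the coverage filter.

**Composition regimes.** `composition_separation = 0` together with equal
GC targets is the *non-separable* regime: transferred genes are drawn from
the same compositional process as fungal genes, modeling complete
amelioration — the study's own interpretation of finding no 5-mer or
codon-usage separation. With `composition_separation > 0`, transferred
genes use a distinct codon-preference table and PCA separates the classes;
the tests confirm both directions.

**What the generator does not emulate:** real codon-usage structure (amino
acid composition, GC3 gradients), repeat content, transposons, sequencing
error, read-level artifacts, or intron splice signals. Passing tests
therefore demonstrate the correctness of the screen's logic and the
calibration of its statistics under the stated model — not performance on
real assemblies, where taxonomically ambiguous hits and uneven coverage
make the filters' conservatism matter more, not less.

## Cohort sizes used by the checks

The published genome-scale statistics (an 806-gene funnel, a GC ANOVA over
tens of thousands of genes) are not reproducible at desk scale, so the
packaged checks run at reduced, stated sizes: 5,000 genes per class for GC
and intron recovery (mean GC recovered within ±0.002); Tukey cohorts of
800 transferred / 100 neighbor / 5,000 fungal genes, mirroring the study's
funnel scale, where the significant (HGT vs. all-fungal) and
non-significant (HGT vs. neighbor, cohort mean 0.488) pattern emerges — at
equal large sizes the 0.003 neighbor difference would trivially reach
significance, so the published pattern is a power phenomenon; 200 genes
per class for the PCA permutation test (499 permutations); 1,000 null
replicates for the ANOVA type-I-error calibration.

## Census, clades, expression, plates

The SM census merges antiSMASH- and SMURF-style predictions (union by gene;
class conflicts resolved in favor of antiSMASH and logged), pools
presentation classes (`NRPS` with `NRPS-like`, `PKS` with `PKS-like`) only
at table time, and cross-tabulates against the final HGT set with
percentages always recomputed from counts — the packaged reference tables
contain one internally inconsistent cell pair (the CBS 931.73 total and
NRPS counts differ by one between the per-genome and per-gene tables),
which is quarantined from every check.

Clade assignment places each query tip into the smallest named clade whose
reference-tip MRCA subtree contains it, after rooting on a supplied
outgroup; queries under no named MRCA are `"unassigned"`. Assignment is
invariant to tip-order permutations, which the tests verify against an
independent rootward path walk.

Expression uses plain TPM (`1e6 * rate / sum(rate)` with annotated
transcript length as the effective length — the inputs are gene-level
counts, so no fragment-length correction applies), and an SM gene is
flagged expressed when its TPM reaches the minimum across the supplied
housekeeping genes.

Plate quantification thresholds yellow in HSV space (hue 40–70°,
saturation ≥ 0.25 — a band separating the dechelated CAS yellow from the
blue-green background; both are configurable since the source protocol
specifies only "yellow") inside a dish detected as the bright near-circular
foreground region; the detected dish diameter provides the pixel scale, so
measured areas are invariant to image resolution. A synthetic 1 cm-radius
halo is recovered within 2% of $\pi$ cm².

## Worked example

```{r example, eval = FALSE}
run <- run_pipeline(sim_config(seed = 42))
print(run)
summarize_donor_taxa(run$screen)
```

## Known limitations

- The screen is list-based, not phylogenetic: no tree reconciliation or
  Alien-Index-style scoring; a gene whose best hits are bacterial because
  of database gaps will be called a candidate.
- The context filter needs annotated neighbors; single-gene scaffolds are
  always removed, which is conservative on fragmented assemblies.
- The halo detector assumes one dish per image, photographed from above.
- Sample-vs-population SD and exon-only vs full-span gene depth are
  documented switches/choices, not inferences; the defaults follow the
  literal reading of the screen's definition.
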