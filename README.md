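# passengerScan

Knockout mouse lines made in one embryonic-stem-cell strain (e.g.
129 or CBA) and backcrossed into another (e.g. C57BL/6) keep a
donor-strain chromosomal segment linked to the targeted locus — a
**passenger region**.  Genes inside it differ between knockout and
wildtype in *cis*, regardless of the knocked-out gene's function, so
naive knockout-vs-wildtype transcriptome comparisons conflate strain
effects with gene function.  `passengerScan` is the audit pipeline
for this confounder, aimed at anyone analysing knockout RNA-Seq (and
companion MethylCap) data:

* **Differential expression** from gene-level counts: median-of-ratios
  normalization, pooled common NB dispersion φ, an exact conditional
  negative-binomial test (two-sided small-p; the binomial exact test
  at φ = 0), and Benjamini–Hochberg FDR.
* **Signature shifts**: for predefined gene sets (light-zone LZS,
  dark-zone DZS, naive NVS, centroblast CBS, control CON, or an
  ad-hoc family such as *Ighv*), median log2 fold change and the
  exact two-sided **sign test** on the signs of member fold changes.
* **Strain-SNP scan**: strain-informative variants (matched to a
  strain panel on chrom/pos/ref/alt) per 50-kb window; maximal runs
  of high-density windows are called as passenger regions.
* **Positional enrichment**: 2×2 test (top-N DE genes × in/out of
  region) by Pearson **chi-square** (no continuity correction) and
  **Fisher exact** test, with odds ratio.
* **Methylation load comparison**: capture coverage projected onto
  TSS/exon/intron/intergenic elements (per-bp load), Mann–Whitney
  per class, Pearson r across TSS elements.
* **Synthetic data** with ground truth for all of the above,
  including scenario presets (`GC`, `activated`, `naive`, `null`).

See `vignettes/passenger-region-audit.Rmd` for the models, parameter
conventions, and what the synthetic world does and does not emulate.

## Worked example

Simulate the pooled 2-vs-2 germinal-center scenario (12,000 genes,
one 20-Mb passenger region with 200 cis-deregulated genes, SNP rates
10 vs 0.2 per 50 kb, δ_LZS = +0.5, δ_DZS = −0.5) and run the whole
audit:

```r
library(passengerScan)
rep <- run_audit(list(simulate = "GC", seed = 42))
print(rep)
```

```
passenger-region audit
DE: 70 of 12000 genes significant at FDR < 0.01 (phi = 0.1163)
signature shifts:
  CON: median log2FC +0.086, sign-test p 0.271
  LZS: median log2FC +0.568, sign-test p 1.31e-14
  DZS: median log2FC -0.506, sign-test p 2.61e-12
  NVS: median log2FC +0.064, sign-test p 0.0886
  CBS: median log2FC +0.032, sign-test p 0.764
region: chr2:40000000-60000000 (400 windows, 4018 variants, strain CBA)
enrichment: chi-square 2339.5 (p = 0), Fisher p = 4.35e-141, OR = 2945.2
methylation: per-TSS Pearson r = 0.9966
  TSS: p = 0.969
  EXN: p = 0.695
  INT: p = 0.918
  ING: p = 0.895
```

Reading it: the shifted signatures are recovered with the configured
signs and magnitudes (LZS median ≈ +0.5, DZS ≈ −0.5) while the
control sets stay null; the SNP scan recovers the injected region
exactly at its true boundaries (chr2:40–60 Mb); the top DE genes are
massively enriched inside it (that is the confounding signature: the
"knockout effect" lives where the donor-strain SNPs live); and the
methylation comparison is null with near-perfect between-group TSS
correlation, as expected when the assay detects no group difference.

Individual stages are plain functions (`run_de`, `score_signatures`,
`sign_test`, `window_density`, `call_regions`,
`region_enrichment_test`, `element_loads`, `compare_methylation`),
and everything reads/writes standard formats (counts TSV/MTX, BED6 +
exon table, VCF, BedGraph, one-gene-per-line set files).

### Command line

```sh
inst/cli/passenger-audit run --simulate GC --seed 42 --out audit_out
inst/cli/passenger-audit simulate --scenario null --seed 7 --out simdir
inst/cli/passenger-audit de --counts simdir/counts.tsv --groups simdir/groups.tsv \
    --annotation simdir/annotation.bed --fdr 0.01 --out de.tsv
inst/cli/passenger-audit scan --vcf simdir/calls.vcf --panel simdir/panel.vcf \
    --chrom-sizes simdir/annotation.bed.chrom.sizes --strain CBA --out scan
```

(Verbs: `simulate`, `de`, `signatures`, `scan`, `enrich`, `methyl`,
`run`; after installation the script also lives under
`system.file("cli", "passenger-audit", package = "passengerScan")`.)

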