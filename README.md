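# mdikit — microbial dysbiosis index scoring for gut microbiota profiles

`mdikit` quantifies how far an individual's gut microbiota has drifted from a
healthy reference community. It is aimed at microbiome researchers and
clinical bioinformaticians working with 16S rRNA taxonomic profiles —
typically of inflammatory bowel disease (IBD) patients — who want a single
interpretable per-patient score rather than a panel of per-taxon tests.

## The index

The patient's profile is compared with the median profile of age- and
gender-matched healthy controls at three taxonomic ranks (phylum, family,
genus). At each rank the package computes the percentage quadratic
dissimilarity

```
Z = sqrt( 1/2 * sum_t ( f_case[t] - f_control[t] )^2 )
```

where `f_case` and `f_control` are relative-abundance vectors aligned to the
union of their taxa (the per-taxon median across a subject's samples, then
renormalised to the simplex). `Z` is 0 for identical profiles, 1 for fully
disjoint one-hot profiles, and stays in `[0, 1]` for any two points on the
probability simplex. The microbial dysbiosis index (MDI) is 100 times the
unweighted mean of the per-rank `Z` values, and patients are classified as

| MDI          | class    |
|--------------|----------|
| below 25%    | mild     |
| 25% to 35%   | moderate |
| above 35%    | high     |

Around the score, the package provides the standard analysis battery:
prevalence/abundance filtering, rarefaction and cumulative-sum-scaling (CSS)
normalisation, Shannon/Chao1 alpha diversity, Bray–Curtis beta diversity
with PERMANOVA, Pearson/Spearman taxa–MDI correlations with
Benjamini–Hochberg FDR and weak/moderate/strong bands, clinical-score
regression, rank-based group tests, a faecal–ileal correlation network, and
a Dirichlet-multinomial synthetic cohort generator so the whole workflow is
testable without any sequencing data.

## Worked example

Generate an emulated 35-patient paediatric IBD cohort (14 UC / 21 CD, plus a
50-control reference pool) and run the full workflow:

```r
library(mdikit)

bundle <- emulate_ibd_cohort(seed = 1)
res <- run_pipeline(bundle$table, bundle$metadata,
                    out_dir = "ibd_run", seed = 1)

res$stratification
#>      class  n percent
#> 1     mild 10    28.6
#> 2 moderate 14    40.0
#> 3     high 11    31.4

res$mdi_results[[1]]
#> <mdi_result> IBD01: MDI = 14.60% (mild; ref [4,11)|male|exact)

head(res$correlations[, c("feature_id", "rho", "q_value", "band")], 3)
#>     feature_id       rho      q_value     band
#> 1  Escherichia 0.6869784 4.483494e-05 moderate
#> 2 Enterobacter 0.5916078 1.182091e-03 moderate
#> 3   Klebsiella 0.4050753 8.206711e-02 moderate
```

The stratification is the per-class patient count with one-decimal
percentages. Each `mdi_result` records the per-rank dissimilarities, the
aggregate MDI, the class, and which reference stratum (and fallback level,
if any) was used. The correlation table mirrors the usual taxa-vs-index
report: here the Enterobacteriaceae genera that the generator enriches with
the injected dysbiosis effect rise to the top with positive coefficients,
while the depleted commensals (`Faecalibacterium` rho −0.75,
`Bacteroides` −0.74) anchor the negative end with `strong` bands. The
PERMANOVA on Bray–Curtis distances across the three dysbiosis classes gives
pseudo-F = 12.2, p = 0.001 for this run. All artifacts (filtered/normalised
tables, reference JSON, MDI report, correlation and diversity tables, run
manifest) are written under `out_dir`, and a rerun with the same seed is
byte-identical.

A thin command-line wrapper with the same functionality ships in
`inst/cli/mdikit.R`:

```sh
Rscript inst/cli/mdikit.R synth --seed 1 --out cohort/
Rscript inst/cli/mdikit.R run --table cohort/taxa_counts.tsv \
    --metadata cohort/metadata.tsv --seed 1 --out run/
```

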