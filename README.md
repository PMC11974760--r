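# repdrift

Tools for quantifying **longitudinal drift and persistence in adaptive
immune receptor repertoires** (AIRR-seq). Given annotated heavy-chain
rearrangements from the same subjects sampled years apart — with multiple
biological replicates per subject and timepoint — `repdrift` answers: how
much of the circulating antibody repertoire is conserved over time, which
clonotypes persist, what distinguishes them, and how much of the apparent
turnover is just finite sampling?

It is written for immunologists and computational biologists analyzing
AIRR-style rearrangement tables (and for method developers, who get a
fully ground-truthed synthetic V(D)J repertoire generator to validate
every stage by parameter recovery).

## What it computes

**Clonotypes.** Sequences are collapsed by the triple
(V gene, J gene, CDRH3 amino-acid sequence); alleles are discarded and
the CDRH3 is the IMGT junction minus its conserved Cys/Trp–Phe anchors.

**Morisita–Horn similarity** over (V gene, J gene, CDRH3-length)
"species", with counts `x_i`, `y_i` and sample sizes `X`, `Y`:

    CH = 2 Σ x_i y_i / [ (Σ x_i²/X² + Σ y_i²/Y²) · X · Y ]

computed directly, with bootstrap rarefaction curves across sampling
depths, pairwise replicate matrices, single-linkage clustering, and
intra- vs inter-timepoint comparisons stratified by isotype and mutation
load.

**Turnover and persistence** at clonotype and nucleotide-sequence level:

    turnover%    = 100 · (appearing + disappearing) / total species
    persistence% = 100 − turnover% = 100 · shared / total

plus sharing-versus-depth diagnostics, characterization of persistent
(shared) versus transient clonotypes (CDRH3 length, IgG frequency, V-gene
mutations, multi-replicate recurrence, sequence logos), and persistent
*public* clonotype analysis across subjects.

**Repertoire classification.** A linear one-versus-rest SVM on V-gene,
J-gene and CDRH3-length frequencies, evaluated leave-one-replicate-out
with per-rotation ROC AUCs and a train/test record-leakage audit.

**Simulation.** `sim_config()` / `simulate_study()` generate annotated
longitudinal repertoires (2 subjects × 2 timepoints × 6 biological
replicates by default) with configurable gene usage, junctional
diversity, naive/memory structure, somatic hypermutation, power-law clone
sizes, a persistent fraction, and a cross-subject public clonotype pool —
with a ground-truth lineage registry tracing every record.

## Worked example

```r
library(repdrift)

cfg <- sim_config(n_subjects = 2, n_timepoints = 2, n_replicates = 6,
                  n_sequences = 1000, persistent_fraction = 0.02, seed = 42)
study <- simulate_study(cfg)

r1 <- subset(study$records, subject == "S1" & timepoint == "T1")
r2 <- subset(study$records, subject == "S1" & timepoint == "T2")
persistence_report(r1, r2, level = "clonotype")
#> # A tibble: 1 × 9
#>   level      n_t1  n_t2 n_shared n_appearing n_disappearing n_total turnover_pct
#>   <chr>     <int> <int>    <int>       <int>          <int>   <int>        <dbl>
#> 1 clonotype  3617  3801       60        3741           3557    7358         99.2
```

Of the 7,358 distinct clonotypes seen across the two timepoints of
subject S1, only 60 are shared: observed persistence is 0.8%. The
generator's true persistent fraction is 2% — the shortfall is the
depth-dependence of observed sharing, which `sharing_vs_depth()` makes
explicit and which is why raw persistence percentages are lower bounds.

```r
strat <- stratified_similarity(study$records)
strat[strat$stratum %in% c("all", "IgG"), ]
#>   stratum comparison n_pairs median   q25   q75
#> 1 all     intra           60  0.798 0.753 0.818
#> 2 all     inter           72  0.343 0.307 0.363
#> 3 IgG     intra           60  0.437 0.405 0.578
#> 4 IgG     inter           72  0.151 0.106 0.190
```

Replicates from the same timepoint are far more similar (median
Morisita–Horn 0.80) than replicates four "years" apart (0.34): the
between-timepoint difference exceeds the sampling noise floor. The
IgG-only stratum is less conserved than the whole repertoire.

```r
ev <- evaluate_loro(study$records, size_grid = c(100, 500),
                    n_repeats = 2, seed = 1)
ev$summary
#>    size class mean_auc
#> 1   100 S1_T1    0.944
#> 2   100 S1_T2    0.778
#> 3   100 S2_T1    0.917
#> 4   100 S2_T2    1
#> 5   500 S1_T1    1
#> 6   500 S1_T2    1
#> 7   500 S2_T1    1
#> 8   500 S2_T2    1
```

With 500 sequences per sample, every held-out replicate is assigned to
its subject and timepoint perfectly from just three marginal feature
distributions; at 100 sequences the assignment starts to degrade.

`run_pipeline(cfg, out_dir)` executes every stage (simulate → collapse →
similarity → persistence → public clonotypes → classify) and writes all
tables plus a JSON run manifest; reruns with the same configuration are
byte-identical. See `vignettes/repertoire-drift.Rmd` for the models,
assumptions and design choices.

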