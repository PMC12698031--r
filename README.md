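# pondFD

Trait-based community assembly analysis for pond zooplankton along a
eutrophication gradient.

Eutrophication can erode the *functional* structure of freshwater
communities even while species richness stays flat. pondFD is for
community ecologists who want to ask, per sample and per trophic state:
is this community assembled by **habitat filtering** (the environment
selects similar traits), **limiting similarity** (competition spaces
traits apart), or indistinguishable from **random**?

The workflow, in the field's standard notation:

1. **Trait space.** Species × trait table (ordinal size class; categorical
   feeding type, trophic group, habitat; 17 categories) → Gower
   dissimilarity `d_ij` (Podani's tie-corrected ranks for the ordinal
   trait) → PCoA embedding (square-root correction), computed once for the
   species pool.
2. **Indices per sample.** Richness `S`; Simpson `D = 1 − Σp²`; functional
   richness `FRic` (convex-hull volume); evenness `FEve` (minimum spanning
   tree regularity); divergence `FDiv`; dispersion
   `FDis = Σ pᵢ‖xᵢ − c‖`; Rao's quadratic entropy
   `RaoQ = Σᵢⱼ pᵢpⱼ d_ij`; redundancy `FRed = 1 − RaoQ/D`; composite
   `FD = (FDis + RaoQ)/2`; plus community-weighted means (CWM) of every
   trait category.
3. **Null models.** `c0` (incidence: species frequencies preserved,
   richness free) and `c0_samp` (biomass: per-species value multisets
   permuted); `SES = (obs − null mean)/null sd`.
4. **Verdicts.** One-sample t or Wilcoxon tests (Shapiro-branched) of SES
   against zero per group; significantly negative → habitat filtering /
   trait convergence, positive → limiting similarity / trait divergence.
5. **Synthetic fishponds.** A generator with known regimes (neutral,
   filtering via a Gaussian TP-tolerance kernel, limiting similarity via
   colonization rejection) emulating the reference design: 9 ponds,
   March–September, 63 incidence + 27 biomass samples, 59-species pool,
   TP 50–600 µg/L.

## Worked example

```r
library(pondFD)

cfg <- pipeline_config(
  synthetic = synthetic_config(regime = "filtering", seed = 7),
  n_iter = 499, seed = 7, out_dir = "run_filtering")
res <- run_pipeline(cfg)

print(subset(res$assembly_calls,
             group == "highly_hypereutrophic" & metric %in% c("FRic", "FDis")),
      row.names = FALSE)
```

which prints (seed 7, 499 iterations, both bases):

```
                 group     basis metric metric_family test_used      p_value direction             label  n
 highly_hypereutrophic incidence   FRic            fd         t 4.528082e-05  negative habitat_filtering 23
 highly_hypereutrophic   biomass   FRic            fd         t 1.557379e-04  negative habitat_filtering 11
 highly_hypereutrophic incidence   FDis            fd         t 9.349812e-02      none            random 23
 highly_hypereutrophic   biomass   FDis            fd  wilcoxon 2.929687e-03  negative habitat_filtering 11
```

Read: in the highly hypereutrophic ponds of this simulated filtering world,
observed functional richness sits far below its null expectation (negative
SES, p < 1e-4) on both data bases — habitat filtering — while
incidence-based dispersion is indistinguishable from random, the same
basis asymmetry the field system shows. The run directory contains
`fd_metrics.csv`, `cwm.csv`, `ses.csv`, `assembly_calls.csv`, `trends.csv`,
a `run_manifest.json` (config echo, row counts, timings) and the generated
inputs plus `truth.json`.

A command-line entry point with subcommands `simulate`, `run`, `metrics`,
`null` and `classify` is installed at `inst/cli/pondfd`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pondfd", package = "pondFD"))')" \
  run --regime neutral --seed 1 --n-iter 499 --out out/
```

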