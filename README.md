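# clonotrace

Single-cell immune-repertoire and interferon-signature analysis in R.

`clonotrace` is for immunologists and computational biologists analyzing
paired single-cell V(D)J (BCR/TCR) and gene-expression data from clinical
cohorts — the setting of autoimmune interstitial lung disease studies
(e.g. anti-MDA5-positive dermatomyositis), where the questions are: is the
B/T-cell compartment clonally expanded in active disease, are antibodies
under antigen-driven selection, is a type-I interferon program switched on,
and does a baseline biomarker predict one-year survival?

It provides, as tested components with a single pipeline driver:

- **Contig QC and chain pairing** — remove low-confidence, non-productive,
  or <2-UMI contigs; keep cells with exactly one IGH + one light chain
  (BCR) or one TRA + one TRB (TCR). Readers/writers for 10x contig CSV and
  AIRR Rearrangement TSV.
- **Clonotyping** — BCR clones by heavy-chain V/J/junction-length partition
  plus single-linkage clustering at normalized junction Hamming distance
  strictly below 0.1; TCR clonotypes by exact paired-chain identity;
  expansion-level annotation.
- **Repertoire statistics** — Shannon entropy `H = -Σ p_i log2 p_i`,
  clonality `1 - H / log2(N)`, Jaccard sharing of (expanded) clonotypes,
  top-20 clone frequency, observed/expected group-preference ratio
  (R<sub>O/E</sub>), pairwise clonal transition index, V-gene usage log2
  fold changes.
- **SHM & selection** — replacement/silent mutation counting against
  IMGT-gapped germlines (V region nt 1–312, junction excluded), SHM
  frequency, and a Beta-binomial log-odds selection strength
  `Σ = (ψ(r+1) − ψ(m−r+1))/ln2 − log2(p_exp/(1−p_exp))`
  with `p_exp` from single-nucleotide-variant enumeration of the germline
  codons (Σ > 0 = positive selection).
- **Signature scores** — cell QC (≥500 genes, ≤10% mitochondrial),
  LogNormalize (scale 10,000), bin-controlled module scores
  (25 bins × 50 control genes, seeded), rank-based pathway scores,
  comprehensive metabolic score (top-20 pathways), donor-level score
  correlations.
- **Prognostics** — ROC/AUC (= normalized Mann–Whitney U), Youden-index
  cutoff, Kaplan–Meier estimator, and log-rank test, implemented in the
  package (validated against `survival`).
- **Synthetic cohorts** — a fully seeded generator (`sim_config`,
  `simulate_repertoire`, `simulate_expression`, `simulate_survival`) with
  planted clones, program shifts, QC defects, and hazard ratios, so every
  claim is testable without restricted patient data.

## Worked example

```r
library(clonotrace)

cfg    <- sim_config(seed = 1)                 # 4-group cohort, 1,900 cells
rep    <- simulate_repertoire(cfg)
contigs <- filter_contigs(rep$contigs)         # UMI/productive/confidence QC
cells  <- pair_chains(contigs, "BCR")          # one heavy + one light chain
clones <- assign_expansion_level(group_bcr_clones(cells))
clones
#> BCR clone assignment: 1747 cells in 1166 clones (263 expanded)

groups <- setNames(rep$truth$group, rep$truth$barcode)
repertoire_metrics(clones, groups)
#>   stratum n_cells n_clones entropy_bits clonality top_n_freq
#> 1     Act     639      250         7.28   0.08552      0.362
#> 2 CtrlIIM     460      375         8.45   0.01159      0.115
#> 3      HD     377      322         8.25   0.00995      0.127
#> 4     Rem     271      219         7.67   0.01364      0.185
```

The active-disease group (`Act`), whose clone sizes are drawn from a
heavier-tailed distribution, shows the elevated clonality (0.086 vs ~0.01)
and top-20 clone frequency (0.36 vs ~0.12) that the real analysis looks
for; healthy donors and disease controls stay near a flat repertoire.

```r
surv  <- simulate_survival(sim_config(seed = 1, survival_n = 40))
curve <- roc_auc(surv$time_days, surv$event, surv$marker, horizon = 365)
curve
#> ROC: AUC = 0.8042 (12 positives, 20 negatives, horizon 365)
cut <- youden_cutoff(curve)                    # threshold 1.300, J = 0.65
hi  <- surv$marker >= cut$threshold
logrank_test(surv$time_days[hi], surv$event[hi],
             surv$time_days[!hi], surv$event[!hi])
#> log-rank: chi-square = 14.9172 (df = 1), p = 0.0001123
```

High-marker patients (simulated hazard ratio 3) die faster; the marker
discriminates one-year survival (AUC 0.80) and stratifies the Kaplan–Meier
curves (log-rank p = 1.1e-4).

## Pipeline and CLI

```r
run_pipeline(pipeline_config(list(seed = 7, out_dir = "out")))
```

runs simulate → qc → clonotype → stats → shm → score → prognosis and
writes every artifact plus a `manifest.json` of MD5 hashes (deterministic
under the seed). The same pipeline is scriptable:

```sh
Rscript inst/cli/clonotrace.R run --seed 7 --out out [--config cfg.yaml]
```

with subcommands `simulate`, `qc`, `clonotype`, `stats`, `shm`, `score`,
`prognosis`, `run`, a YAML/JSON config, and CLI-flag overrides.

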