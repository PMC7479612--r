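# ancientmt

Authentication, consensus assembly and dating of ancient mitochondrial
DNA, for palaeogeneticists and archaeogenetics pipelines working with
short, deaminated sequence fragments captured from Pleistocene skeletal
material.

## What it computes

Ancient DNA survives as fragments of a few dozen base pairs, carrying
cytosine-deamination damage (read as C→T substitutions concentrated at
fragment ends) and mixed with present-day human contamination. From
aligned fragments, `ancientmt` implements the standard inference chain:

* **Fragment QC** — the ≥ 35 bp, MAPQ ≥ 25 inclusion rule
  (`filter_fragments`), plus TSV/SAM readers and FASTA I/O.
* **Damage profiling** — per-offset C→T mismatch frequency from each
  fragment end, modelled as
  `p(i) = b + (p_max − b) exp(−λ i)`
  (single-stranded library behaviour, both ends symmetric), and
  selection of putatively deaminated fragments with a terminal C→T in a
  `k_term`-bp window (`profile_damage`, `select_deaminated`).
* **Authentication** — fixed archaic/modern differences derived from an
  aligned panel (`find_diagnostic_positions`), per-fragment majority
  vote (`classify_fragments`), and a contamination proportion with a
  Wilson 95% interval (`estimate_contamination`), overall and per
  library.
* **Consensus** — duplicate collapse by identical alignment start/end
  (`dedup_fragments`) and per-position calls requiring coverage ≥ 3
  unique fragments and majority support ≥ 2/3, everything else masked N
  with explicit flags (`call_consensus`, `audit_consensus`).
* **Tip dating** — molecular branch shortening: the missing evolution
  `δ = mean_m d(m, outgroup) − d(query, outgroup)` (Jukes–Cantor
  distances) converted to years as `age = max(0, δ / rate)`, with a
  column-bootstrap confidence interval (`estimate_tip_age`,
  `pairwise_differences`, `distance_matrix`).
* **Radiocarbon calibration** — posterior over calendar age on a 1-year
  grid against an IntCal-style curve, highest-posterior-density ranges
  at any mass, and collagen screening (> 1% yield, C:N 2.9–3.6)
  (`calibrate_date`, `hpd_interval`, `collagen_qc`).
* **Synthetic data** — a fully seeded generator of labelled ancient-DNA
  datasets (panel evolution along a tree, fragmentation, terminal
  deamination, contamination admixture, sequencing error) used to
  validate every estimator against ground truth (`sim_config`,
  `simulate_dataset`).

`run_pipeline()` chains the stages end to end, writing one plain-text
artifact per stage and a manifest with MD5 checksums; a thin
command-line wrapper ships in `inst/scripts/ancientmt`.

## Worked example

```r
library(ancientmt)

cfg <- sim_config(ref_len = 16569, contamination_frac = 0.05, seed = 7)
ds  <- simulate_dataset(cfg, n_fragments = 5000)

frags <- dedup_fragments(filter_fragments(ds$fragments))
profile_damage(frags, ds$ref)
#> <damage_profile> 4978 fragments, K=15
#>   offset :      0      1      2      3      4
#>   C>T 5' :  0.286  0.225  0.179  0.138  0.108
#>   C>T 3' :  0.289  0.203  0.163  0.130  0.100

diag <- find_diagnostic_positions(ds$panel)   # 245 positions here
classify_fragments(frags, diag, ds$ref)
#> <fragment_assignments> 4978 fragments
#>   calls: endogenous=2496, contaminant=125, ambiguous=19, uninformative=2338
#>   fraction matching archaic state: 0.954

estimate_contamination(
  classify_fragments(frags, diag, ds$ref, exclude_damage_like = TRUE))
#> <contamination_estimate> scope=all
#>   point 0.0420 (95% Wilson CI 0.0342-0.0516), 2046 decided fragments (86 contaminant)

audit_consensus(call_consensus(frags, ds$ref, dedup = FALSE), 16569)
#> <consensus_audit> mean coverage 15.4-fold; 0 low-coverage and 2 low-support positions

grid <- seq(5000, 15000, by = 1)
calibrate_date(10000, 100, calibration_curve(grid, grid, rep(10, length(grid))))
#> <calibrated_date> 10000 +/- 100 14C BP
#>   68.2% HPD ranges (cal BP):
#>     10100 to 9900 (68.3%)

collagen_qc(5.4, 3.2)
#> <collagen_qc> yield 5.40%, C:N 3.20: PASS
```

Reading the numbers: the damage profile shows ~29% terminal C→T decaying
into the fragment interior — the authenticity signature. 95.4% of
diagnostic-state matches hit the archaic state, and the Wilson interval
on decided fragments (4.2%, CI 3.4–5.2%) brackets the true simulated
contamination of 5%. The consensus audit reports coverage and the two
exclusion counts; the calibration of 10,000 ± 100 ¹⁴C BP on a linear
curve reproduces the Gaussian 68.2% interval.

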