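# jnknoise

Single-cell heterogeneity of apoptotic JNK signaling from gene
expression noise.

In high-risk neuroblastoma, a fraction of tumor cells survives
chemotherapy without any genetic resistance mechanism. One proposed
origin of this fractional killing is gene expression noise inside the
stress-activated JNK network: each cell draws its own abundance of every
pathway component, and the cells that happen to draw a weak network
cannot activate the apoptotic JNK response at all. `jnknoise` implements
that analysis as a reusable, fully synthetic-testable pipeline for
computational biologists working on single-cell signaling
heterogeneity:

- a deterministic ODE model of the three-tiered MAPK cascade
  ZAK → MKK4/MKK7 → JNK, with distributive two-site
  (de)phosphorylation, a switchable positive feedback in which active
  JNK phosphorylates MKK7 and multiplies its catalytic output, and
  inhibitory Akt cross-talk that drives phosphorylated MKK forms into
  catalytically dead states;
- per-cell parameterization: relative abundances
  (ZAK, MKK4, MKK7, JNK, phospho-Akt; population mean 1, e.g. from
  five-color flow cytometry) scale the protein pools and the cross-talk
  flux of each cell's model instance;
- ensemble simulation of thousands of cells at a basal input
  (1/20th of saturation) and a saturating input (1000 arbitrary stress
  units), with the emergent statistics of the study: the JNK-impaired
  fraction (cells whose stimulated peak never exceeds the mean basal
  activity), the output coefficient of variation, and the
  with/without-feedback contrast;
- kinase translocation reporter (KTR) conversion between
  cytoplasmic:nuclear ratio and active-JNK concentration (four-state
  steady-state model, inversion capped at 200 concentration units);
- longitudinal trace analysis: reporter-expression QC (mean MFI outside
  10–200 excluded), tracking-coverage filters, caspase-onset calling
  (first sample > 50 MFI), peak-window activity, apoptotic-outcome
  grouping with effect-size-gated statistics, commitment-curve
  threshold estimation, and onset-curve slope regression;
- synthetic-data generators that emulate the study's measurements
  (log-normal expression noise with component CoVs of 33–43%, biosensor
  traces, caspase reporters with a phenomenological logistic commitment
  layer), so every stage is testable without any raw data.

## Model sketch

For one cell with relative abundances
(zak, mkk4, mkk7, jnk, pakt), the protein pools are
`T_i = 100 · abundance_i`. Kinase steps are distributive two-site
Michaelis–Menten reactions, e.g. for the MKK4 tier

    d[MKK4**]/dt = k4 · ZAK* · [MKK4*]/(Km + [MKK4*]) − p4 · [MKK4**] − ka4 · pakt · [MKK4**]

and active JNK (JNK**) is produced by active MKK4 plus active MKK7,
where feedback-marked MKK7 (phosphorylated by JNK**) acts with a
40-fold catalytic gain. The stress input S enters as a sustained step
at t = 0; each simulation starts from the cell's pre-stimulus steady
state at the basal input. The feedback makes the stimulated response
ignition-like: cells below the switching threshold stay near basal
(the JNK-impaired subpopulation), cells above it activate strongly,
and the 33–43% component noise is amplified into ~73% output noise.
The right-hand side is compiled C run through `deSolve::lsoda`, with an
independent R implementation backing a fixed-step Runge–Kutta oracle.

## Worked example

```r
library(jnknoise)

cfg <- generatorConfig(nCells = 500L, seed = 42L)   # synthetic flow table
res <- runSingleCellExperiment(config = cfg)
res$summary
#>   n_cells n_failed feedback impaired_fraction cov_stim_percent
#> 1     500        0     full             0.106             73.2
#>   cov_basal_percent cov_nofeedback_percent amplitude_ratio
#> 1               470                   78.2            97.7
```

10.6% of these 500 synthetic cells fail to push their saturated
response above the mean basal activity (the JNK-impaired,
chemoresistance-prone subpopulation), and the 33–43% noise of the five
inputs emerges as a 73% coefficient of variation of the output. Without
the JNK→MKK7 feedback the mean amplitude collapses (ratio ≈ 98×) while
the output CoV *increases* (78.2% vs 73.2%) — the feedback sets the
amplitude, not the noise.

```r
thr <- runThresholdExperiment(config = cfg)        # traces + caspase calls
thr$groups
#> OutcomeGroups: 23 apoptotic vs 445 nonapoptotic cells
#>   Cohen's d = 2.520, fraction above nonapoptotic mean = 1.000
thr$curve$midpoint
#> [1] 0.652
```

After QC filtering, caspase-positive cells sit far above the
nonapoptotic mean peak activity (d = 2.5; every apoptotic cell above
it), and the commitment curve places the 50% apoptosis point near the
generator's configured threshold of 0.6 normalized activity units.

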