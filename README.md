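# edura

Joint structural and functional analysis of bacterial gene regulation on a
circular chromosome.

Bacteria regulate transcription through two distinct infrastructures: the
transcriptional regulatory network (TRN) of transcription-factor genes and
their targets ("digital" control), and the spatial organization of the
chromosome — supercoiling domains and nucleoid-associated proteins acting
on chromosomal neighborhoods ("analog" control). The replication axis
through the origin (Ori) and terminus (Ter) splits the circular chromosome
into its two replichores and is a natural candidate organizer for both.
This package asks, and makes testable, two questions:

1. **Structural** — is the chromosomal embedding of the TRN systematic
   with respect to the Ori–Ter axis? Relative to a candidate axis at
   position *a*, every directed edge falls into one of six categories
   (along the right or left arm, pointing away from or towards Ori —
   r+, r−, l+, l− — or across the arms, rl and lr). The scan statistic
   EDURA (edge distribution under rotation of an axis) rotates the axis,
   tracks the arm asymmetries

   A±^r = (n(r+) − n(r−)) / (n(r+) + n(r−) + n(rl)),

   its left-arm mirror, and the cross–along asymmetry, subtracts the mean
   signal of degree-preserving switch-randomized graphs, and detects a
   systematic axis as a *drop* in the windowed correlation of the two arm
   asymmetries — smooth category transformation under rotation makes high
   correlation the default, so disruption is the signal.

2. **Functional** — do digital and analog control trade off across
   expression contrasts? For each contrast (per-gene logFC column), the
   genes called differentially expressed (|logFC| > T_FC, default 2.5)
   induce an *effective* subgraph of the TRN and of the gene proximity
   network (GPN: genes within T_GPN = 20 kbp linked). The control ratio
   R = N_connected / N_isolated of each effective network is z-scored
   against 10,000 random gene sets (the control-type confidence, CTC),
   giving a digital and an analog control strength per contrast, plus
   their Spearman correlation across contrasts. A shuffle-corrected
   decision-tree analysis complements this: nine per-gene features (Ori
   distance, fis/hns/crp site densities, called GPN neighbors, called TRN
   regulators, three direct-regulation flags) predict the call labels,
   and mean-decrease-impurity importances — corrected by the mean over
   100 label shuffles — are rank-correlated with the CTCs.

Everything runs on synthetic data with known ground truth: generators for
genomes (uniform or clustered gene density), hub-dominated TRNs, binding
sites, planted-axis "systematic random networks", and contrast matrices
whose called sets mix a network-spreading (digital) and a
chromosomal-neighborhood (analog) mechanism with tunable weight λ.

## Worked example

Detect a planted axis:

```r
library(edura)

counts <- c(n_r_plus = 120, n_r_minus = 30, n_l_plus = 120, n_l_minus = 30,
            n_rl = 20, n_lr = 20)
sn <- generate_systematic_network(400, counts, ori_bp = 250000, g = 1e6, seed = 42)
scan <- scan_axes(sn$trn, sn$genome)
scan <- baseline_subtract(scan, sn$trn, sn$genome, n_random = 20, seed = 43)
detect_axis(scan)
#> # A tibble: 1 × 4
#>    ori_bp  ter_bp correlation_min window
#>     <dbl>   <dbl>           <dbl>  <int>
#> 1 249874. 749874.         -0.0283     81
```

The planted Ori at 250,000 bp is recovered to 126 bp: the correlation of
the two arm asymmetries collapses only at the true axis.
`autoplot(scan, axis = detect_axis(scan))` draws the asymmetry curves with
the detected axis marked.

Digital versus analog control on synthetic contrasts:

```r
genome <- generate_genome(2000, g = 1e6, seed = 1)
trn    <- generate_trn(genome, 5000, n_hubs = 20, seed = 2)
gpn    <- build_gpn(genome, 20000)

sim_d <- generate_contrasts(genome, trn, contrast_spec(lambda = 1), 10,
                            seed = 3, contrast_prefix = "dig")  # network spreading
sim_a <- generate_contrasts(genome, trn, contrast_spec(lambda = 0), 10,
                            seed = 4, contrast_prefix = "ana")  # chromosomal windows
cm <- dplyr::inner_join(sim_d$contrasts, sim_a$contrasts, by = "gene_id")

cs <- control_scan(cm, trn, gpn, genome, analysis_config(n_null = 2000, seed = 5))
cs[c(1, 11), c("contrast_id", "n_called", "digital_ctc", "analog_ctc")]
#> # A tibble: 2 × 4
#>   contrast_id n_called digital_ctc analog_ctc
#>   <chr>          <int>       <dbl>      <dbl>
#> 1 dig001             6      49.3        0.229
#> 2 ana001            18       0.907      4.83
glance(cs)
#> # A tibble: 1 × 4
#>   n_contrasts spearman mean_digital_ctc mean_analog_ctc
#>         <int>    <dbl>            <dbl>           <dbl>
#> 1          20   -0.817             46.5            5.28
```

A contrast generated by network spreading scores a digital CTC of ~49
standard deviations above its null and an analog CTC near zero; a
chromosomal-window contrast reverses the pattern, and across the mixture
the two strengths anti-correlate (Spearman −0.82 here). `autoplot(cs)`
draws the digital-vs-analog scatter.

The full pipeline on files (`run_all()`), a threshold robustness sweep
(`parameter_sweep()`), and a thin command-line wrapper
(`inst/cli/edura.R` with subcommands `simulate`, `simulate-systematic`,
`scan`, `ctc`, `features`, `sweep`, `all`) are documented in the package;
the methods vignette (`vignettes/edura-methods.Rmd`) derives the
statistics and records every numerical and design choice.

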