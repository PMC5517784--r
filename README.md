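# opcflux

Reference-gene stability, differential expression and Cumulative Flux
Index (CFI) scoring for cerebrospinal-fluid-treated oligodendrocyte
progenitor cells.

## The problem

Oligodendrocyte progenitor cells (OPCs) remyelinate damaged axons; in
multiple sclerosis (MS) and neuromyelitis optica (NMO), factors present in
patient cerebrospinal fluid (CSF) perturb their energy metabolism. A
one-color microarray experiment comparing OPC cultures exposed to CSF from
different clinical subtypes (two inflammatory relapsing-remitting forms
G+/M- and G+/M+, medullary MS, PPMS, NMO) against non-inflammatory
neurological controls raises three computational questions this package
answers:

1. **Which genes may be used for normalization?** Classical housekeeping
   genes (ActB, Gapdh) are themselves perturbed by CSF exposure. The
   package ranks candidate reference genes with from-scratch
   implementations of two standard stability algorithms:
   * **geNorm**: the stability measure of gene *j* is
     `M_j = mean_{k != j} sd_samples( log2(x_j / x_k) )`, with stepwise
     exclusion of the least-stable gene until an inseparable pair remains
     (tied at rank 1);
   * **NormFinder**: a model-based decomposition of log2 expression into
     intra-group variance and shrunken inter-group deviations; the
     stability value is the group-average of |shrunken deviation| plus its
     estimation uncertainty.
2. **Which genes respond to CSF?** Arrays are scaled to a common 75th
   percentile, low-expressed probes are removed against the pooled 30%
   quantile, probes are merged per gene (geometric mean), values are
   normalized to the geometric mean of the chosen reference genes, and
   per-condition relative expression `r` is tested with one-way ANOVA plus
   Tukey HSD contrasts against control and Benjamini-Hochberg FDR
   (calls require |fold change| >= 2, p < 0.01, FDR < 0.1).
3. **How impaired is glucose metabolism per subtype?** The **Cumulative
   Flux Index** treats each significantly changed enzyme of a pathway as a
   multiplicative factor on that pathway's flux:

   `CFI(pathway, condition) = prod over called members g of r(g, condition)`

   (unchanged members contribute 1, upregulated members their r > 1), and
   `total CFI = prod over pathways CFI` across glycolysis, the TCA cycle
   and the electron transport chain. Lower total CFI = stronger inferred
   bioenergetic impairment; conditions are ranked by it.

The original raw arrays are not publicly deposited, so the package ships a
seeded synthetic-data generator (`default_scenario()`,
`generate_expression()`) that emulates the study design — 6 conditions x 4
replicate arrays, 2 probes per gene, log-normal noise, stable and unstable
reference genes, and per-condition pathway downregulation calibrated so
each condition's configured effect products equal the published
per-pathway CFI values. Every stage of the pipeline is tested against this
generator.

## Worked example

```r
library(opcflux)
cfg <- default_scenario(seed = 1)          # the emulated study design
res <- analyze_expression(generate_expression(cfg), cfg$pathways,
                          probe_map = scenario_probe_map(cfg),
                          candidates = scenario_candidates(cfg))
writeLines(pipeline_report(res))
```

```
== Reference-gene stability ==
gene       geNorm_M  rank   NormFinder  rank    anova_p
B2m           0.092     1        0.150     4     0.0145
Tfrc          0.092     1        0.117     1    0.00741
Hprt          0.153     2        0.148     3     0.0411
Mrpl19        0.153     3        0.144     2      0.327
ActB          0.468     4        0.331     6   1.61e-10
Gapdh         0.498     5        0.311     5   1.85e-12
...
== Condition ranking (ascending total CFI; lower = stronger
   inferred bioenergetic impairment) ==
 1. NMO      2.1E-07
 2. G+/M+    3.5E-07
 3. Med      6.7E-06
 4. G+/M-    1.4E-04
 5. PPMS     2.6E-04
```

The stability block shows both algorithms placing the four simulated-stable
references (Mrpl19, Hprt, B2m, Tfrc) above the unstable housekeeping
candidates (ActB, Gapdh) — geNorm M around 0.09-0.15 versus 0.47-0.50.
The flux block gives each condition's per-pathway CFI (4 decimals) and the
total in 2-significant-figure scientific notation; on this seed the
aggressive forms (NMO, G+/M+, medullary) sit orders of magnitude below the
more benign G+/M- and PPMS, the qualitative conclusion the scenario
encodes.

A file-based run with a manifest:
`run_pipeline(pipeline_config("out", seed = 1))`, or from a shell via the
thin front end `inst/scripts/opcflux` (subcommands `simulate`, `run`,
`stability`, `report`, `reproduce`).

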