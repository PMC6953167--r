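# fusedgrn

Joint Bayesian inference of two gene regulatory networks (GRNs) measured
under different conditions — tumor vs. normal tissue, treated vs.
untreated — with genetic perturbations, for researchers who want the
*differential* network (which regulatory edges changed) and not just two
independently estimated networks.

## The model

Each condition's GRN is a structural equation model coupling expression
`Y` (n samples × p genes) to the weighted adjacency matrix `B` (zero
diagonal, possibly cyclic) and to known cis-eQTL genotypes `X`
(n × q, F2-cross coding {1,2,3}):

    Y⁽ᵏ⁾ = Y⁽ᵏ⁾B⁽ᵏ⁾ + X⁽ᵏ⁾F⁽ᵏ⁾ + E⁽ᵏ⁾,   k = 1, 2.

The eQTLs act as instrumental variables and make directed — even cyclic —
networks identifiable when each gene has at least one unique cis-eQTL
with known support. For each gene the two conditions' regressions are
re-parameterized into a single integrated linear model
`y_i = W_i β_i + e_i` whose coefficient vector stacks both conditions,
and a hierarchical fused shrinkage prior (a Bayesian analogue of the
fused lasso, with adaptive per-term rates) makes the separate networks
*and* their difference `ΔB = B⁽¹⁾ − B⁽²⁾` sparse:

    penalty ~ λ₁ Σⱼ |β_j|  +  λ₂ Σₖ |β_{p_i+k} − β_k|

realized as Gaussian scale mixtures with inverse-Gaussian Gibbs
conditionals. Convergence is monitored with the potential scale reduction
factor (R̂ < 1.1, three chains); posterior means are thresholded
(|entry| > t, default 0.2) to produce sparse networks, and the
differential GRN is the difference of the thresholded matrices. A
relative-change significance filter and bootstrap edge-stability analysis
(edges kept when detected in strictly more than 80 of 100 resamples) are
provided for real-data work, along with a synthetic paired-network
simulator with full ground truth and PD/FDR evaluation.

See the methods vignette (`vignettes/fused-differential-grn.Rmd`) for the
prior, the full conditionals, numerical guards, and design decisions.

## Worked example

```r
library(fusedgrn)

sim <- simulate_paired_dataset(p = 8, n = 120, n_e = 1, sigma2 = 0.01,
                               kind = "dag", seed = 11)
sim$data
#> Paired expression/genotype dataset: 8 genes, 16 eQTLs, 120 samples per condition
sim$truth
#> Ground truth: 8 + 8 edges, 3 differential entries, sigma2 = 0.01

fit <- infer_all_genes(sim$data, hyperparams(), seed = 22)
fit
#> Joint GRN fit: 8 genes, 8/8 converged, 0 failed

B1s <- threshold_network(fit$Bhat1, 0.2)
B2s <- threshold_network(fit$Bhat2, 0.2)
differential_network(B1s, B2s)$edges
#>   source target weight_cond1 weight_cond2    delta
#> 1    G02    G01       -0.875        0.000 -0.87460
#> 2    G08    G01       -0.819       -0.815 -0.00433
#> 3    G07    G03        0.653        0.657 -0.00438
#> 4    G02    G04        0.553        0.541  0.01218
#> 5    G05    G04        0.000        0.820 -0.81958
#> 6    G07    G04       -0.627        0.836 -1.46308
#> 7    G02    G05       -0.526       -0.517 -0.00907
#> 8    G01    G07       -0.600       -0.608  0.00778
#> 9    G02    G07        0.619        0.603  0.01606

unlist(paired_network_metrics(fit$Bhat1, fit$Bhat2, sim$truth, t = 0.2)[1:4])
#>  pd_networks fdr_networks     pd_delta    fdr_delta
#>            1            0            1            0
```

Reading the edge table: rows 1, 5 and 6 are the true differential edges —
an edge present only in condition 1 (`G02→G01`), one present only in
condition 2 (`G05→G04`), and a shared edge whose weight flipped sign
(`G07→G04`, −0.63 vs +0.84). The remaining rows are conserved edges whose
posterior means differ by under 0.02; they vanish once the same threshold
is applied to `ΔB` (which is how the PD/FDR scoring defines differential
support), giving perfect recovery here.

The same pipeline is available from the shell via the launcher in
`inst/scripts/fusedgrn` (subcommands `simulate`, `infer`, `bootstrap`,
`evaluate`, `study`; every run writes a `manifest.json` with its options
and seed, which fully reproduce the outputs).

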