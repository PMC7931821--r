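# mbgan

Simulation of microbiome relative-abundance tables with a Wasserstein
GAN, a Normal-to-Anything (NorTA) copula baseline, and a fidelity
evaluation suite.

## Who this is for

Developers of statistical methods for metagenome-wide association
studies need synthetic abundance tables that look like real gut
microbiome profiles: 70–90% zeros per sample, overdispersed abundances,
phylogenetic structure, and substantial taxa–taxa covariation.
Parametric simulators capture marginals but struggle with the joint
structure.  `mbgan` instead *learns* a simulator from a training table —
no explicit distributional model — and provides everything needed to
check how faithful the result is.

## The method

A generator \(g_\theta\) maps Gaussian noise \(z \sim N(0, I)\) through
fully connected layers to a softmax head, so each output row is a closed
composition over species.  A critic \(f_\omega\) scores samples; the
difference of mean scores estimates the Earth Mover's (Wasserstein-1)
distance, minimized under the WGAN-GP gradient penalty
\(\lambda\,\overline{(\lVert\nabla_{\hat x} f(\hat x)\rVert_2 - 1)^2}\)
with \(\lambda = 10\), five critic steps per generator step, and RMSprop
updates.  Before scoring, every composition passes a phylogeny
transformation: abundances are aggregated over all nodes of a rooted
taxonomic tree (phylum → species) and amplified elementwise by
\(x \mapsto \log[(1+1000x)/(1+x)]\) so rare taxa carry training signal.
Simulated abundances below \(10^{-4}\) are truncated to zero.

The baseline simulator is NorTA with zero-inflated negative-binomial
marginals: correlated Gaussians → \(\Phi\) → uniforms → ziNB quantiles →
counts → row-normalized compositions, with the target correlation matrix
estimated from the training counts.

The evaluation suite computes sample sparsity, Shannon diversity
(\(-\sum_j p_j \log p_j\)) with Wilcoxon rank-sum comparisons,
unweighted UniFrac (\(U_{mk} = \text{unique}/\text{observed}\) branch
length) embedded by non-metric multidimensional scaling, pairwise
Spearman structure (R², MSE), and Lovell proportionality
\(\phi(\log x_m, \log x_k) = \mathrm{var}(\log x_m - \log x_k)/
\mathrm{var}(\log x_m)\) on clr-transformed samples.

The neural-network engine (forward, backward, and the exact
double-backward of the gradient penalty for leaky-ReLU networks) is
implemented directly on R's BLAS matrix operations and verified against
finite differences in the test suite.

## Worked example

```r
library(mbgan)

## a ground-truth fixture: logistic-normal composition, two latent
## correlation blocks, 50% zero-masking, balanced taxonomy
spec <- fixture_spec(n_samples = 120, n_species = 20,
                     correlation = list(structure = "block",
                                        n_blocks = 2, rho = 0.6),
                     zero_inflation = 0.5, branching = c(4, 5), seed = 42)
fx <- make_fixture(spec)
fx$table
#> <abundance_table> 120 samples x 20 taxa (species level)
#>   row closure: rows sum to 1; input normalization: none

model <- mbgan_train(fx$table, fx$tree,
                     gan_config_small(max_iterations = 1500, seed = 1))
model
#> <gan_model> 20 taxa, 26 critic-input nodes, 1500 iterations trained
#>   selected checkpoint: iteration 1500; converged at: not reached

sim <- gan_simulate(model, 200, seed = 2)
report <- compare_fidelity(fx$table, list(mbgan = sim), tree = fx$tree,
                           top_fraction = 0.25, nmds_seed = 3)
report
#> <fidelity_report>
#>   sparsity real       min/median/max 0.250 / 0.500 / 0.750
#>   sparsity mbgan      min/median/max 0.050 / 0.300 / 0.600
#>   shannon  mbgan      median 1.955 (real 2.062), rank-sum p = 0.000681
#>   spearman mbgan      R^2 0.332 MSE 0.0104 | phi R^2 0.000 MSE 0.1376
#>   nMDS stress 0.2944 over 200 samples
```

Read the report as follows: after only 1 500 iterations the simulator
already tracks the real diversity profile (median Shannon 1.96 vs 2.06
nats) and recovers a third of the variance in the pairwise Spearman
structure, while the zero pattern is still under-dispersed (median
sparsity 0.30 vs 0.50) — training longer narrows that gap, and the
vignette discusses the limit this plateaus at for tables with few taxa.
`write_fidelity_report()` serializes the full report (JSON plus UniFrac
and ordination TSVs), and `plot(report)` draws the four standard panels.

A command-line interface over the same functions ships at
`inst/cli/mbgan.R`:

```sh
Rscript inst/cli/mbgan.R fixture  --n 300 --species 30 --out fix/
Rscript inst/cli/mbgan.R train    --input fix/table.tsv --tree fix/tree.nwk --out run/
Rscript inst/cli/mbgan.R simulate --model run/model.rds --n 1000 --out sim/
Rscript inst/cli/mbgan.R norta    --input counts.tsv --n 1000 --out nsim/
Rscript inst/cli/mbgan.R evaluate --real fix/table.tsv --sim sim/simulated.tsv --out report/
```

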