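# succpred

Prediction of succinylated lysine residues in proteins from the structural
and evolutionary context of each lysine.

Succinylation swaps the positive charge of a lysine side chain for a
negative one and is implicated in metabolic regulation and disease, but
annotated sites are scarce: curated benchmarks carry roughly ten unmodified
lysines per modified one. `succpred` implements a complete predictor for
this setting, aimed at computational biologists who have per-residue
profiles for their proteins (a PSI-BLAST PSSM and SPIDER2-style structural
predictions) and want cross-validated site predictions without touching a
web server.

## Method

Each lysine K at position *c* is described by the 31-residue peptide
*P* = {A₋₁₅, …, A₋₁, K, A₁, …, A₁₅}; windows that overrun a terminus are
completed by mirror reflection about the terminal residue (p < 1 → 2 − p,
p > L → 2L − p). The window's tracks become a 657-component descriptor:

* 248 structural values — ASA, helix/strand/coil probabilities p_h, p_e,
  p_c, and backbone angles φ, ψ, θ, τ over the 31 slots;
* 400 PSSM-bigram features — the bigram transition profile
  B(p,q) = Σₖ m(k,p)·m(k+1,q) of the 31×20 linear-probability PSSM window,
  flattened row-major;
* 9 secondary-structure-bigram features — the same transform of the 31×3
  probability window.

The negative class is thinned by k-NN elimination: any negative whose k
nearest neighbours (z-scored Euclidean, both classes pooled) include a
positive is dropped, with k grown from 10 until negatives ≤ 1.10 ×
positives. An RBF-kernel soft-margin SVM (C = 1, γ = 0.01, z-scored
features) provides the decision function
y′ = sign(Σᵢ αᵢ yᵢ exp(−γ‖xᵢ − x′‖²) + β), and stratified n-fold
cross-validation reports sensitivity, specificity, accuracy, Matthews
correlation coefficient and AUC.

A synthetic-data module generates proteins, PSSMs, structural profiles and
site annotations with a tunable class signal δ ∈ [0, 1], in exactly the
file dialects the parsers read, so the whole pipeline is testable without
PSI-BLAST or SPIDER2. See the vignette
(`vignettes/succinylation-prediction.Rmd`) for the full model description
and design rationale.

## Worked example

Balancing a 10:1 benchmark (weakly separated classes, the regime the
elimination rule targets):

```r
library(succpred)
gen  <- synth_generate(synth_config(n_proteins = 60, len_range = c(150, 300),
                                    n_pos = 30, n_neg = 300, delta = 0.1,
                                    seed = 42))
data <- featurize_dataset(gen$records, gen$pssms, gen$profiles)
dim(data$X)
#> [1] 330 657
bal <- balance_dataset(data, k_start = 10)
c(bal$report$k_final, bal$report$retained_negatives)
#> [1] 87 32
round(bal$report$ratio_final, 3)
#> [1] 1.067
```

The neighbourhood had to grow from 10 to 87 before the 300 negatives were
reduced to 32 — within 10% of the 30 positives, so the classifier no longer
learns the class prior.

Cross-validating on a balanced benchmark with a moderate planted signal:

```r
gen  <- synth_generate(synth_config(n_proteins = 120, len_range = c(150, 300),
                                    n_pos = 300, n_neg = 300, delta = 0.25,
                                    seed = 42))
data <- featurize_dataset(gen$records, gen$pssms, gen$profiles)
cross_validate(data, n_folds = 10, seed = 42)
#> 10-fold cross-validation (seed 42)
#>    sensitivity specificity accuracy    mcc auc
#> 1       0.9333           1   0.9667 0.9354   1
#> 2       0.9667           1   0.9833 0.9672   1
#> ...
#> 11      0.9300           1   0.9650 0.9331   1
```

Row 11 is the fold average: at δ = 0.25 the pipeline recovers 93% of the
planted positive sites with no false positives; at δ = 0 the same protocol
returns chance-level accuracy (≈ 0.49), confirming that nothing leaks
between generation and evaluation.

A command-line wrapper over the same functions lives at
`inst/cli/succpred.R` with subcommands `synth`, `extract`, `balance`,
`train`, `evaluate` and `predict`.

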