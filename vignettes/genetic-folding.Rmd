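---
title: "Evolving SVM kernels by genetic folding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving SVM kernels by genetic folding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofold)
```

## The problem

Support vector machines classify through a kernel function $K(x, y)$ that
stands in for an inner product in an implicit feature space. The stock
choices — linear, polynomial, RBF — each impose a fixed functional form and
(for the latter two) hyperparameters that must be tuned. Genetic folding
takes a different route: it *searches* the space of kernel functions
directly, treating a kernel as an evolvable program, and scores candidates
by how well an SVM trained with them classifies held-out data. The target
application shipped with this package is binary clinical survey
classification (a lung-cancer symptom questionnaire: gender, age and
thirteen yes/no symptom indicators), but nothing in the machinery is
specific to it.

## Genotype: the folding chromosome

A candidate kernel is stored as a *linear chromosome*: an ordered array of
genes, each carrying a symbol and a link. Operator genes link to their two
children as `l.r` pairs pointing strictly forward in the array; terminal
genes link to themselves. "Folding" the links turns the flat array into a
binary expression tree. The canonical seven-gene example,

```
links:   2.3, 4.5, 3, 6.7, 5, 6, 7
symbols: *_s, -_s, x, +_v, x, y, x
```

folds into `*_s(-_s(+_v(y, x), x), x)`. `encode_expression()` lays genes
out in breadth-first order, which reproduces this printed layout exactly,
and `decode_chromosome()` inverts it; the test-suite checks the round trip
exhaustively over all trees with up to seven nodes.

Validity is purely structural — symbol arity must match the link form,
links must point forward, and every non-root position must be referenced
exactly once — so the genotype space contains no broken programs, and
symbol-only mutation can never create one.

## Phenotype: expression semantics

The language has terminals $\{x, y\}$ (the two argument vectors) and five
binary operators. Vector operators `+_v`, `-_v` act elementwise (a scalar
operand broadcasts); scalar operators `+_s`, `-_s` first *reduce* each
operand to a scalar by component summation; `*_s` is the inner product
when both operands are vectors and otherwise the product of the reduced
operands. A vector value surviving at the root is reduced by component
summation, so every expression defines a real-valued kernel. These
semantics are a design choice of this package — the encoding itself does
not dictate how mixed scalar/vector operands combine — selected because
(a) every expression is well-typed, (b) hand oracles are easy, and (c) the
plain linear kernel is the expression `*_s(x, y)`, so the evolved language
contains the most important baseline as a special case.

`eval_kernel()` implements the definition recursively per pair.
`kernel_gram()` computes whole Gram matrices without pair loops by
exploiting a closure property: every vector-valued subexpression equals
$\alpha x + \beta y + \gamma \mathbf{1}$ with pairwise scalar fields
$\alpha, \beta, \gamma$, so each node reduces to elementwise arithmetic on
a handful of $n \times m$ matrices ($A B^\top$, row norms, row sums). The
two routes are checked against each other to $10^{-10}$ in the tests; the
vectorized path is what makes evolution affordable.

## Indefinite kernels and Gram repair

Nothing forces an evolved expression to be symmetric (`-_s(x, y)` is not)
or positive semidefinite, while SVM theory and solvers assume both. The
package therefore always symmetrizes, $K \leftarrow (K + K^\top)/2$, and
*clips* the spectrum — eigenvalues below zero are set to zero — before
training. Clipping is the standard repair for indefinite kernels: it is
idempotent, leaves PSD matrices untouched, and yields the PSD matrix
nearest in Frobenius norm. `repair_gram()` exposes both `"symmetrize"` and
`"clip"` for inspection and export, but the training path does not offer a
"train on the indefinite Gram anyway" option: the solver's contract is PSD
input, and silently feeding it an indefinite matrix produces undiagnosable
convergence failures rather than a meaningfully different model.

Two consequences matter for prediction. First, training actually happens
on the *empirical kernel map* of the clipped Gram, $Z = V
\Lambda_+^{1/2}$: a linear SVM on $Z$ is exactly the precomputed-kernel
SVM on $Z Z^\top$, and the factorization is a free by-product of the
repair. Second, a model trained on the symmetrized kernel must be
evaluated with the symmetrized kernel: `kernel_cross_gram()` returns
$(k(u, v) + k(v, u))/2$ between new and training points. Using a
one-sided cross Gram for an asymmetric kernel silently degrades held-out
accuracy — this is easy to get wrong and is why the helper exists.

Non-finite Gram entries (overflow in deeply nested products) invalidate
the kernel outright — fitness 0 — rather than being clamped; clamping
would hide pathological genotypes inside the population. A cosine
normalization $K_{ij}/\sqrt{K_{ii} K_{jj}}$ is available
(`cosine_normalize()`) but off by default, and it refuses kernels with a
non-positive self-similarity.

## Fitness and the evolutionary cycle

Fitness of a chromosome is the mean accuracy of a soft-margin SVM (cost
`C`, default 1) over stratified `cv_folds`-fold cross-validation (default
5) on the training data, using the candidate's repaired precomputed Gram.
One fold assignment is drawn per run and shared by every candidate, so
fitness differences reflect kernels rather than fold luck. The full
training Gram is clip-repaired once per chromosome and folds subset the
factorized map; a principal submatrix of a PSD matrix is PSD, so each fold
still trains on a valid repaired Gram at a fifth of the eigendecomposition
cost. The factorization does use all of the run's rows, including each
inner fold's held-out portion — an unsupervised preprocessing shared
across folds, analogous to fitting a kernel PCA on the training split.
Labels of held-out rows are never seen, and the *outer* evaluation in
`compare_kernels()` is fully nested, so reported accuracies are not
inflated by selection.

The cycle (`evolve_kernel()`, or the modelling wrapper `gfs()`):

1. initialize `population_size` (default 50) random chromosomes, grown to
   depth at most `max_depth` (default 4);
2. score each by cross-validated accuracy;
3. copy the `elitism` best (default 1) unchanged — this makes the
   best-fitness trajectory provably non-decreasing, a tested invariant;
4. fill the rest with roulette-wheel-selected parents mutated at
   `mutation_rate` (default 0.5): each gene, independently, swaps its
   symbol for a uniformly drawn different symbol of the same kind;
5. repeat for `generations` (default 20), optionally stopping early after
   `patience` improvement-free generations (off by default).

Variation is mutation-only — there is no crossover — and mutation is
symbol-only, so tree shapes are fixed at initialization and structural
diversity comes entirely from the initial population. Ties in fitness
break toward lower complexity (operator count), then earlier index:
parsimony pressure plus a deterministic order. When every fitness is zero,
roulette selection falls back to uniform.

All randomness flows through R's RNG; `seed` fields in
`gfs_control()`/`survey_config()` make runs bit-reproducible, and
`compare_kernels()` derives per-fold evolution seeds from the base seed so
folds are independent but reproducible.

## Numerical choices

* **Solver.** The QP is delegated to libsvm (via e1071) on the empirical
  kernel map. Eigenvalues below $10^{-9} \lambda_{\max}$ are dropped from
  the map — they contribute nothing but columns.
* **Scale equivariance.** Evolved kernels arrive at arbitrary magnitudes
  (products of sums can reach $10^6$ and beyond). The SVM is therefore
  solved on $K/m$ at cost $C \cdot m$, with $m$ the mean repaired
  diagonal — an *exact* reformulation (substitute $\beta = m\alpha$ in the
  dual) that leaves the decision function unchanged while keeping the QP
  well-scaled.
* **Tolerances.** Fitness evaluations run the solver at KKT tolerance
  0.05; reported comparisons and final refits use 0.001
  (`svm_control()`). Fitness is a selection signal computed thousands of
  times per run; the looser tolerance changes cross-validated accuracies
  negligibly (spot-checked at the third decimal) while avoiding rare
  multi-second solver stalls on ill-conditioned candidates.
* **Degenerate inputs.** Constant Gram matrices (information-free
  kernels), non-finite entries, and empty positive spectra all score
  fitness 0; single-class training labels are an error, as is a class
  smaller than the fold count.

## The synthetic survey generator

`synthesize_survey()` emulates the shape of the motivating clinical survey
so that every pipeline stage can be exercised without the external
dataset: 309 records by default, a 39:270 benign:malignant imbalance, age
$\mathcal{N}(62.6, 8^2)$ rounded and truncated to plausible bounds
[21, 90], gender as a fair coin, and thirteen 1/2-coded symptoms whose
marginal means match the study's reported feature table (fatigue 1.8,
coughing and shortness of breath 1.6, the rest 1.5). The age SD and the
gender balance are not reported for the study population and are set once
to survey-plausible values.

A *linear* signal is planted by shifting each symptom's class-conditional
prevalence by `linear_effect` (default 0.2) while preserving the marginal
mean exactly. A *nonlinear* signal (`nonlinear_pair`) draws two symptoms
fair-coin and gives the outcome log-odds an XOR interaction of size
`effect_size`, with the intercept solved numerically so the marginal
outcome rate is unchanged.

What the generator does **not** emulate: correlated symptoms, age- or
gender-linked outcome effects, non-stationary survey artifacts, and label
noise beyond the Bernoulli outcome model. Tests passing on this generator
therefore demonstrate that the machinery recovers planted signals of the
stated forms — not that the evolved kernels would reach any particular
accuracy on real survey data.

## The comparison experiment

`compare_kernels()` runs the nested protocol: one stratified 5-fold outer
split shared by all models; per outer fold an evolution on the training
portion only, then the evolved kernel and the linear/RBF/polynomial
baselines are trained on that portion and scored on the held-out fold
(accuracy, Mann–Whitney AUC from decision scores, MSE of 0/1-coded
predictions — identical to the misclassification rate, the one coding
that keeps MSE in $[0,1]$ alongside accuracy). Means and SDs (sample SD,
$n-1$) are reported across folds. Baseline hyperparameters default to
$C = 1$, `gamma = "scale"` ($1/(d \cdot \mathrm{var}(X))$), degree 3,
`coef0` 0. Feature standardization is re-fit on each outer training split
to avoid leakage.

The shipped demonstration condition is planted-XOR survey data with
*balanced* classes ($n = 300$, interaction effect 6 on the log-odds scale,
no linear effects). Balance is deliberate: under the study's 87:13
imbalance an XOR signal cannot beat the majority rule, so every model
would tie at the majority rate and the comparison would be vacuous. On
true XOR a linear kernel can label at most three of the four
feature-combination cells correctly (empirically 50–75% here), while the
evolved language contains products of inner products — degree-2
polynomial behaviour — and reliably reaches 90%+; the acceptance checks
assert the evolved kernel matches or beats the linear baseline in at
least 4 of 5 seeded replicates. Problem sizes throughout (n = 300 for the
comparison, n = 10,000 for generator moments, 1,000-case property loops)
were chosen once as the smallest scales at which the statistical
assertions are stable.

## Known limitations

* Mutation-only, structure-frozen variation means the search cannot grow
  trees beyond the initial population's shapes; an optional
  subtree-regenerating mutation is a natural extension.
* Spectrum clipping makes the *training* kernel PSD but the evolved
  function itself remains indefinite; test-time kernel values are used
  through the same symmetrized map, which is consistent but means the
  "kernel" reported to users is the expression, not the repaired
  operator.
* Fitness shares one fold assignment per run — cheap and low-variance for
  ranking, but fitness values are optimistically biased estimates of
  generalization; trust the nested `compare_kernels()` numbers, not raw
  fitness, when quoting accuracy.
* Class imbalance handling (`balance = "weights"` or `"oversample"`) is
  available but off by default; with strong imbalance, accuracy is a
  blunt fitness signal and a rank-based objective would be better.
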