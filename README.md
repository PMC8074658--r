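# backmic

Estimation of the **maximal information coefficient (MIC)** for paired
numeric samples, with grid refinement terminated by a chi-squared test
instead of a hard cap on the number of bins.

MIC measures dependence of any functional form. For a paired sample
$(X, Y) \in \mathbb{R}^n \times \mathbb{R}^n$,

$$\mathrm{MIC}(X,Y) = \max_{n_x n_y \le B(n,\alpha)}
  \frac{\max_G I_G(X,Y)}{\log_2 \min(n_x,n_y)},$$

the maximum over $n_x \times n_y$ grids $G$ on the scatterplot of the
normalized mutual information of the induced contingency table, with
$B(n,\alpha) = n^\alpha$. It is 1 for noiseless functional relationships,
tends to 0 for independent pairs, and depends on the data only through
ranks.

The package implements three estimators of this quantity:

* `backmic()` — the chi-squared-gated **back-search** estimator. One axis is
  equipartitioned, the other refined cut by cut; each candidate segment
  point must pass a chi-squared test on its *detection area* (the two
  columns it creates, crossed with all bins of the other axis; Yates
  continuity correction when that table has two rows; threshold 0.01). The
  originally equipartitioned axis is then re-searched from scratch with the
  learned partition held fixed, so both axes of the reported grid are
  controlled by the test and the original $\log_2\min(n_x,n_y)$ normalizer
  is retained. Because the gate, not $B(n,\alpha)$, stops refinement, the
  score is essentially independent of $\alpha$.
* `chimic()` — the gated search without the back-search, normalized by
  $\log_2 n_{equ}$ (the equipartitioned axis's bin count).
* `appmic()` — the original dynamic-programming approximation
  (equipartition one axis, optimize the other, over all shapes under the
  cap).

Around the estimators: generators for the benchmark simulation designs
(13 noiseless functional relationships, 'I'-type and chequerboard block
patterns, independence nulls, noise-amplitude suites), evaluation
procedures (`statistical_power()`, `run_power_experiment()`,
`run_equitability_experiment()`, `grid_frequency()`, `alpha_sweep()`), and
K-means clustering of expression samples under the $(1-\mathrm{MIC})$
distance (`kmeans_mic()`, `purity()`, `rand_index()`), as used for
cancer/normal sample classification. Everything is deterministic for fixed
input; simulation and clustering functions take explicit seeds.

## A worked example

```r
library(backmic)

p <- gen_function_pair("parabolic", 500, noise_level = 0.2, seed = 1)
backmic(p)
#> <mic_result> backmic = 0.7583  grid 7 x 2  (I = 0.7583 bits, n = 500)
#>   equipartitioned axis: y  n_equ: 2  norm: min

chimic(p)$score     # 0.7481 — equipartition restriction, log2(n_equ) normalizer
appmic(p)$score     # 0.8485 — cap-bound search, varies with alpha

# independence: scores shrink toward 0
backmic(gen_independent_pair(1000, seed = 2))$score
#> 0.0153 (a 2 x 3 grid)

# the noiseless 'I'-type block pattern: 520 points in 13 unit squares
backmic(gen_itype(40, 0, seed = 3))
#> <mic_result> backmic = 0.2720  grid 3 x 4  (I = 0.4312 bits, n = 520)
```

On the noisy parabola the three estimators agree on strong dependence while
differing in grid and normalizer; on independent draws the score collapses
toward zero on a near-minimal grid. The 'I'-type score sits just above the
pattern's ideal 3×3 value $I/\log_2 3 = 0.2561$: the gate keeps the three
column blocks and occasionally admits one extra row of sampling structure.

Clustering expression samples:

```r
m  <- read_matrix("expr.tsv")              # genes x samples, ids in col 1
m  <- top_variance_filter(m, 1000)
cl <- kmeans_mic(m, K = 2, distance = "mic", seed = 7)
purity(cl, truth); rand_index(cl, truth)
```

A thin command-line front end over these functions ships in
`inst/cli/mic.R` (`compute`, `matrix`, `simulate`, `cluster`, `bench`
subcommands).

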