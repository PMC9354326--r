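# dagboot

Bootstrap-aggregated structure learning of directed acyclic graphs (DAGs)
over **mixed continuous and binary variables**.

## Who this is for

Systems-biology and biomarker studies often need a *directed* dependence
network over variables of mixed type: protein, metabolite or transcript
abundances (continuous) together with a clinical endpoint such as
treatment response (binary, 0/1). Single-run greedy structure learners
are fast but notoriously unstable — a large share of their edges reflect
chance correlation. `dagboot` addresses both problems: it scores mixed
node types with the appropriate regression model each, and it stabilizes
the estimate by learning one DAG per bootstrap resample and aggregating
the ensemble into a consensus.

## The method

Each node is scored given its parent set with a decomposable BIC:

- continuous node *X*: `n·log(RSS_X / n) + |pa_X|·log(n)` from the
  least-squares fit of *X* on its parents (binary parents enter as 0/1);
- binary node *Y*: `−2·loglik + |pa_Y|·log(n)` from a logistic
  regression of *Y* on its parents;
- graph score = sum of node scores, minimized by a hill-climbing search
  over add / delete / reverse moves with incremental score and
  acyclicity bookkeeping (the search core is C++), and optional
  whitelist/blacklist edge constraints.

For stability, `B` DAGs are learned on bootstrap resamples and the
consensus is the DAG minimizing the mean structural Hamming distance
(SHD; a reversal counts one unit) to the ensemble:

```
d(G, G~) = Σ_{i<j} max{ |A(i,j) − A~(i,j)|, |A(j,i) − A~(j,i)| }
(1/B) Σ_b d(G, G_b) = Σ_{e ∈ E(G)} (1 − 2·gp_e) + C,   gp_e = f_fwd + f_rev/2
```

so an edge enters the consensus exactly when its generalized selection
frequency `gp` exceeds 1/2. The package also ships the calibrated
synthetic-data generator (linear Gaussian mechanisms with
signal-to-noise control and heavy-tailed/skewed noise options, logistic
mechanisms for binary nodes) and the power/FDR/F1 evaluation harness
used in its experiments.

## Worked example

A small mixed-type network: ten continuous nodes plus one binary node
that is the child of two continuous parents and the parent of one
continuous child (the shape of an outcome wired between biomarkers).

```r
library(dagboot)

mech <- mixed_motif_mechanism(p_continuous = 10, n_extra_edges = 5, seed = 7)
d    <- simulate_dataset(mech, n = 500, seed = 8)
fit  <- bagged_dag(d, config = bag_config(B = 25, seed = 9))
fit
#> dag_bag: consensus of B = 25 bootstrap DAGs; 8 edges

consensus_edges(fit)
#>   parent child f_forward f_reverse   gp
#> 1     X2    X5      0.84      0.16 0.92
#> 2     X2    X9      0.92      0.04 0.94
#> 3     X3    X2      0.80      0.20 0.90
#> 4     X3    X6      0.72      0.28 0.86
#> 5     X3    Y1      0.80      0.20 0.90
#> 6     X5    Y1      0.72      0.24 0.84
#> 7    X10    X9      0.68      0.32 0.84
#> 8     Y1    X9      0.96      0.04 0.98

skeleton_metrics(fit$dag, mech$dag)
#> skeleton: power 1.0000, FDR 0.0000, F1 1.0000 (8/8 true, 8 est)
directed_mixed_metrics(fit$dag, mech$dag, mech$kinds)
#> directed_mixed: power 1.0000, FDR 0.0000, F1 1.0000 (3/3 true, 3 est)
```

All eight true edges are recovered with no false positives, including
the directions of the three continuous–binary edges (`X3→Y1`, `X5→Y1`,
`Y1→X9`); `f_forward`/`f_reverse` show how often each edge (and its
reversal) appeared across the 25 bootstrap DAGs. On harder problems the
`gp` column separates confident consensus edges (`gp` near 1) from
marginal ones (`gp` just above 0.5).

Prior knowledge enters through edge lists:

```r
pri <- prior_lists(whitelist = data.frame(parent = "X3", child = "Y1"),
                   blacklist = data.frame(parent = "X9", child = "Y1"))
fit2 <- bagged_dag(d, priors = pri, config = bag_config(B = 25, seed = 9))
```

A command-line front end with `simulate`, `learn`, `evaluate` and
`experiment` subcommands is installed at
`system.file("scripts", "dagboot", package = "dagboot")`.

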