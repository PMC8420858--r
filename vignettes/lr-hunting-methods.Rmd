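---
title: "LR hunting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LR hunting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell–cell communication is commonly inferred from single-cell expression
data by scoring ligand–receptor (LR) gene pairs: a ligand measured in a
*sender* cell population and its cognate receptor measured in a *receiver*
population. Most scoring schemes treat each pair in isolation (correlations,
expression products, permutation tests). Biologically, however, several
ligands compete for the same receptor and signalling programs are
coordinated, so the LR relationships are many-to-one or many-to-many.
`lrhunt` ranks all candidate pairs *simultaneously* inside one multivariate
model: an unsupervised random forest in which variables that interact tend
to split near each other.

The obstacle is that ligand expression lives in the sender cells and
receptor expression in the receiver cells — no cell ever observes both. The
package therefore works in an *interaction space*: with $X^{(A)}$ the
$n_A \times p_A$ sender/ligand matrix and $X^{(B)}$ the $n_B \times p_B$
receiver/receptor matrix, the stacked $(n_A + n_B) \times (p_A + p_B)$
matrix has two structurally missing off-blocks (sender rows × receptor
columns, receiver rows × ligand columns). The blocks are completed with
random-forest imputation under the working assumption that expression
follows one joint distribution, and the completed data are analysed with
unsupervised forests.

## Unsupervised multivariate forests

Trees are grown on bootstrap samples (on average $(1-1/n)^n \approx 37\%$
of cases are out of bag, OOB). Because there is no response variable, every
node draws a fresh random set of $q$ *pseudo-responses* among the columns
and evaluates a candidate split $s$ on a candidate variable $X_i$
(daughters $t_L = \{X_i \le s\}$, $t_R = \{X_i > s\}$) by the multivariate
within-daughter sum of squares

$$D_q(s,t) = \sum_{k=1}^{q} \Big[ \sum_{j \in t_L} (X_{j,k} - \bar X_{t_L,k})^2
 + \sum_{j \in t_R} (X_{j,k} - \bar X_{t_R,k})^2 \Big],$$

minimized over `mtry` candidate variables and all midpoints between
consecutive distinct in-node values. Candidate variables and
pseudo-responses are allowed to overlap (a variable acting as its own
pseudo-response contributes no information and is harmless). An alternative
unsupervised construction — predicting a synthetic dataset drawn from the
column marginals — is available as
`forest_params(unsupervised_mode = "synthetic_contrast")`; the
pseudo-response rule is the default because it is the one the split
statistic above defines.

### Missing values during growing

Missing entries are *discarded* from the split statistic. To route a case
whose split-variable value is missing, the value is replaced by a random
draw from the in-bag non-missing in-node values of that variable, redrawn at
every node. OOB cases are dropped down the tree by the same rules, so every
case lands in exactly one terminal per tree.

### Imputation

After a forest is grown on the incomplete matrix, each missing entry
(cell $i$, gene $g$) is imputed as the average over trees of the mean of
*OOB* non-missing values of $g$ in $i$'s terminal node, falling back per
tree to in-bag terminal values and finally to the gene's observed mean (the
fallback is needed because small terminal nodes may contain no OOB
non-missing data; occurrences are counted on the returned object). A mean
rather than a random draw makes single imputations stable and testable;
stochasticity across imputations enters through bootstraps and seeds.
Imputation is a single pass — robustness comes from repeating the whole
procedure $M$ times (multiple imputation), not from iterative refinement.

## Pairwise minimal depth and the IMDI

For a variable $v$, a *maximal $v$-subtree* is a subtree whose root splits
on $v$ and has no ancestor splitting on $v$; the minimal depth $D_v$ is the
distance from the tree root to the closest such root. Within a maximal
$v$-subtree of depth $m$ (longest root-to-terminal path, in edges), the
pairwise depth $d$ of a second variable $w$ is the within-subtree depth of
the closest maximal $w$-subtree root. Interacting variables split close
together, so small $d$ recurring across trees is evidence of interaction.
Each observation is normalized as $d/m \in [0,1]$; `make_figure1b_tree()`
ships the worked example (two maximal $v$-subtrees; in the deeper one,
$d = 2$, $m = 3$, $d/m = 2/3$). Two conventions deserve note:

* $m$ is the depth of the maximal $v$-subtree, not of the $w$-subtree —
  that is the convention under which the worked example's $2/3$ arithmetic
  holds, and the one implemented.
* An ordered pair with no co-occurrence in the whole forest scores the
  maximal penalty 1: absent evidence must rank weakest, because smaller
  values indicate stronger interaction.

Directional observations are averaged over all (tree, maximal subtree)
occurrences, each direction over its own observation count, and the final
index is the mean of the two directional means. Computed on imputed dataset
$m$ this gives $I_{(m)}(S)$ for gene pair $S$, and the aggregated index is

$$I(S) = \frac{1}{M} \sum_{m=1}^{M} I_{(m)}(S),$$

which stabilizes by about $M = 20$ (the package default; the test suite
checks that two independent $M=20$ runs agree better than two $M=5$ runs).
Significance is assessed against the empirical distribution of $I(S)$ over
the candidate-pair ensemble: $p(S)$ is the left-tail proportion including
$S$ itself, so $p \in [1/n_{\text{pairs}}, 1]$ and ranking by $p$ equals
ranking by $I(S)$. The empirical ensemble is the candidate LR table per run
direction; sender→receiver and receiver→sender are separate runs.

An analytic alternative to $d/m$ is available
(`normalization = "cdf"`): under a balanced-tree model where each node
splits on one of $p$ variables uniformly, a weak variable's minimal depth
has
$$\mathbb{P}(D_v = s) = (1 - 1/p)^{2^s - 1}\big[1 - (1 - 1/p)^{2^s}\big]$$
($2^s - 1$ nodes above level $s$ miss $v$, at least one of the $2^s$ nodes
at level $s$ hits it), and the pairwise depth CDF follows by the
convolution over subtree positions. The exponents are $2^s$, not $2s$; the
Monte-Carlo simulation in the test suite is the arbiter of that reading.
$d/m$ is the default because it gives very similar ranks at a fraction of
the bookkeeping.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 1000 | trees per forest (imputation and detection stages) |
| `M` | 20 | imputations aggregated into $I(S)$ |
| `mtry` | $\lceil\sqrt{p}\rceil$ | candidate split variables per node |
| `q_pseudo` | $\lceil\sqrt{p}\rceil$ | pseudo-responses per node |
| `nodesize` | 5 | minimum in-bag terminal size; nodes under `2*nodesize` stop |
| `max_depth` | none | optional depth cap |
| `normalization` | `"dm"` | $d/m$ or analytic CDF |
| `seed` | 1 | master seed; all stage streams derive from it |

`n_trees = 1000` and `M = 20` are the method's stated operating point;
`mtry`, `q_pseudo` and `nodesize` are conventional forest defaults surfaced
in the configuration because the method itself does not pin them.

## Numerical and design choices

* **Split points** are midpoints between consecutive distinct in-node
  values — exhaustive and reproducible.
* **Tie handling.** The exposed `best_split()` breaks ties deterministically
  (lowest variable index, then lowest split value). Inside tree growing,
  exact ties of $D_q$ — which are common in small nodes, where two
  variables often induce the *identical* case partition — are instead
  broken uniformly at random (seeded). Awarding ties to the lowest index is
  not harmless at forest scale: it measurably biased forest-averaged pair
  depths along the column order of the input matrix (about $-7\times10^{-4}$
  per column index on independent noise, eight standard errors from zero),
  which distorts null rankings. Random tie-breaking removes the bias while
  keeping runs bit-reproducible under a fixed seed.
* **Determinism.** Every stage derives its RNG stream from the master seed
  with a labelled hash; the same configuration yields byte-identical result
  tables. Rows of the interaction space are ordered by cell id, so results
  are invariant to the row order of the input matrices.
* **Degenerate inputs.** Columns or rows with no observed values are
  rejected before imputation; candidate variables with fewer than two
  distinct in-node values are unsplittable; a node with no valid split
  becomes terminal. A gene acting as both ligand and receptor keeps two
  role-suffixed columns rather than being merged.
* **Rank sums across samples** (for interaction diagrams) penalize a pair
  absent from a sample with that sample's `max(rank) + 1`.
* **Comparison score.** For benchmarking against product-based rankings the
  package provides the penalized product
  $\sqrt{lr} / (\mu + \sqrt{lr})$ with user-supplied scale $\mu$
  (conventionally the mean nonzero expression).

## The synthetic generator

`generate_dataset()` emulates *post-normalization* expression of two
populations sharing latent activity: each planted pair $k$ has a latent
factor $z_k$ realized per cell in both populations; the planted ligand
(sender block) and receptor (receiver block) load on it with strength
$\beta$ (default 2, noise $\sigma = 1$, $n_A = n_B = 200$,
$p_A = p_B = 20$, 5 planted pairs), and `n_context` genes per block
(default 5) load on the same factors. Context genes matter: without
informative companions in each block the interaction space has no structure
to recover at all. Remaining genes are independent noise; an optional
Poisson/log-normal layer followed by library-size log-normalization
emulates count data. The default candidate table is the full
$p_A \times p_B$ cross product.

What the generator does *not* emulate: zero inflation and dropout, library
size variation across cells (beyond the optional count layer), batch
effects, doublets, and ambient contamination. Passing tests on this
generator demonstrate the machinery's statistical behaviour, not
performance on raw scRNA-seq pathologies — real input is expected to be
normalized upstream (e.g. SCTransform-style workflows); `log_normalize()`
is only a basic convenience.

## Known limitations

* **Cross-block identifiability.** No cell observes both blocks, so the
  joint distribution linking sender and receiver measurements is not
  identifiable from the data; imputed cross-block values reproduce local
  marginal structure, not cell-level truth. Empirically (and by
  construction), imputed entries do not correlate with withheld truth in a
  matched-rows simulation. What the pipeline detects is therefore driven by
  the *marginal informativeness* of both pair members — genes that
  organize their own population's variation split near roots in the
  detection forests and co-occur in shallow subtrees. On the synthetic
  conditions above this recovers planted pairs with AUC well above 0.8
  while scoring chance level when no structure is planted.
* Pairs are single ligand gene × single receptor gene; multi-subunit
  complexes are excluded at load time.
* Minimal depth conflates main effects with interactions; the empirical
  p-values are relative to the candidate ensemble of the run, not
  calibrated error rates.

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use deliberately scaled study
sizes chosen to make the statistical checks decisive yet quick: recovery at
the generator defaults with $M = 5$ and 200 trees (AUC averaged over three
replicates), stability comparisons on $100+100$ cells and $10+10$ genes
with 100 trees, the OOB law at $n = 1000$ over 1000 bootstraps, and the
minimal-depth law on 20,000 simulated balanced trees. The full operating
point ($M = 20$, 1000 trees) is the package default for real analyses.
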