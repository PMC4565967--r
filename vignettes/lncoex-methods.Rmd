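---
title: "Methods: co-expression-based lncRNA function annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression-based lncRNA function annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncoex)
options(lncoex.quiet = TRUE)
```

# The model

`lncoex` annotates long non-coding RNAs by guilt-by-association: a lncRNA
whose expression co-varies with a set of protein-coding genes across samples
is hypothesised to participate in the biological processes those genes are
annotated with. The pipeline has four statistical stages, each exposed as a
tibble-first function.

## Association testing

For a query lncRNA with expression $x$ and a protein-coding gene with
expression $y$ over $n$ matched samples, two methods are offered.

**Linear regression** (`method = "regression"`, the default): ordinary least
squares of $y$ on $x$, i.e. the lncRNA is treated as the putative regulator.
The slope is $b = S_{xy}/S_{xx}$ and its two-sided $t$-test on $n - 2$
degrees of freedom provides the significance. For simple OLS the slope
$t$-statistic is algebraically identical to the Pearson correlation test, so
the direction of the regression does not affect which pairs are called
significant — the regulator framing is interpretive, not statistical. By
default both profiles are transformed as $\log_2(x + 1)$ first
(`log_transform = TRUE`): FPKM/RSEM-scale values are strongly right-skewed
and a handful of extreme samples would otherwise dominate the least-squares
fit. The signed Pearson correlation $r$ is stored alongside the slope as the
correlation-scale effect.

**Spearman rank correlation** (`method = "spearman"`): the Pearson
correlation of average-ranked values (ties receive mean ranks), with the
two-sided $t$-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ degrees of freedom;
$\rho = \pm 1$ is reported as $p = 0$. The $t$-approximation is used at every
sample size rather than an exact permutation null; this matches common
practice at RNA-Seq dataset sizes but is coarse below roughly 10 samples — a
documented limitation, not a configuration.

Pairs where the protein-coding gene is constant across samples have no
defined correlation; they are skipped with a log entry rather than failing
the run. A constant *query* lncRNA is excluded with a warning.

## Expression filtering

Only expressed genes are tested. `filter_expressed()` keeps a gene when its
mean expression exceeds `expr_threshold` (default 0.001, suited to
FPKM/RSEM-scale values where true zeros and trace noise sit well below it).
Because it is ambiguous whether such a cutoff should apply to the average or
to individual samples, a second mode keeps genes exceeding the threshold in
at least half the samples (`expr_filter_mode = "fraction"`); the mean is the
default.

## CEG extraction

A gene is a co-expressed gene (CEG) of a lncRNA when **every configured
threshold passes**: $p \le$ `p_threshold` and $|r| \ge$ `coef_threshold`.
Either may be left unset, but not both — a disjunctive reading would admit
arbitrarily non-significant pairs through the coefficient branch alone. The
coefficient threshold applies to the correlation-scale effect $r$ rather than
the raw slope so that a single value is meaningful for both methods (slope
units depend on arbitrary expression scaling). Defaults are $p \le 0.01$ with
no effect-size floor, the tool's standard operating point for a single
dataset.

## Combinatorial merging

Two semantics connect multiple lncRNAs to one gene set:

* **union** — genes co-expressed with *any* of the lncRNAs; enrichment of the
  union reflects functions coordinately correlated with the group;
* **intersection** — genes co-expressed with *all* of them; enrichment
  reflects cooperative correlation of shared targets.

With several datasets the merge is strictly two-level: first across lncRNAs
within each dataset, then across datasets (`merge_across_datasets()`). The
order matters — for mixed modes (say union within, intersection across) the
flattened one-shot merge computes a different set, so no flattened variant is
offered. An empty intersection is a legitimate biological outcome; it
propagates as an empty set with a warning instead of an error, and
enrichment of an empty set returns an empty table.

## Enrichment

The merged CEG set is tested against GMT collections (GO BP/CC/MF, KEGG) with
the one-sided upper-tail hypergeometric test:

$$P(X \ge k) = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

where $N$ is the universe, $K$ the term size, $n$ the CEG count and $k$ the
overlap, all counted **inside the universe**. Over-representation only;
depletion is out of scope.

The universe default is `"annotated"`: expressed protein-coding genes
carrying at least one annotation in the collection under test. Genes with no
annotation can never contribute to an overlap, so including them
(`universe = "all"`) only shrinks every expectation $nK/N$ and inflates
significance uniformly; the annotated background is the conservative choice.
Note the direction of this sensitivity: at fixed $(k, K, n)$, *growing* $N$
lowers the expected overlap and therefore lowers $p$.

Corrections: Bonferroni ($\min(1, mp)$) and Benjamini–Hochberg step-up,
applied **per collection** — GO BP, CC, MF and KEGG are reported as separate
lists, so each is its own multiple-testing family. Results are filtered to
adjusted $p \le$ `alpha` (default 0.05; raw $p$ when `correction = "none"`),
terms with zero overlap are never reported significant, and term-size bounds
(default 5–1000 after universe restriction) drop terms too small to be
stable or too broad to be informative.

## Network export

`build_network()` emits the strictly bipartite lncRNA–CEG graph, one edge per
association that passed thresholds, with coefficient, p-value and dataset as
edge attributes. Multi-dataset graphs keep one edge per dataset so
cross-dataset support is visible; `collapse_edges()` merges parallel edges,
keeping the smallest p-value and recording the supporting datasets. GraphML,
SIF (plus an edge-attribute table) and node/edge TSV are all re-readable by
`read_network()`, which re-checks bipartiteness.

# Numerical choices

* The hypergeometric tail is accumulated in log space (`lchoose` plus
  log-sum-exp) so that genome-scale universes do not underflow term by term;
  the result is clamped to $[0, 1]$ and $k = 0$ returns exactly 1.
* Correlations are clamped to $[-1, 1]$ before the $t$-transform so that
  floating-point excursions beyond $\pm 1$ yield $p = 0$ rather than `NaN`.
* BH adjustment delegates to `stats::p.adjust`; set merges are plain sorted
  set algebra, so results are independent of input order.
* All writers emit numbers at full round-trip precision; reruns of any
  command with the same inputs and seed are byte-identical, and the
  `manifest.json` written alongside every output records the resolved
  configuration, MD5 hashes of the inputs (keyed by file name), package
  version and seed.

# The synthetic benchmark

`simulate_dataset()` generates the data every stage is tested on. Each lncRNA
is a latent standard-Gaussian signal $z_l$; each of its targets is
$z_g = \rho z_l + \sqrt{1-\rho^2}\,\varepsilon$ with independent Gaussian
$\varepsilon$, and every latent profile is mapped through
$\exp(\mu + \sigma z)$ to a lognormal FPKM-like scale ($\mu = \sigma = 1$: a
median near 2.7 with a heavy right tail). Planting the correlation on the
latent scale keeps it analytically controllable: the lognormal map is
monotone, so rank statistics see $\rho$ exactly — for bivariate Gaussians the
population Spearman coefficient is $(6/\pi)\arcsin(\rho/2)$ (about 0.786 at
$\rho = 0.8$), and tests compare against that image rather than $\rho$
itself. Pearson-scale statistics see the correlation only approximately,
which is intended: it mimics the mild nonlinearity of real abundance data.

The default parameters are the package's standard benchmark condition, chosen
once as a realistic single-dataset scenario: 50 samples (a typical GEO
RNA-Seq series), 2 query lncRNAs with 50 targets each at $\rho = 0.8$ (a
strong but noisy regulatory module), 2000 unrelated null genes (so null
calibration is measured on 4000 pairs), and per lncRNA one planted term
holding 80% of its targets (filled to 50 members with null genes) plus 10
decoy terms of 20–60 null genes. Decoys are drawn **only** from non-target
genes, guaranteeing clean separation for rank-based recovery checks. Terms
are planted per lncRNA, so the generator exposes `decoy_terms_per_lnc`
rather than a flat total term count; the total
(`n_lncrnas * (1 + decoy_terms_per_lnc)`) is carried in the parameter
object. The whole bundle — expression, catalog, GMT, ground truth — is
reproducible bit for bit from the seed, and `write_fixture()` round-trips
through the package's own readers.

What the generator does **not** emulate: count overdispersion (negative
binomial noise), library-size and batch effects, correlated null genes
(co-expression among non-targets), missing values, or annotation bias. A
passing benchmark therefore demonstrates statistical correctness and
calibration of the machinery — sensitivity $\ge 0.95$ at $\rho = 0.8$,
$n = 50$; null admission within [0.005, 0.02] at $p \le 0.01$; planted terms
ranked first and BH-significant — not performance on any particular real
dataset, where effect sizes are smaller and nulls are not independent.

Problem sizes throughout the test suite and the acceptance script were
chosen to exercise genome-like proportions at desk scale: 2100 genes × 50
samples for the benchmark, universes of a few hundred to 15000 for the
hypergeometric checks, 200–500 random instances for the estimator-oracle
comparisons.

# Design decisions

* **Annotation modes.** GENCODE distributes lncRNAs both as a separate GTF
  and as biotypes inside the main annotation; `read_gene_catalog()` supports
  both (two-file mode classifies *everything* in the lncRNA file as lncRNA;
  single-file mode matches `gene_type` against the GENCODE long-non-coding
  biotype list, configurable). Version suffixes (`.N`) are stripped from all
  identifiers before any join, since annotation versions drift between
  releases.
* **Symbol ambiguity.** A symbol mapping to several genes is reported as
  ambiguous and never silently expanded; identifiers are matched before
  symbols.
* **Default thresholds.** Expression 0.001; association $p \le 0.01$;
  enrichment $\alpha = 0.05$ with BH. These are the tool's standard operating
  point for a typical bulk RNA-Seq dataset; all are flags/arguments.
* **Filtering on adjusted p.** When a correction is selected, the
  significance filter applies to the adjusted value — reporting a corrected
  column while filtering on the raw one would be misleading.
* **Dense matrices.** Expression input is dense TSV; at bulk RNA-Seq scale
  (tens of thousands of genes × tens to hundreds of samples) sparsity
  machinery buys nothing.
* **Normalisation is the caller's.** The reader accepts any non-negative
  table and deliberately does not renormalise; whether upstream values are
  FPKM, TPM or RSEM counts is a dataset-level decision left to configuration
  (the log2 transform is the only in-package adjustment, and only for
  regression).

# Known limitations

* Co-expression is correlation: no partial correlation, mutual information
  or network-module detection, and no causal claim — "target" in the
  synthetic ground truth means a planted correlate.
* Spearman p-values for $n < 10$ are approximate (see above).
* GMT collections are taken as-is: no GO ancestor propagation; if the input
  GMT is not propagated, enrichment is with respect to direct annotations
  only.
* Cross-dataset integration is set algebra (union/intersection) by design;
  no significance-aware meta-analysis such as Fisher's method is provided.
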