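---
title: "From genome sequences to functional guilds: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genome sequences to functional guilds: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitguilds)
```

# The problem

Genome sequencing gives microbial ecology a continuous stream of
isolate genomes, MAGs and SAGs. Taxon-centric summaries of such data
scale poorly and hide physiology; the alternative is to describe each
genome by a vector of *traits* — measurable, genome-derivable
characteristics that affect fitness — and to group genomes into
*functional guilds* by their trait profiles. This package implements
that pipeline end to end: profile-HMM gene detection, a Boolean rule
layer mapping gene content to traits, genome-size-normalised trait
matrices, genome-wide life-history predictors, and guild discovery by
mixed-type distances and distance-based variance partitioning.

# Gene detection and trusted cutoffs

Gene families are modelled as profile HMMs. ORF calling delegates to
Prodigal and profile search to HMMER/`hmmsearch`; both run behind thin
interfaces (`predict_orfs()`, `scan_proteins()`) so the rest of the
package only sees data frames. We threshold the **full-sequence bit
score**: it is the quantity the calibration benchmarks are expressed
in, and unlike E-values it does not depend on database size. E-values
are retained for reporting only. Domain-level thresholds are a
conceivable alternative; we flag that choice for sensitivity analysis
but do not implement it.

A hit is retained when its score is **greater than or equal to** the
model's trusted cutoff (consistent with choosing the *smallest* score
that maximises F, below). For one (protein, model) pair only the
best-scoring hit counts, and the count unit is **distinct proteins per
model** — traits are framed per enzyme or complex, so multiple domain
hits within one protein should not inflate counts. A protein may count
toward several models; family overlap is resolved downstream by the
rule layer, not by forcing a best-model assignment.

## Calibration

Each model's trusted cutoff is selected on a labelled score set:
positives are sequences known to belong to the family, negatives known
not to. For every observed score `t` (F is piecewise constant between
observed scores, so a grid adds nothing):

* `TP = #positives ≥ t`, `FP = #reported negatives ≥ t`,
  `FN = #positives < t`, `TN = n_negatives_total − FP`;
* precision `P = TP/(TP+FP)` (undefined when `TP+FP = 0`; such
  thresholds are excluded from the argmax to avoid vacuous maxima),
  recall `R = TP/#positives`, `F = 2PR/(P+R)`,
  `FPR = FP/n_negatives_total`.

Search engines only report scores above a floor, so negatives without
a reported score are counted as below every threshold through
`n_negatives_total`. The cutoff is the **smallest** `t` attaining the
maximal F. Exact rational ties in F can differ by one ulp depending on
the evaluation route, so thresholds within `1e-9` of the maximum are
treated as tied and the smallest wins; genuine F differences on
realistic benchmark sizes are orders of magnitude larger. Models whose
best F is undefined or zero are reported *uncalibratable* rather than
given an arbitrary cutoff.

# The rule language

Each gene family is a Boolean variable (detected/not detected). Rules
are named expressions over variables and other rules with `&` (AND),
`|` (OR), `!` (NOT) and parentheses; `!` binds tightest, then `&`,
then `|`. The tokens and precedence follow C/R convention for
familiarity; the reference framework presents its logic graphically
without fixing a textual grammar, so this is a design choice. NOT is
included even though pathway diagrams only need AND/OR: exclusion-style
definitions (e.g. "reduces N2O but cannot produce it") require it.
Identifiers are case-sensitive because gene symbols can legitimately
differ only by case.

Parsing canonicalises associative operators (`(a | b) | c` and
`a | b | c` build the identical n-ary node), which makes
serialise-then-parse the identity on ASTs. Rulesets compile against a
manifest: every leaf must resolve to a rule or a manifest variable, the
rule-reference graph must be acyclic, and a stable topological order
(Kahn's algorithm, FIFO queue seeded in input order) fixes the
evaluation order deterministically. Gene families in the closure that
are missing from an input genome default to `FALSE` with a warning
rather than an error — provisional genomes (MAGs/SAGs) routinely lack
detections, and the rules are designed to tolerate that.

## Complex counts and substrate classes

Count traits quantify transporter/enzyme complexes per substrate
class. A complex needs all its subunits, so a definition like
`xylF & xylG & xylH` contributes `min` over the subunit counts.
Alternative forms of the same function (OR branches, e.g. the two
nitrate reductases `NarGHI | NapAB`) contribute the `max` across
forms, not the sum: the alternatives realise one function. The
aggregation is not specified by the reference framework; min/max is
our documented choice, flagged for sensitivity analysis. Standalone
annotated families count as one-subunit complexes (their raw count).

# Trait matrices

Binary trait = the bound rule's assertion. Count trait = complex count
divided by genome length in bp, stored **per bp** exactly
("per-base-pair genomic investment"); any per-Mbp display is
presentation only. Missing genome size is an error by default (a
`raw`-counts policy flag exists for proteome-only input, with a
warning). Traits sit at the leaves of a three-level hierarchy; parents
aggregate children by OR (binary) and sum (count), so presence
propagates upward and investments are conserved: a granularity-1 count
trait equals the sum of its granularity-3 descendants.

The packaged schema is deliberately small and representative — the
four-step denitrification pathway over its 12 canonical gene families
(NarGHI, NapAB, NirS, NirK, NorBC, NorVW, NosZ), a substrate-uptake
set with substrate-class annotations, and a stress-tolerance set —
plus ribosomal-protein models used by the life-history stage. The
trusted cutoffs in the packaged manifest are illustrative placeholders
meant to be replaced by `run_calibrate()` output for any real library.
End-product trait definitions (e.g. whether "to N2" requires the
nitrate step) are plain rules in the rules file, editable by the user,
because reconfigurability of trait definitions is a core requirement.

# Life-history traits

Two composite traits are predicted from genome-wide signals:

* **Minimum doubling time (hours).** Fast growers show strong
  synonymous codon bias in highly expressed genes. We use ribosomal
  protein genes (located via the manifest's ribosomal models, default
  pattern `^(rpl|rps|rpm)`) as the highly expressed set and quantify
  bias with MILC (Supek & Vlahovicek 2005): per gene,
  `MILC = Σ_a M_a/L − C` with
  `M_a = 2 Σ_c O_c ln(f_c/e_c)` against genome-wide background codon
  frequencies and `C = Σ_a (r_a − 1)/L − 0.5`. The background
  frequencies are used exactly (no pseudocounts), so a gene whose
  usage equals the background scores exactly `−C`; only a codon never
  seen in the background falls back to a half-count expectation.
  Fewer than 10 ribosomal genes (configurable) flags the estimate
  low-confidence.
* **Optimal growth temperature (°C).** A documented set of
  compositional features: genome G+C and nucleotide fractions, ORF
  nucleotide fractions and G+C, proteome amino-acid fractions, the
  IVYWREL fraction and the charged-residue (DEKR) fraction. Features
  derived from tRNA and rRNA genes are not computed — the package
  carries no detector for them — so model files are validated against
  the available features and predictors restricted accordingly.

Both predictions go through plain-text linear-model files
(`feature`/`weight` pairs, metadata header naming the response,
transform and units). The packaged model files are **synthetic
examples** (`synthetic_*.tsv`, so labelled in their headers): the
coefficients of published growth-rate and growth-temperature
regressions are external to this package and are treated as pluggable
inputs, versioned together with the bias statistic they expect.
Responses may be modelled on the log scale (`transform: log`), in
which case predictions are exponentiated.

# Guild discovery

## Distance

Trait matrices mix binary and numeric columns, so distances use
Wishart's mixed-type metric: for genomes *i*, *j* over *p* variables

$$d_{ij} = \sqrt{\frac{1}{p}\left[\sum_{\mathrm{numeric}\ k}
\frac{(x_{ik}-x_{jk})^2}{s_k^2} + \sum_{\mathrm{binary}\ k}
\mathbf{1}[x_{ik}\neq x_{jk}]\right]}$$

Like Gower's distance it averages per-variable contributions, but
numeric variables are weighted by their sample variance `s_k²` (not
their range) and enter squared. Consequences we rely on: per-column
affine rescaling of numeric traits cancels, and `d²` is a weighted
squared Euclidean distance (binary mismatches are squared Euclidean on
0/1), which underwrites the monotonicity of the variance curve below.
Zero-variance numeric columns have an undefined weight and are dropped
with a warning; an all-constant matrix yields the zero distance matrix
with a warning. Count traits enter as numeric variables already per-bp
normalised; binarising them is a display device, not analysis.

## Clustering, variance curve, guild definition

Genomes are clustered with complete linkage (`stats::hclust`), whose
merge heights are non-decreasing and whose agglomeration is
deterministic for a given input order. For every k from 1 to n the
tree is cut and the explained variance computed as in distance-based
(PERMANOVA-style) variance partitioning:

$$SS_{\mathrm{total}} = \tfrac{1}{n}\sum_{i<j} d_{ij}^2,\qquad
SS_{\mathrm{within}} = \sum_g \tfrac{1}{n_g}\sum_{i<j\in g} d_{ij}^2,\qquad
R^2(k) = 1 - \frac{SS_{\mathrm{within}}}{SS_{\mathrm{total}}}$$

`R²(1) = 0`, `R²(n) = 1`, and because `d²` is Euclidean-embeddable,
refining a nested cut can only decrease `SS_within`, so the curve is
non-decreasing. The test suite cross-checks these values against
`vegan::adonis2` as an independent implementation. Guilds are defined
either at a fixed k or at the smallest k whose `R²` reaches a target
fraction; where the user operates on this curve is a judgement about
complexity versus information loss, not something the package decides.
Guilds smaller than `min_size` are flagged but retained — filtering
happens after variance accounting, so the curve is unaffected by the
flagging policy.

Guild profiles report per-guild trait means ("trait positivity" for
binary traits), across-guild Kruskal–Wallis rank tests per trait with
Benjamini–Hochberg adjustment (the reference framework marks
significance without naming a test; a rank test is the natural choice
for mixed binary/skewed-count columns), and per-guild life-history
quantiles. Trait correlation structure uses Spearman's rank
correlation; constant traits yield flagged `NA`s.

# Synthetic data: what it emulates and what it does not

All tests run on generated data; nothing is downloaded.

* `make_score_set()` draws positive and negative bit scores from
  normal distributions (defaults: 50 + 50 scores, means 100 and 30
  bits, sd 5) — a clean stand-in for benchmark scans against labelled
  reference sequences. Real score distributions are heavier-tailed
  and asymmetric; what passing tests show is the correctness of the
  threshold arithmetic and selection rule, not benchmark realism.
* `make_planted_guild_matrix()` plants guild structure: 60 genomes in
  3 guilds, 20 binary + 5 count traits, genome sizes uniform on 2–6
  Mb. Every trait receives a high/low pattern that is non-constant
  across guilds (a constant trait carries no guild signal and only
  dilutes the planted structure); binary values are Bernoulli draws at
  `0.5 ± divergence/2` (default divergence 0.9) with a flip
  probability `noise` (default 0.05); count traits are Poisson with
  per-Mb rates (defaults 2 and 20 per Mb) scaled by the drawn genome
  size — the per-bp investment is the guild-conserved quantity, which
  is precisely why the pipeline normalises counts by genome size.
  Real trait matrices are sparser, correlated and phylogenetically
  structured; recovery results on this fixture demonstrate the
  clustering machinery, not performance on real compendia.
* `make_toy_genome()` back-translates planted proteins (ATG start,
  TAA stop, random synonymous codons) between random spacers. Two
  constructions keep gene callers honest rather than lucky: spacers
  are flanked by a motif with stop codons in every frame on both
  strands, and back-translation resamples codons until no shifted or
  reverse-strand frame contains a long stop-free stretch (default
  cap 150 bp, 50 attempts) — otherwise spurious ORFs can outscore and
  displace planted genes. Toy genomes have none of the codon-usage,
  GC-skew or operon structure real gene callers exploit.

All generators derive per-purpose sub-seeds from one Mersenne-Twister
seed by stable string hashing, so adding one fixture never perturbs
another and every output is reproducible from a single integer.

# Numerical and engineering choices

* Threshold candidates are the observed scores only; comparisons at
  the cutoff are `≥`; F ties resolve to the smaller threshold with a
  `1e-9` tolerance.
* Compilation, evaluation, extraction and clustering are deterministic
  given input order; extraction parallelises over genomes
  (`parallel::mclapply`) and collected hits are re-sorted, so outputs
  are byte-identical for any worker count. Run manifests record
  package and engine versions, the seed and the cutoff-table hash.
* ORF prediction uses Prodigal's metagenome mode below 100 kb (single
  mode needs enough sequence to train on) and caches per genome id
  and sequence fingerprint within a session.
* Trait matrices are written with a two-row header (trait, strategy)
  at full double precision; reading infers binary columns as those
  containing only 0/1.
* Problem sizes in the tests (5-genome extraction fixtures, 17-model
  toy HMM library, 60-genome guild fixtures, 10⁴ rule-engine oracle
  cases, ≥10³ calibration oracle cases) were chosen to exercise every
  code path at desk scale while keeping the default suite fast.

# Known limitations

* No genome-completeness correction: per-bp investments from
  incomplete MAGs are biased low; completeness-aware correction is
  future work.
* No fragment-mode (metagenome read) gene calling; inputs are genomes
  or proteomes.
* tRNA/rRNA-derived growth-temperature features are absent (no
  detector dependency); OGT models must restrict to compositional
  features.
* The packaged schema is a representative miniature, not a full trait
  hierarchy; users supply their own manifests, rules and hierarchies
  for production use, and the packaged life-history coefficients are
  synthetic placeholders.
* Complete linkage is sensitive to outlier genomes; with the planted
  fixture this is mitigated by trait-panel width, but on real data a
  user should inspect guild sizes and the R²(k) curve before fixing k.
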