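---
title: "Homoeolog triads: bookkeeping, expression bias and Ka/Ks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homoeolog triads: bookkeeping, expression bias and Ka/Ks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadlens)
```

## The setting

Hexaploid bread wheat carries three diploid subgenomes (A, B, D), so a gene
family surveyed genome-wide is really a family of *triads*: each gene
potentially owns one homoeolog per subgenome, on corresponding
(homoeologous) chromosomes. Three questions recur in every such survey, and
they are what this package computes:

1. **How intact are the triads?** Counting genes by subgenome composition
   (ABD, AB, AD, BD, A, B, D) summarises homoeolog retention and loss.
2. **Which triads sit on rearranged chromosomes?** Homoeologous chromosomes
   are largely collinear; members that violate collinearity usually mark one
   of a handful of well-characterised wheat rearrangements.
3. **Do the three copies contribute equally to expression, and does that
   change under stress?** Relative homoeolog abundance within a triad is a
   point on a 2-simplex; its position, category and movement between
   conditions describe subgenome dominance and suppression.

A fourth component, a Nei–Gojobori Ka/Ks estimator, serves the standard
follow-up question of what selective regime duplicated family members
evolve under.

## Rosters and triads

The roster is the package's primary input: one row per homoeolog with its
triad identifier (`gene_name`), subgenome, physical chromosome (`1A`–`7D`),
arm (S/L or unknown), 1-based inclusive coordinates and a phylogenetic group
label. Coordinates follow GFF convention and are used only for ordering;
no arithmetic is done on them. Triads are keyed by the explicit `gene_name`
column rather than by parsing homoeolog identifiers, because the naming
schemes used in family surveys are not algorithmically invertible.

One validation rule deserves comment. Ordinarily a homoeolog's chromosome
letter must equal its subgenome, and `read_roster()` treats disagreement as
a data-entry error. But genes captured by an inter-subgenome translocation
genuinely violate it: in wheat, a segment ancestrally from 7BS resides on
4AL, so a B-lineage homoeolog can legitimately sit on an A-subgenome
chromosome. `on_mismatch = "flag"` keeps such rows, marked `translocated`,
which is exactly the signal the rearrangement module interprets. The strict
default stays, because for an ordinary roster the mismatch is far more
likely a typo than a translocation.

## Rearrangement annotation

Within a triad with at least two members, the *collinear expectation* is the
majority vote over members' (chromosome number, arm). A member disagreeing
with the majority is a deviant; with exactly two members that disagree there
is no majority and the triad is flagged indeterminate rather than guessed.
Members with unknown arm participate in the chromosome-number vote only.

Deviants are then matched against a declarative rule table keyed one-to-one
by the deviant's (observed, expected) chromosome/arm pair. The packaged
default encodes the events known from the wheat literature: the 4A
pericentromeric inversion (4AL→4AS and 4AS→4AL), the 4AL/5AL reciprocal
translocation (both directions), the 7BS→4AL and 5AL→7BS legs of the
ancient cyclic translocation, 5BS→4BL, and a 6B arm swap. This rule-driven
design was chosen over de novo synteny-block computation deliberately: at
the scale of one gene family, deviations are interpreted against events the
cytogenetics literature has already established, and a declarative table
makes that interpretation explicit, auditable and extensible.

Two reporting choices matter downstream. The 6B arm swap is suggested by
synteny but not an established event, so its two rules carry the separate
class `putative_pericentromeric_inversion` and are tallied apart from the
established inversions. And a deviant matching no rule is *reported* with
class `unexplained_deviation`, never silently dropped — an unexplained
deviation is a finding, not an error. A deviant matching more than one rule
is an error, because the one-to-one keying of the rule table is the
package's answer to the genuinely open question of how to attribute a
location that several events could explain; a table that violates it needs
the user's attention, not a tie-break heuristic.

## Expression bias

### The simplex model

For a triad with condition-level TPM values $(t_A, t_B, t_D)$, the relative
abundances are $r_i = t_i / \sum_j t_j$, a point on the unit 2-simplex. The
package classifies each point by Euclidean nearest centroid among seven
canonical expression patterns:

| category | centroid |
|---|---|
| Balanced | (1/3, 1/3, 1/3) |
| A/B/D dominant | unit vector of the dominant subgenome |
| A/B/D suppressed | 0 at the suppressed subgenome, 1/2 at the other two |

Nearest-centroid assignment is the natural decision rule for this scheme:
the seven centroids are the idealised patterns, and the rule is symmetric
under subgenome permutation (a property the tests verify). Exact ties are
assigned Balanced — the conservative call, since a tie means the data do
not favour any biased pattern over the balanced one. A configurable variant
(`balanced_radius`) additionally forces any point within a chosen distance
of the balanced centroid to Balanced; it is off by default because the
default scheme needs no tuning parameter.

### Filters and conventions

- **Expression filter.** A triad whose summed TPM in a condition falls
  below `min_total_tpm` (default 0.5) is "not expressed" there: relative
  abundances on a near-zero denominator are noise. The threshold is a plain
  argument, since no principled universal value exists.
- **Missing versus zero.** An absent expression row or missing cell is *no
  data* and excludes the triad from analysis in that condition; an observed
  0.0 is *evidence of no expression* and keeps the triad (which may then be
  not-expressed). Compendium data genuinely conflate these — a blank can
  also mean expression only under untested conditions — so the package
  keeps the distinction explicit in its input format (`.`/empty = missing).
- **Replicates.** Samples of the same condition are averaged (mean by
  default, median selectable) before normalisation. Averaging TPM then
  normalising is used rather than normalising per sample and averaging
  simplex points, because the ratio of averaged expression is the natural
  estimate of a triad's condition-level composition.
- **Log transform.** Heatmap-style visualisation conventionally uses
  $\log_2(\mathrm{TPM} + 1)$; the +1 pseudo-count keeps zeros finite and
  maps 0 to 0. The transform never feeds the simplex computation, which
  works on raw TPM.

### Ternary coordinates and shifts

For plotting, the simplex maps to the unit-edge triangle by
$x = r_B + r_D/2$, $y = (\sqrt3/2)\,r_D$, with corners A = (0,0),
B = (1,0), D = (1/2, √3/2). The map is affine and invertible
(`ternary_to_simplex()`); round-trips are exact to machine precision.

Between two conditions, `shift_table()` cross-tabulates categories of the
triads expressed in both into a 7 × 7 transition matrix, alongside
per-subgenome dominance/suppression tallies per condition. Only
both-expressed triads enter the matrix, so its total equals the shared
triad count by construction.

## Nei–Gojobori Ka/Ks

The NG86 estimator is implemented from scratch (it is the analytical core,
not a wrapper), with the conventions most implementations share, stated
here explicitly because the method's brief descriptions often leave them
implicit:

- **Sites.** Each codon position contributes (synonymous single-nucleotide
  changes at that position)/3 synonymous sites; *changes producing stop
  codons count as nonsynonymous*. Thus $s + n = 3$ per codon exactly, and
  $S + N$ equals the compared length in nucleotides. $S$ and $N$ are
  averaged across the two sequences.
- **Differences.** Codon pairs differing at $k$ positions are scored by
  averaging over all $k!$ orderings of the single changes, *excluding
  pathways that pass through a stop codon*. If every pathway is blocked —
  impossible under the standard code between sense codons, but possible
  under injected codes — all pathways are used with equal weight and a
  warning is issued. When nothing is excluded, $s_d + n_d = k$.
- **Correction.** Both proportions $p_S = S_d/S$ and $p_N = N_d/N$ receive
  the Jukes–Cantor correction $d = -\tfrac34\ln(1 - \tfrac43 p)$.
  Proportions at or beyond 3/4 are saturated: the corrected distance is
  undefined and flagged, never clamped.
- **The ratio.** $K_a/K_s$ is reported as 0 when $K_a = 0$ with $K_s > 0$
  (strong purifying selection), and as undefined (`NA`, with the
  corresponding flag) when $K_s = 0$ or either side is saturated. An
  undefined ratio is not an error; group means simply exclude it and report
  how many pairs they used.
- **Alignment handling.** Codons containing gaps or ambiguity characters in
  either sequence are skipped pairwise, keeping $S + N$ consistent with the
  compared length. Internal stops are a validation error. Only the standard
  genetic code ships, but any 64-codon table can be injected. No
  codon-frequency or transition/transversion weighting is applied — those
  define NG's modified variants, not NG86.

For speed, per-codon site counts and the 61 × 61 pathway-averaged
difference matrices are precomputed once per genetic code and cached;
a 10,000-codon pair then costs a few lookups per codon. The test suite
checks the difference counting against an independent brute-force pathway
enumerator over all 61 × 61 sense-codon pairs, exactly.

## The synthetic-data generators

The generators define the statistical world in which the package is
validated; their defaults are fixed study conditions, not tuning knobs.

**Triad expression.** Each triad draws a category from `category_mix`
(default: 2/3 Balanced, the remainder spread evenly — matching the common
observation that roughly a third of triads show bias under normal
conditions), relative abundances from a Dirichlet distribution with
parameters `concentration × centroid` (default concentration 200, a tight
but not degenerate spread), and a total TPM from a log-normal (meanlog
log 10, sdlog 1 — moderately expressed genes spanning roughly two orders of
magnitude). Homoeolog TPM is the product. Because dominant and suppressed
centroids lie on the simplex boundary, a small ε = 10⁻³ is mixed into the
centroid before scaling so every Dirichlet parameter is positive.
`missing_rate` drops homoeolog rows independently, emulating compendium
blanks. A condition pair with known transition structure comes from
`simulate_stress_shift()`, which redraws each triad's category from the row
of a 7 × 7 stochastic matrix (the default mildly favours D- and B-dominance
gains under stress, the qualitative pattern reported for abiotic stress).

**Codon pairs.** A random sense-codon ancestor evolves into two descendant
copies: single-nucleotide changes are proposed uniformly, stop-creating
changes rejected, synonymous changes accepted with relative rate 1 and
nonsynonymous with rate ω, until a Poisson(t · n_codons) number of accepted
substitutions per lineage. Rejection of stops was chosen over renormalised
rate matrices as the simpler construction that is exact enough for an
oracle: its one systematic consequence is that nonsynonymous sites adjacent
to stop codons (about 4% of changes) can never substitute, so NG86
slightly underestimates ω — an effect of a few percent, well inside the
validation bands used (mean ratio within 10% of 1 under neutrality;
ω = 0.2 recovered within [0.15, 0.25]).

**What the generators do not emulate.** Replicate-level biological and
technical variance (conditions are generated as single samples),
correlation between conditions beyond the category transition, read-level
noise and mapping bias between near-identical homoeologs, real genome
coordinates, and codon-usage or transition/transversion structure in the
sequence simulator. Passing the recovery tests therefore demonstrates the
*estimators* are correct under their stated models, not that real wheat
compendia meet those models.

**Fixtures.** `make_fixtures()` writes three small TSVs: a 257-homoeolog
roster realising the published family-wide distribution pattern
(76/4/3/3/3/3/3 across ABD/AB/AD/BD/A/B/D; chromosome placements and
coordinates synthetic, only the pattern is meaningful), the 36 published
homoeolog placements on rearranged chromosomes (arms verbatim; coordinates
synthetic placeholders), and the default rule table. Output is
byte-identical for a given seed, and the packaged copies under `extdata/`
are exactly this output.

## Numerical choices

- Simplex membership is validated with tolerance 10⁻⁶ (inputs come from
  division and can carry rounding error); nearest-centroid ties use a
  10⁻¹² margin; ternary round-trips are exact to ~10⁻¹⁵.
- All randomness funnels through one seed argument per generator, applied
  with save/restore of the caller's RNG state, so library calls never
  perturb a user's stream and fixed seeds give bit-identical output.
- Validation problem sizes were chosen to make the statistical checks
  sharp but cheap: 400–1000 triads for category and transition recovery
  (at concentration 200 the binomial/3σ bounds are decisive), 10,000-codon
  alignments with 20 neutral replicates for ω recovery, and the full
  61 × 61 codon-pair grid for exact oracle agreement.

## Limitations

- Rearrangement detection is only as complete as the rule table; novel
  events surface as `unexplained_deviation` and need manual curation.
- The seven-category scheme is a hard partition of the simplex; triads near
  category boundaries flip under resampling noise. The ternary coordinates
  are provided precisely so users can see boundary proximity rather than
  trust labels alone.
- NG86 is a counting method: it ignores codon frequencies and
  transition/transversion bias, and saturates quickly (p ≥ 3/4
  uncorrectable). For deep divergences a likelihood codon model is the
  right tool; this package targets the shallow within-family comparisons
  where NG86 is standard.
- The bias pipeline assumes TPM is comparable across the three homoeologs;
  mapping ambiguity between near-identical copies violates this in ways no
  downstream statistic can repair.
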