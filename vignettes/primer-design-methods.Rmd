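---
title: "Primer design with primerkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primer design with primerkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerkit)
```

primerkit is a toolkit of composable primer-analysis operations rather than
a single designer: annealing temperature, rule-based dimer/hairpin scoring,
exhaustive binding-site and product search, candidate enumeration,
prioritised and multi-objective ranking, and a microsatellite
flanking-primer pipeline. This vignette documents the models behind each
step, the parameters that matter (with units and defaults), the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Coordinates and the sequence model

All coordinates are 1-based, closed intervals, the R/Bioconductor
convention (a binding site `start = 101, end = 120` covers bases 101..120;
`product_length = reverse_end − forward_start + 1`). The alphabet is
restricted to A, C, G, T, N; other IUPAC ambiguity codes are rejected at
validation so that the exhaustive matcher's semantics stay unambiguous. Ns
are treated conservatively everywhere: they never match in binding-site
search, never pair in dimer scoring, count only in the denominator of GC
content, and make Wallace/nearest-neighbor temperatures undefined (an
error) rather than silently wrong.

## Annealing temperature

Four methods sit behind one registry (`tm_methods()`,
`melting_temperature()`), so callers can switch methods without code
changes and new ones can be added with `register_tm_method()`:

* **wallace** — `2(A+T) + 4(G+C)` in degrees C; a rough rule for short
  oligos, kept because it is cheap and monotone in GC content.
* **breslauer_nn**, **santalucia_nn**, **freier_nn** — nearest-neighbor
  thermodynamics: ΔH and ΔS summed over adjacent dinucleotide stacks from
  the named published table plus that table's initiation terms
  (Breslauer 1986: ΔS −16.8 cal/K/mol with any G·C pair, −20.1 otherwise;
  SantaLucia 1998 unified: per-terminal A·T +2.3 kcal/+4.1 eu and
  G·C +0.1/−2.8; Freier 1986: ΔS −10.8), then

  `Tm = ΔH / (ΔS + R ln(C_T/x)) − 273.15 + 16.6 log10[Na+]`

  with R = 1.987 cal/(K·mol), total oligo concentration `C_T` = 5e-8 M and
  monovalent salt 0.05 M by default. The symmetry factor x is 4, or 1 plus
  the table's symmetry entropy term (−1.3/−1.4 eu) for self-complementary
  oligos.

Design choices worth stating: the default method is the
SantaLucia-parameterised calculation (the convention of the widely used
oligoTm-style code). The Freier 1986 parameters are an RNA nearest-neighbor
set; they are included, applied to the DNA letters with T read as U, as an
approximate method in the long-primer regime where all NN extrapolations
degrade — it is a method choice exposed to the user, not a claim of DNA
accuracy. Only the monovalent `16.6·log10[Na+]` salt correction is
implemented; divalent corrections are out of scope. Because Tm estimates
are least reliable for long primers, the pairing layer also scores
*similarity* characteristics (length and GC differences) so that pairs can
be matched even when their absolute Tm is uncertain.

## Hairpin and dimer scoring

The rule-based score examines a window of `tail_length` bases (default 12)
at the primer's 3′ end — the end that matters for extension — and slides it
ungapped and antiparallel against the partner sequence at every offset
(partial overlaps included), summing `weight_gc` = 2 per G·C complement and
`weight_at` = 1 per A·T. The maximum over offsets is reported, capped at
`max_score` (default `2·tail_length`). `pair_dimer_score()` evaluates both
tails (a's tail against b and b's against a) and reports the larger;
`hairpin_score()` folds the tail back onto the primer's own 5′ portion,
counting only folds that leave at least `hairpin_min_loop` (default 3)
unpaired loop bases; sequences too short to fold return score 0 with status
`"too short"` instead of an error.

Numeric defaults (weights, the 12-base tail, the cap, and the rejection
threshold `0.55·max_score`) are package choices: the G/C > A/T weighting
follows the three-hydrogen-bond intuition behind rule-based scorers of this
family, and every value is user-configurable. Ungapped alignment only —
thermodynamic (ΔG-based) secondary-structure evaluation is a different
method class and deliberately out of scope. One property that deserves a
warning: a *windowed* score is not invariant under jointly
reverse-complementing both inputs (that swaps which end is the 3′ end);
invariance holds when the window covers the whole primer, and the tests
check exactly that configuration.

## Binding sites and products

`find_binding_sites()` is an exhaustive scan: every offset, both strands,
no seeding heuristic or index. A site must have at most `max_mismatches`
substitutions over the full primer (default `floor(length/5)`) *and* an
exactly matching block of `three_prime_exact` bases (default 5) at the 3′
end, since 3′ mismatches are what block extension; `three_prime_exact = 0`
gives a pure Hamming criterion (used to compare against a naive oracle in
the tests). Minus-strand sites are reported in plus-strand coordinates;
there the primer's 3′ end lies at the site's low-coordinate side. The
guarantee — every site satisfying the parameters is found — is the point:
seeded alignment heuristics can miss short sites with evenly spaced
mismatches, precisely the mis-priming candidates one wants to know about.
The cost is O(primer × template), implemented as vectorised per-position
comparison; at genome scales users would run the same interface against a
chunked template.

`search_for_pcr_products()` takes all plus-strand sites of the forward
primer and minus-strand sites of the reverse primer and emits one product
per convergent pair with `0 < length ≤ max_product_length` (default 3500
bases — an extension-time budget at roughly 1000 bases/min). The intended
amplicon always appears as one of the products, so *more than one* product
is the secondary-product signal (`attr(,"secondary_products")`).
Forward×forward and reverse×reverse convergent pairs are off by default
(`include_same_primer`), since whether to count same-primer products is
application-dependent.

## Candidates, pairing, selection

`generate_candidates()` enumerates *every* substring of the window with
length in `[length_min, length_max]` (windows in practice are ≤ ~1000
bases, so exhaustive enumeration is tractable and deterministic), then
applies hard filters: N-free (default), no-C or no-G for special designs,
excluded motifs, GC bounds. Chimeric primers built with
`chimeric_primer()` (up to 120 bases) flow through the same evaluation
code paths as short candidates — there is no separate long-primer scorer.

Selection normalises each characteristic to a penalty where 0 is ideal
(|Tm − preferred|, |GC − preferred|, raw dimer scores,
`max(0, binding_count − 1)`, `max(0, products_count − 1)`,
|length − optimum|; pair frames combine forward/reverse by mean for
deviations and max for dimer-type scores). Two mechanisms:

* **Prioritised stable sort** — characteristics are applied from lowest to
  highest priority, each pass moving over-threshold candidates to the
  bottom (marked rejected) and stable-sorting survivors by penalty, so the
  priority-1 key dominates while earlier keys break ties. If a threshold
  would reject *every* remaining candidate and `keep_suboptimal` is set
  (default), the violators are retained, flagged `suboptimal`, and still
  ordered — the reports carry an explicit SUB-OPTIMAL banner in that case.
* **Multi-objective score** — `F = Σ wᵢ · g(xᵢ)`,
  `g(x) = 1/(1 + exp(−k(x − o)))`, minimised. The sigmoid's gain `k`
  (default 1.0) sets how sharply it discriminates; the offset `o` (default
  0) should sit near the midpoint of the penalty distribution so scores
  fall in the steep region. The combined mode applies thresholded
  prioritised sorting first and refines the survivors by F as the last
  step, which is where a scalarised score is most informative.

The sign convention (penalties, minimise F) and the per-characteristic
normalisations are package decisions, documented here because different
tools state the same objective with opposite signs. This is a weighted
scalarisation, not Pareto-front enumeration.

## The SSR pipeline

`find_microsatellites()` scans every start and unit length (2–4 by
default), seeds on one exact unit repetition, and extends comparing each
base to the base one unit upstream: +1 per match, −6 per mismatch, keeping
the extension endpoint with the maximal cumulative score. Strict mode
(reporting) requires a span of at least 21 bases and score ≥ 15; relaxed
mode (the contamination screen used inside primer design) requires 12
bases and score ≥ 8. The score thresholds are package choices in the
spirit of classic repeat scanners, and configurable. Units that are
themselves periodic (e.g. ATAT) are skipped so each repeat is reported
once, under its shortest unit; overlaps resolve deterministically left to
right (ties: higher score, then shorter unit). Two quirks of the
"one unit upstream" rule worth knowing: pure homopolymer runs are never
reported (their 2–4-base units are all periodic), and a repeat adjacent to
a homopolymer run can extend into it, since a poly-T tract trivially
satisfies `s[j] == s[j−u]`.

`design_flanking_primers()` enforces the marker-design constraint set:
primer length 20–30; product 80–300 bases spanning the repeat; product
N-free; forward/reverse GC within 0.1 of each other and each Tm within
5 °C of the preferred value (default 60 °C — an application parameter, not
a universal constant); no two tandem copies of the repeat unit (in either
orientation) inside a primer — literal single-copy exclusion would forbid
nearly every primer for a 2-base unit; no relaxed-mode microsatellite in a
primer or in the flank between a primer and the repeat (the recursive
finder call); and exactly one within-read binding site per primer under
the default match parameters. Tm is computed first (it is cheap), the best
`shortlist` candidates per side (default 25) go through the expensive
screens, and the surviving pairs are ranked by the selection layer
(pair-dimer first, then Tm deviation, GC difference, self-dimer, with a
final multi-objective pass). Returning nothing is a legitimate outcome —
for example, when an N run leaves no 80-base N-free product window, or
when a flank is itself a repeat.

## Synthetic data: what a green test establishes

`make_template()` draws a uniform-random background from a seed and plants
primer-binding sites — verbatim, or with a requested number of clustered or
evenly spaced substitutions, on either strand — then *re-draws* the
background (never masks it) if an accidental site at the verification
budget would make the manifest inexact. `make_ssr_read()` builds a
500-base read (a typical long-read length) with a centred repeat and clean
or deliberately contaminated flanks (N runs, a repeat-bearing flank),
re-drawing until the strict finder reports exactly the planted repeat.
Fixtures therefore carry exact ground truth, which is what lets the test
suite assert *set equality* against naive oracles rather than statistical
agreement.

What the generators do not emulate: real base-composition structure (GC
skew, isochores), naturally occurring repeat families beyond those
planted, sequencing-error profiles, and genome-scale background size. A
green suite establishes algorithmic correctness (completeness of the
matcher, exactness of the scores, soundness of the filters and sorting) on
the stated synthetic world — not wet-lab performance of any particular
primer, and not throughput at genome scale.

## Numerical and degenerate-input choices

* Stable ordering is made explicit (`order(key, seq_along(key))`), so ties
  preserve input order by construction rather than by sort-algorithm
  accident.
* The sigmoid saturates numerically at extreme penalties (`exp` overflow
  maps to 0/1); no clamping is needed.
* Empty results are values, not errors: zero binding sites, zero products,
  zero candidate pairs and an undesignable repeat all return empty frames
  or NULL with enough status to report cleanly.
* A primer longer than its template yields an empty site frame with a
  status attribute; a hairpin on a too-short sequence yields score 0 with
  status `"too short"`.
* Reports round floating-point columns to 4 decimals at the formatting
  layer only; every number in a report is recomputable from the library
  API, and CSV output is byte-identical across reruns of the same inputs.
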