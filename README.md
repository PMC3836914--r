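# primerkit

An R toolkit for PCR primer design and in-silico evaluation, built for the
awkward cases that single-purpose design programs handle poorly: long and
chimeric primers (up to 120 bases), exhaustive — rather than heuristic —
secondary-binding and secondary-product detection, constraint-heavy batch
designs, and microsatellite (SSR) marker panels. It is aimed at people
building bespoke design pipelines (genome engineering, marker development,
high-throughput confirmation PCR) who need the individual analysis steps as
composable functions rather than one monolithic designer.

## What it computes

**Annealing temperature.** Four interchangeable methods behind one
interface: the Wallace rule, `Tm = 2(A+T) + 4(G+C)`, and three
nearest-neighbor parameterisations (Breslauer 1986; the SantaLucia 1998
unified table, the default; Freier 1986) under

```
Tm = ΔH / (ΔS + R ln(C_T / x)) − 273.15 + 16.6 log10[Na+]
```

with ΔH, ΔS summed over dinucleotide stacks plus each table's initiation
terms, x = 4 (1 for self-complementary duplexes). New methods can be added
with `register_tm_method()` without touching existing ones.

**Hairpin / self-dimer / pair-dimer potential.** A rule-based score over a
user-definable window at the primer's 3′ end: the tail is slid, ungapped and
antiparallel, against the partner (or the primer's own 5′ portion across a
minimum loop), scoring 2 per G·C and 1 per A·T complement by default,
capped at `max_score`. Because only the 3′ tail is scored, the same rule
works for 10-mers and 100-mers alike.

**Binding sites and products.** `find_binding_sites()` scans every offset
on both strands (no seeding heuristic), with a mismatch budget over the
full primer and an exactly matching 3′-terminal block — so every site
meeting the parameters is found, including sites with evenly spaced
mismatches that alignment heuristics miss. `search_for_pcr_products()`
pairs every convergent forward/reverse site within a window (default 3500
bases, a typical polymerase extension budget); more than one product
signals potential secondary amplification.

**Candidates and selection.** Exhaustive candidate enumeration in a window
with hard sequence filters (no-N, no-C/no-G designs, excluded motifs, GC
bounds), Cartesian pairing under product-size bounds, and two ranking
mechanisms: a stable iterative prioritised sort with per-characteristic
rejection thresholds (and a "best available sub-optimal" fallback), and a
weighted multi-objective score `F = Σ wᵢ · g(xᵢ)` with the sigmoid
`g(x) = 1 / (1 + exp(−k (x − o)))` applied to normalised penalties
(gain k defaults to 1.0).

**SSR pipeline.** A built-in tandem-repeat finder (match +1 / mismatch −6
extension against the base one unit upstream; strict mode: units of 2–4
bases spanning ≥ 21 bases) plus flanking-primer design under the full
marker-design constraint set: primer length 20–30, product 80–300 bases,
N-free products, matched GC, Tm near a preferred value, no repeat unit or
other microsatellite in primers or flanks (checked recursively with a
relaxed finder), unique within-read binding.

## Worked example

```r
library(primerkit)

tm_wallace("ACGTACGTACGTACGTACGT")          # 60
tm_nearest_neighbor("ACGTACGTACGTACGTACGT") # 46.92025 (SantaLucia, 50 nM, 50 mM Na+)

self_dimer_score("GGGGGGCCCC", dimer_params(tail_length = 4))
# score 8: the CCCC tail pairs all four bases with the internal GGGG run

fx <- make_template(6000, seed = 7)              # seeded synthetic template
fa <- tempfile(fileext = ".fa"); write_fasta(fx$sequence, fa)
run_design(c("--template", fa, "--target", "2500:2700",
             "--format", "text", "--pairs", "3"))
```

prints (abridged to the leading columns):

```
 rank           forward_bases forward_start forward_tm forward_binding_count           reverse_bases product_length pair_dimer products_count score_f
    1 TAGCGGTCCAGGGACCAGCCGCT          2379    59.9135                     1 GGCGGTCAACAGGGATCCGCCCG            347         11              1  3.6059
    2 TGCGCACCGCCGTTTACCTCGGG          2415    59.6212                     1 GGCGGTCAACAGGGATCCGCCCG            311         13              1  3.6418
    3 GCGGTCCAGGGACCAGCCGCTTT          2381    59.5470                     1 GGCGGTCAACAGGGATCCGCCCG            345         11              1  3.6507
```

Each row is a ranked pair flanking the target region: both primers bind the
template exactly once (`*_binding_count`), the pair forms exactly one
potential product (`products_count`, the target amplicon itself), the
pair-dimer score is under the rejection threshold (13.2 by default), and
`score_f` is the final multi-objective refinement (lower is better). The
same table is available as CSV or a standalone HTML page, and the `bind`,
`products` and `ssr` subcommands of `exec/primertool` expose the lower-level
searches and the SSR pipeline from a shell.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computations from scratch on seeded synthetic
inputs — a full command-line design on a 10 kb template and a strict-mode
microsatellite detection plus flanking-primer design on a 500-base read —
and writes the results JSON to `--out`.
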