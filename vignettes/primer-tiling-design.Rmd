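---
title: "Designing conserved overlapping primer tilings for circular genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing conserved overlapping primer tilings for circular genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmprimer)
```

## The problem

Sequencing a complete circular genome — a mitochondrial genome, a plastid, a
small bacterial chromosome — by Sanger chemistry requires amplifying it as a
series of PCR products and reading each from both ends. Two constraints make
this harder than routine primer design:

* the first 30–40 nt of a Sanger read are unreliable, so consecutive
  amplicons must *overlap* enough that every position is covered by the
  trustworthy interior of at least one read (primer walking);
* when the same primer set should work across several closely related
  species, every primer must sit in sequence that is *conserved* across a
  multiple sequence alignment of those species.

`swarmprimer` takes a pre-computed alignment (ClustalW, MAFFT, …; computing
the alignment is deliberately out of scope), extracts the conserved regions,
and walks the circle designing one primer pair per amplicon so that the
amplicons tile the whole molecule with controlled mutual overlap.

## Candidate encoding and the per-amplicon search

Within one design window a candidate primer pair is encoded as the integer
vector `{Fs, Fl, Rl, Pl}`: forward-primer start, forward length, reverse
length, product length. The forward primer is the template slice
`Fs … Fs+Fl−1`, the amplicon is `Fs … Fs+Pl−1`, and the reverse primer is the
reverse complement of the amplicon's last `Rl` bases. All coordinates are
1-based and inclusive on the ungapped reference record of the alignment; on
a circular template they wrap modulo the genome length, so an amplicon may
span the origin.

```{r}
tpl <- template_sequence("ACTTAGCGAATG", circular = FALSE)
decode_particle(c(2, 3, 4, 10), tpl)
```

Each window is searched with particle swarm optimization: a population of 20
candidates carries a 4-dimensional velocity, updated for 50 iterations by the
canonical rule `v' = w·v + c1·r1·(pbest − x) + c2·r2·(gbest − x)` with
inertia `w = 0.8`, `c1 = c2 = 2`, and per-dimension velocity clamping to
`[−6, 6]`. Positions remain continuous and are rounded to integers (and
clipped into their legal ranges) only at decode time; termination is by
iteration count alone. `r1`/`r2` are drawn per dimension per update (a
configuration switch restores the scalar-per-update variant). Runs are fully
deterministic given the R random seed.

Initial forward starts are drawn from the window *intersected with the
conserved regions* — that intersection is the definition of the sliding
window — while lengths and product length are uniform over their admissible
ranges and velocities are uniform in `[0, 1]`.

## The fitness function

A candidate pair is scored by a weighted sum of nonnegative penalty terms;
zero fitness means every constraint is satisfied. Defaults:

| term | default rule | form |
|---|---|---|
| `tm_range` | Tm of each primer in \[54, 65\] °C | count (0–2) |
| `tm_diff` | within-pair ΔTm ≤ 3 °C | indicator |
| `length_range` | lengths in \[18, 28\] nt | count (0–2) |
| `length_diff` | within-pair Δlen ≤ 3 nt | indicator |
| `gc_range` | GC% in \[40, 60\] | count (0–2) |
| `product_len` | product in \[800, 1100\] nt | distance to nearest bound |
| `hairpin` | no stem ≥ 4 bp with loop ≥ 3 nt | count (0–2) |
| `dimer` | ≤ 5 contiguous pairings at any antiparallel offset (self ×2 + cross) | count (0–3) |
| `specificity` | binding site unique on both strands of the circle | extra-occurrence count |
| `gc_clamp` | 3′-terminal base is G or C | count (0–2) |
| `endmatch` | 3′-terminal 3-mers of the pair not mutually complementary | indicator |
| `terminus_gc` | ≤ 3 G/C among the 5 terminal bases, both ends | count (0–4) |
| `conserved` | primer bases inside conserved regions | non-conserved base count |

The GC window is a *soft* term on purpose: published conserved primer sets
contain occasional primers outside it (one of the reference primers has
GC 34.6%), and treating it as a hard filter would discard workable designs in
AT-rich conserved stretches. The `product_len` and `conserved` terms are
graded (distance/count) rather than 0/1 so the swarm has a slope to descend:
with indicator penalties a window containing a single admissible conserved
start becomes a needle in a flat landscape that no gradient-following search
can find reliably.

Weights default to 1 for the comfort terms, 10 for the safety-critical terms
(`hairpin`, `dimer`, `specificity`, `endmatch`) and 50 for `conserved`, so
the swarm can never profitably trade conserved placement against anything
else. The exact penalty arithmetic behind the published method is not
recoverable from its description, so every term is reported separately
(`pen_*` columns) and the aggregation is auditable:
`fitness == Σ weight_i · term_i` is an invariant checked in the tests.

The dimer rule reads "more than 5 base pairings" as the longest *contiguous*
complementary run over all ungapped antiparallel offsets (a `total`-pairings
mode is a switch); the hairpin rule takes stem ≥ 4 bp as inclusive and
imposes the physical minimum loop of 3 nt; specificity is exact string
matching of the primer and its reverse complement against the circularized
template (no mismatch tolerance).

## Melting temperature

Tm is computed from nearest-neighbor thermodynamics:

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C/4)} - 273.15
        + 16.6 \log_{10}[K^+]_{eq}$$

with ΔH/ΔS accumulated from dinucleotide stacking terms plus duplex
initiation terms, `R = 1.987` cal/(°C·mol), `C` the oligonucleotide
concentration and `[K+]eq = monovalent + 120·√Mg²⁺` (mM), the
von-Ahsen-style monovalent equivalent used by NetPrimer-class calculators.

Two parameter sets ship with the package. The default is the SantaLucia 1998
unified DNA table at `C = 250` nM, which reproduces the reference primer
set's reported Tm column with a mean absolute deviation of about 1.5 °C;
Breslauer 1986 is selectable (`thermo_params(table = "breslauer1986")`) but
runs several degrees hot for these primers under the same salt model.
Calculator manuals in this tradition quote the concentration default as
"250 pM"; at picomolar concentrations no nearest-neighbor table yields
PCR-plausible Tm values, so the package treats the figure as the
conventional nanomolar-scale annealing concentration. Both tables are
reverse-complement symmetric, making `Tm(s) == Tm(revcomp(s))` exact — a
property the tests verify. Tm and GC% are carried in full precision and
rounded only by the output writers.

## Walking the circle

The first window opens at the first base of the first conserved region. After
a pair is accepted, the next forward primer is sought in the interval
`[prev_end − 200 + 1, prev_end − 90 + 1]` — positions from which the new
amplicon overlaps the previous one by 90–200 nt — intersected with the
conserved regions. If the window admits no conserved start, or the swarm
(after 5 fresh restarts) finds no acceptable pair, the admissible overlap is
extended by 50 nt steps up to a 500 nt cap, widening the window upstream;
the junction is then flagged `extended`. A pair is *accepted* when its
`conserved`, `product_len`, `specificity`, `dimer`, `hairpin` and `endmatch`
terms are all zero; the remaining comfort terms are minimized best-effort
and reported per pair. Requiring strict zeros on the comfort terms as well
would stall the walk in AT-rich conserved stretches for no experimental
benefit.

The walk terminates by circular closure: once the running amplicon chain
wraps past the first pair's forward start by at least the minimum overlap,
the final junction against pair 1 is validated with the same modular
arithmetic (`overlap = rev_start + rev_len − fwd_start (mod L)`) as every
other junction. The closing overlap is a remainder rather than a designed
quantity; when it exceeds 200 nt the closing junction is flagged `extended`
too. If a junction cannot be designed even at the overlap cap, a *partial*
tiling is returned with per-junction diagnostics instead of an error —
a design run that almost closed is far more useful than an exception.

Exact interval arithmetic over the circle (coverage, overlaps, the
product-length identity `Pl = rev_start + rev_len − fwd_start (mod L)`) is
re-checked from coordinates in the test suite.

## What the synthetic generator emulates

`simulate_family()` draws an ancestral circular sequence and mutates each
descendant independently, substitutions only, at per-block scaled rates.
Substitution-only evolution keeps the family exactly pre-aligned, which
gives conserved-region extraction a closed-form oracle and keeps fixtures
generable in code. The default block profile imitates a vertebrate
mitogenome: ~6% of the genome as rRNA-like blocks at 0.2× the background
rate, thirteen coding-like blocks at 1×, and a ~7% control-region-like block
at 3×. The 3× figure reflects the relative D-loop rate typical between
congeneric fish and, importantly, keeps conserved anchors at few-hundred-nt
spacing inside the control region — the regime in which published conserved
primer sets bridge the D-loop with junction extensions of a few hundred nt.
Rates are rescaled so `divergence` is the genome-wide expected substitution
rate per site per descendant; two descendants then differ at a site with
probability `2d(1−d) + (2/3)d²`, a closed form the tests check against
simulation.

What the generator does *not* emulate: insertions/deletions (real alignments
have gap columns; the extraction code handles them, the generator never
produces them), tandem repeats and heteroplasmy in the control region,
compositional strand asymmetry, and phylogenetic structure beyond
star-shaped independent descent. Passing tests on synthetic families
therefore demonstrate the algorithm's bookkeeping and search behaviour, not
performance on the full messiness of real mitogenomes.

## Numerical and design choices

* **Boundary handling**: positions are clipped (not reflected) into their
  ranges after each move; the published description gives no boundary rule
  and clipping keeps the update pure.
* **Tie-breaking**: the first candidate attaining the best fitness is kept,
  making runs reproducible bit-for-bit under a seed.
* **Velocity bounds**: the clamp is symmetric, `[−Vmax, Vmax]` with
  `Vmax = 6`.
* **Infeasibility** is a typed condition (`swarmprimer_infeasible`), consumed
  by the tiler's extension rule rather than crashing the walk.
* **Degenerate inputs**: N columns and gap columns are never conserved;
  single-record alignments are legal (the whole sequence is one conserved
  region); empty region lists are a legal result for `conserved_regions()`
  but an error for `tile_genome()`.
* **Problem sizes in the tests**: the exhaustive-oracle experiment uses a
  7×11×11×11 = 9317-candidate window on a 400 nt conserved template — small
  enough to enumerate, large enough that the swarm's 1000 evaluations cannot
  brute-force it by accident; end-to-end tilings use 16.5 kb families at
  divergence 0 and 2%, and the smaller unit-test tilings use 3–4 kb
  templates.

## Known limitations

* Secondary-structure checks are rule-based (pairing counts), not
  thermodynamic ΔG folding; borderline hairpins/dimers near the thresholds
  may be misclassified relative to a full folding model.
* No degenerate-base (IUPAC) consensus primers: a column must be identical
  across species to be usable.
* The walk is greedy with local extension only — it never backtracks to
  redesign an earlier pair, mirroring the published pseudo-code. A genuinely
  unbridgeable window therefore yields a partial tiling.
* Tm values depend on the chosen nearest-neighbor table; reported values
  from other software are approximated to within a degree or two, not
  reproduced bit-exactly.
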