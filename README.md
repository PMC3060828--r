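# swarmprimer

Design a complete set of mutually overlapping PCR primer pairs that tiles an
entire **circular genome** — typically a mitochondrial genome — using only
sequence that is **conserved across a multiple sequence alignment** of
closely related species.

The package is for researchers who need to amplify and Sanger-sequence whole
mitogenomes (or plastids, or small circular chromosomes) of species without
a reference, by borrowing conservation from sequenced relatives: one common
primer set, amplicons of 800–1100 nt, each overlapping its neighbours by
90–200 nt so the unreliable first 30–40 nt of every read are covered by the
trustworthy interior of the previous amplicon (primer walking).

## Method

A candidate primer pair inside one design window is encoded as the particle
`{Fs, Fl, Rl, Pl}` (forward start, forward length, reverse length, product
length): the forward primer is template `Fs…Fs+Fl−1`, the amplicon is
`Fs…Fs+Pl−1`, and the reverse primer is the reverse complement of the
amplicon's last `Rl` bases. Each window is searched by particle swarm
optimization (population 20, 50 iterations, inertia 0.8, c₁ = c₂ = 2,
velocities clamped to ±6), minimizing a weighted sum of penalty terms:

* melting temperature in [54, 65] °C (nearest-neighbor ΔH/ΔS with
  `Tm = 1000·ΔH / (ΔS + R·ln(C/4)) − 273.15 + 16.6·log₁₀[K⁺]eq`),
  within-pair ΔTm ≤ 3 °C;
* primer lengths in [18, 28] nt, within-pair Δlen ≤ 3 nt; GC in [40, 60] %;
* product length in [800, 1100] nt (graded outside the window);
* no hairpins (stem ≥ 4 bp, loop ≥ 3 nt), no self/cross dimers (> 5
  contiguous pairings), unique binding site on both strands of the circle,
  3′ GC clamp, no 3′-end complementarity between the pair, ≤ 3 G/C in the
  5 terminal bases;
* all primer bases inside conserved alignment regions.

A sliding window walks the circle: the next forward primer is sought 90–200
nt upstream of the previous amplicon's end, intersected with the conserved
regions; when no acceptable pair exists there the admissible overlap is
extended in 50 nt steps (to a 500 nt cap) and the junction is flagged. The
walk closes the circle by validating the final junction against pair 1 with
the same modular arithmetic, `overlap = rev_start + rev_len − fwd_start
(mod L)`.

See `vignettes/primer-tiling-design.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

Simulate a pair of closely related 16.5 kb circular mitogenome-like
sequences (2 % divergence, mitogenome-like rate blocks), extract conserved
regions, and tile the genome:

```r
library(swarmprimer)

fam     <- simulate_family(sim_spec(genome_len = 16500, divergence = 0.02, seed = 42))
regions <- conserved_regions(fam$alignment, ref_id = "sim_01")
nrow(regions)        # 295 conserved regions, 13129 nt in total
tiling  <- tile_genome(fam$templates[[1]], regions, seed = 7)
tiling
#> <primer_tiling> 20 pairs on 16500 nt circular template (complete)
#>   junction overlaps: 91-259 nt, 1 extended
glance(tiling)
#> # A tibble: 1 × 8
#>   n_pairs coverage min_overlap max_overlap n_extended min_product max_product
#>     <int>    <dbl>       <int>       <int>      <int>       <int>       <int>
#> 1      20        1          91         259          1         842        1073
```

Every template position is covered, all 20 products lie in 800–1100 nt, and
one junction needed an automatic overlap extension (259 nt) to bridge the
hypervariable control-region block. `tidy(tiling)` returns the primer table
as a tibble — the first designed pair:

```r
tidy(tiling)[1, c("set", "fwd_seq", "fwd_start", "product_len", "tm_f", "tm_r")]
#>     set fwd_seq                  fwd_start product_len  tm_f  tm_r
#> 1     1 GAACGTACAACTGAGATAGTCACC        15         886  58.4  60.6
```

`write_primer_table()`, `write_tiling_bed()` and `write_run_report()` export
TSV/BED/JSON; `autoplot(tiling)` draws the overlap structure;
`run_pipeline()` glues alignment → regions → tiling → files behind a YAML
config, and `inst/scripts/swarmprimer` exposes the verbs
`regions`, `design`, `validate` and `simulate` on the command line.

A published 22-pair conserved primer set for the *Scarus forsteni* /
*S. rubroviolaceus* mitogenome pair ships as a validation fixture
(`scarus_primer_set()`); `validate_primer_set()` audits any primer table —
published or freshly designed — against the pairwise constraints.

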