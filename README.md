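# looprule

Loop-length estimation along cryo-EM density-map skeletons.

## The problem

In de novo modelling from medium-resolution (5–10 Å) cryo-EM maps, α-helices
can be detected reliably but the chain connecting them cannot be traced
atom-by-atom. A key constraint for assigning sequence segments to detected
helices is the length of the loop between two helices: measured along the
map's voxel skeleton it should agree with the sequence expectation

```
expected = 3.8 Å × (n + 1)
```

for a loop of *n* residues (3.8 Å is the mean Cα–Cα distance between
sequence-adjacent residues). Measuring that length is not trivial: the
skeleton is a point cloud on a cubic lattice, it contains helix voxels and
disconnected clutter, and a naive walk along lattice edges overestimates the
length through zigzagging.

`looprule` implements the measurement pipeline:

1. **Helix masking** — remove skeleton voxels within 2.3 Å of either helix
   central axis (an α-helix is ≈2.3–2.5 Å in radius).
2. **Local connectivity graphs (LCGs)** — normalise distances to voxel units
   and join every pair of points closer than *l* < 2; the connected
   components are spatial clusters of skeleton voxels.
3. **Cluster selection** — for each of the four helix-endpoint pairs
   *Z* = {{p,r},{p,s},{q,r},{q,s}}, pick the LCG *b* minimising the directed
   Hausdorff distance *h(z,b)* = max over endpoints of the min distance to
   the cluster.
4. **Attachment and pathfinding** — connect each endpoint to its closest
   cluster voxel (discard the pair if either new edge exceeds 5 Å) and trace
   a breadth-first-search path between the endpoints.
5. **Simplification and measurement** — simplify the path with
   Douglas-Peucker vertex removal at tolerance ε and sum the remaining
   segments; sweeping ε over [0, 6] Å in 0.05 Å steps gives a non-increasing
   step function of measured length.

A seeded synthetic generator (`generate_hlh()`) builds helix-loop-helix
skeletons from cubic Bézier curves with analytically exact arc length, so the
whole pipeline can be validated against known ground truth.

## Worked example

```r
library(looprule)

hlh <- generate_hlh(3, seed = 7)          # 3-residue loop, true length 15.2 A
fit <- estimate_loop_length(hlh$cloud, hlh$helices, n_residues = 3)
fit
#> Loop length estimate (1 LCGs from 13 masked skeleton points)
#>  pair feasible expected measured    diff rel_err epsilon lcg_id
#>   p-r    FALSE     15.2       NA      NA      NA      NA  lcg01
#>   p-s    FALSE     15.2       NA      NA      NA      NA  lcg01
#>   q-r     TRUE     15.2    15.11 0.08824  0.5805       0  lcg01
#>   q-s    FALSE     15.2       NA      NA      NA      NA  lcg01
```

Only the `q-r` endpoint pair (the two helix ends actually bracketing the
loop) admits a path whose attachment edges stay within the 5 Å cutoff; its
measured length, 15.11 Å at the best swept tolerance, is within 0.09 Å of the
15.2 Å sequence expectation for a 3-residue loop. `plot(fit)` draws the
measured-length-versus-ε step function; `summary(fit)` adds the per-pair
Hausdorff distances and attachment lengths.

File-based runs use `run_measurement()` (skeletons as MRC/CCP4 maps or
plain-text XYZ; helices as JSON or 7-column text), or the shell wrapper:

```sh
Rscript inst/scripts/looprule simulate --n-loop 3 --seed 5 --out fx
Rscript inst/scripts/looprule measure --skeleton fx/skeleton.txt \
    --helices fx/helices.json --loop-residues 3 --report fx/report.tsv
```

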