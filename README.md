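# parabolaEDA

Fast parabola detection in binary edge images with a Univariate
Marginal Distribution Algorithm (UMDA), for curve parameterization
problems in medical image analysis — the major temporal arcade of
retinal fundus images and the plantar arch / heel contours of footprint
photographs are the motivating applications.

## The method

A sideways parabola in the image frame is described by its general form

    A*y^2 + B*y + C = x        (x = column, y = row, 0-based)

with vertex `y_v = -B/(2A)`, `x_v = C - B^2/(4A)` and aperture
`4p = 1/A`.  Three pixels with distinct rows determine the curve in
closed form, so a candidate solution is just a triplet of foreground
pixel indices, encoded as a concatenated bit string (`ceil(log2(N))`
bits per index).  The UMDA evolves a small population of such triplets
under a fully factorized probability model: each generation keeps the
best 60%, re-estimates per-bit marginal frequencies, and samples the
next population from them.  A candidate is scored by the Hadamard
(elementwise) product between its rasterized curve and the edge image —
the count of co-foreground pixels — so a detection needs at most
`10 individuals x 30 generations = 300` fitness evaluations regardless
of image size.

The package also provides the two classical baselines (a 3-parameter
Hough accumulator over the vertex form, and RANSAC with a
least-squares consensus refit), a ground-truthed synthetic scene
generator with salt-and-pepper noise sweeps and Zhang–Suen
skeletonization, the grayscale conditioning chain (3×3 mean filter →
Canny → disk dilation) with foot sectioning, and RMSD/overlap metrics
with benchmark orchestration.  See the vignette in `vignettes/` for the
model details and design rationale.

## Worked example

```r
library(parabolaEDA)

scene <- generate_scene(seed = 42)   # 512x512, 3 lines, 2 circles, 1 parabola
scene$truth
#> parabola (x = A*y^2 + B*y + C): A=-0.0237415  B=9.55604  C=-604.071
#>   vertex (x=357.5, y=201.3)  aperture 4p=-42.1203

res <- detect_parabola_umda(scene$image, umda_params(seed = 7))
res
#> detection_result (umda): fitness = 249, generations = 30 (best at 8), evaluations = 300
#> parabola (x = A*y^2 + B*y + C): A=-0.0231566  B=9.30325  C=-576.077
#>   vertex (x=358.3, y=200.9)  aperture 4p=-43.1843

overlap_fraction(scene$truth, res$parabola, 512, 512)
#> [1] 1
rmsd_report(scene$truth, res$parabola, 512, in_frame_only = TRUE, width = 512)
#> fit_report: RMSD = 4.748 px, normalized = 0.4748, matched 10 / 246 rows
```

The detection's `fitness = 249` says 249 of its rasterized pixels land
on scene foreground (the planted curve has 246 in-frame pixels); the
best individual was found in generation 8.  The recovered vertex
(358.3, 200.9) and aperture −43.2 sit within a pixel of the planted
(357.5, 201.3) and −42.1: the curve tracks the planted band across its
full extent (`overlap_fraction` = 1), while the in-frame RMSD of 4.7 px
reflects that the fitness cannot distinguish curves inside the same
3-px-thick band.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/parabola-detect.R simulate --out scenes/ --battery --seed 7
Rscript inst/cli/parabola-detect.R detect --input scenes/scene_0001.png --method umda
Rscript inst/cli/parabola-detect.R benchmark --scenes scenes/ --out results.csv
```

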