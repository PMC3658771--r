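# mpac — multipass active contours for adaptive contour maps

`mpac` builds a spatially adaptive contour map of a grayscale image —
nested, intensity-ordered contours plus their inclusion tree — for
topographic analysis of biomedical images such as mammograms, where the
bright end of the intensity range carries the interesting structure
(candidate masses) and fixed-interval isocontour maps give either too many
or too few curves.

## The method

A two-phase level-set segmentation is applied *recursively*. One pass
minimizes the piecewise-constant (Chan–Vese) energy restricted to the
current base region `w_k` (characteristic function `M_k`):

    E(c1, c2, φ) = λ₁ ∫ (I − c1)² H(−φ) M_k  +  λ₂ ∫ (I − c2)² H(φ) M_k
                 + μ ∫ g δ(φ) |∇φ|  +  v ∫ g H(−φ)
                 + α ∫ ½ (|∇φ| − 1)²

with region means `c1` (inner, `φ < 0`) and `c2` (outer), edge indicator
`g = 1/(1 + |∇I|²)`, and an internal penalty holding `φ` near a signed
distance function so no re-initialization is ever needed. The pass is
initialized from the *darkest seed* of the region (pixels within `κ` of
the regional minimum get `+ρ`, the rest `−ρ`), so the retained inner
region is the brighter part; it becomes the next base region. The
recursion ends when a pass degenerates (a sub-region empties), when a
split separates nothing (means closer than a contrast floor), or at a
pass cap. The input is denoised once with ROF total-variation smoothing
before segmentation.

The result is a chain `w0 ⊃ w1 ⊃ w2 ⊃ …` of strictly nested, strictly
brightening regions: a per-pixel label map (label = nesting depth),
sub-pixel zero-level polylines for each pass, and a path-shaped inclusion
tree annotated with areas and mean intensities.

## Worked example

Generate the reference synthetic phantom (128×128, four nested plateaus at
intensities 40/100/160/220, 5% uniform noise) and segment it:

```r
library(mpac)
ph  <- make_nested_phantom(phantom_spec(seed = 7))
res <- run_multipass(ph$image)
print(res)
#> Multipass segmentation: 3 productive passes, terminated by stationary
#>  pass iters terminated       c1        c2 inner_area outer_area     energy
#>     1   200  max_iters 133.1877  40.30744       9214       7170 2564640027
#>     2   200  max_iters 174.7897  99.89311       4096       5118  643346764
#>     3   200  max_iters 219.1145 160.01472       1024       3072   96015190
```

Pass 1 peels off the dark surround (mean 40.3) and keeps everything
brighter (mean 133.2); pass 2 peels the 100-plateau; pass 3 isolates the
brightest 32×32 core. The recursion then stops: bisecting the remaining
near-homogeneous core would split means less than 5 gray levels apart.
Each recovered region matches its ground-truth nested mask almost
pixel-perfectly (Jaccard agreement 0.9998, 1.0000, 1.0000).

```r
cmap <- build_contour_map(res)
print(cmap)
#> Adaptive contour map: 3 nested contours over a 128x128 grid
#>   inner areas by depth: 9214 > 4096 > 1024

build_inclusion_tree(cmap, res$image)
#>  id   name parent depth  kind  area mean_intensity
#>   1     w0     NA     0  root 16384          92.54
#>   2 w1_bar      1     1 outer  7170          40.31
#>   3     w1      1     1 inner  9214         133.19
#>   4 w2_bar      3     2 outer  5118          99.89
#>   5     w2      3     2 inner  4096         174.79
#>   6 w3_bar      5     3 outer  3072         160.01
#>   7     w3      5     3 inner  1024         219.11
```

The tree is a path along the inner chain `w0 → w1 → w2 → w3`; the outer
shells `wk_bar` are leaf siblings, their mean intensities increasing with
depth — the topographic, darkest-to-brightest decomposition.

From the shell, the same pipeline is:

```sh
exec/mpac phantom --out ph --seed 7
exec/mpac segment ph/phantom.pgm --out ph_seg
exec/mpac inspect ph_seg
```

which writes `labels.png`, per-pass masks, `contours.csv` (0-based
row/col polyline vertices), `tree.json` and a reproducibility manifest.

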