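---
title: "Multipass active contours: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipass active contours: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Topographic (isocontour) analysis of grayscale biomedical images — the
motivating case is mammography, where candidate masses live in the bright
end of the intensity range — needs a set of nested contours that is neither
too dense nor too sparse. Fixed-interval isocontour maps give either,
depending on image conditions. `mpac` instead builds the map *adaptively*:
a two-phase active-contour segmentation is applied recursively, each pass
splitting the current base region into a darker outer shell and a brighter
inner core, and only the core is split further. The contours accumulated
over all passes form the adaptive contour map; the nesting relations form a
path-shaped inclusion tree. Because every pass discards the darkest part of
its region, spurious local optima are spent in the least informative (dark)
areas and the bright, diagnostically interesting regions survive to the
later, finer passes.

## The energy

One pass minimizes, over a level-set field $\phi$ (inner region
$\{\phi < 0\}$) restricted to the base region's characteristic function
$M_k$,

$$
E(c_1, c_2, \phi) \;=\; \lambda_1 \!\int_\Omega (I - c_1)^2 H(-\phi)\, M_k
\;+\; \lambda_2 \!\int_\Omega (I - c_2)^2 H(\phi)\, M_k
\;+\; \mu \!\int_\Omega g\,\delta(\phi)\,|\nabla\phi|
\;+\; v \!\int_\Omega g\,H(-\phi)
\;+\; \alpha \!\int_\Omega \tfrac12 \left(|\nabla\phi| - 1\right)^2 ,
$$

the piecewise-constant (Chan–Vese) region terms with means $c_1$ (inner)
and $c_2$ (outer), an edge-weighted length and area regularization with the
edge indicator $g = 1/(1 + |\nabla I|^2)$, and the internal penalty that
holds $\phi$ near a signed distance function, removing the classical
re-initialization step. Heaviside and Dirac factors are the regularized
pair $H_\epsilon(z) = \tfrac12(1 + \tfrac{2}{\pi}\arctan(z/\epsilon))$,
$\delta_\epsilon = H_\epsilon'$. Minimization alternates between the
closed-form means and explicit gradient descent
$\phi \leftarrow \phi + \tau\,Q(\phi)$, where $Q$ is the negative
variation of $E$; its penalty part is diffusion with rate
$\alpha\,(1 - 1/|\nabla\phi|)$, positive where $|\nabla\phi| > 1$ and
reversed where $|\nabla\phi| < 1$.

Each pass is initialized with a two-valued field: $+\rho$ outside the base
region and on its *darkest seed* (pixels within $\kappa$ of the regional
minimum), $-\rho$ elsewhere. On a region homogeneous to within $\kappa$
the seed swallows everything, the inner region is empty, and the recursion
terminates by degeneracy.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `lambda1`, `lambda2` | 100 | (gray)$^{-2}$-ish weight | inner/outer region terms |
| `mu` | $200/225^2$ | weight | edge-weighted contour length |
| `v` | 0 | weight | edge-weighted area (sign drives shrink/expand) |
| `tau` | 1 | — | explicit time step |
| `alpha` | $0.2/\tau$ | weight | signed-distance penalty; `tau * alpha < 1/4` enforced |
| `eps` | 1.5 | px | Heaviside/Dirac regularization width |
| `eps_d` | $10^{-8}$ | — | division guard inside gradient-magnitude roots |
| `rho` | $4\,\epsilon = 6$ | — | initial plateau magnitude and clamp range |
| `kappa` | 1 | gray | darkest-seed offset / homogeneity quantum |
| `min_split_contrast` | 5 | gray | minimum $|c_1 - c_2|$ for a split to count |
| `max_iters_per_pass` | 200 | — | safety cap |
| `stationary_window`, `stationary_tol` | 3, 0.02 | — | quiescence detection |

ROF denoising (`rof_config()`) runs first, once per image: gradient descent
on $\int |\nabla I| + \lambda \int (I_0 - I)^2$ with `lam = 0.1` on the
0–255 scale, `dt = 0.1`, 100 iterations (the fidelity update is
semi-implicit, so arbitrarily large `lam` is stable and returns the input).
These descent settings are a package choice — measured as converged on the
reference phantom: plateau statistics are unchanged between $10^2$ and
$5\times 10^3$ iterations.

## Numerical choices

**Discrete-gradient consistency.** The energy is discretized with forward
differences for $|\nabla\phi|$ (with `eps_d` inside the square root, one
shared value per pixel for the x/y pair) and pointwise Heaviside/Dirac
factors; `gradient_flow()` is then assembled as the *exact* negative
gradient of `total_energy()` at fixed $c_1, c_2$: flux divergences are
backward differences with zero (no-flux) boundary padding — the exact
adjoint of the forward gradient — and the length term uses the
conservative form
$\mathrm{div}(g\,\delta_\epsilon(\phi)\,\nabla\phi/|\nabla\phi|) -
g\,\delta_\epsilon'(\phi)\,|\nabla\phi|$, whose continuum limit is the
familiar $\delta_\epsilon(\phi)\,\mathrm{div}(g\,\nabla\phi/|\nabla\phi|)$.
Exactness is what makes the explicit scheme an honest descent and lets the
test suite verify the flow against finite differences of the energy to
$10^{-6}$ relative. The standalone `curvature_divergence()` operator keeps
the classical mixed forward/central pairing with replicate-edge boundaries
and is validated separately against the analytic curvature $1/\rho$ of
disk level sets.

**Saturation of the level set.** With the default weights on 0–255
intensities the region force at a wrongly-labeled pixel is of order
$\delta_\epsilon(\rho)\,\lambda\,(I - c)^2 \sim 10^3$–$10^4$ per step.
Left unchecked this blows $|\phi|$ up to $10^3$–$10^5$, after which the
zero crossing creeps diffusively for hundreds of iterations. `evolve_pass()`
therefore clamps $\phi$ to $[-\rho, \rho]$ after every step (projected
descent): the region forces only need to decide the *sign* of $\phi$, and
within the $\pm\rho$ band the penalty shapes the profile. The clamp range
equals the initialization's plateau values, so the initial field is
feasible by construction. Scaling the intensities into $[0,1]$ instead was
tried and rejected: it weakens the region force to the point that the
penalty's diffusion erases the small, isolated darkest-seed set within one
or two iterations and every pass degenerates.

**Stationarity.** A pass is stationary when it is *quiescent* — the inner
pixel set unchanged **and** no pixel of $\phi$ moving by more than
`stationary_tol` — for `stationary_window` consecutive iterations. Sign
stationarity alone is not enough: it can trigger while pixels are still
drifting toward a crossing, or while the penalty is still reshaping the
profile that the sub-pixel contour extraction interpolates.

**Degeneracy.** Smoothed Heavisides are never exactly zero, so "empty
sub-region" means a weighted area below 0.5 pixel-equivalents; the binary
sets $\{\phi<0\}$, $\{\phi\ge 0\}$ within the base region are additionally
checked each iteration.

**Recursion stop.** Besides degeneracy and the exact fixed point, the
driver rejects a converged split with $|c_1 - c_2| <$
`min_split_contrast` (default 5 gray levels) and declares the recursion
stationary. This is required in practice: total-variation denoising
cannot flatten a noisy plateau to within $\kappa = 1$ — at *any* fidelity
weight the minimizer loses edge contrast faster than it removes the last
few gray levels of plateau spread — so without a contrast floor the
recursion keeps bisecting residual noise (splits with contrast 1–3 gray
levels) long after the real structure (contrast $\geq 50$ on the reference
phantom) is exhausted. Five gray levels is about twice the residual noise
spread that ROF leaves at the default settings, i.e. 2% of the 8-bit
range; set `min_split_contrast = 0` to recover the undamped recursion.

## The synthetic generator

`make_nested_phantom()` emulates what the method assumes: strictly nested
sharp-edged intensity plateaus (squares, disks, or drifting "offset"
disks), darkest level outermost, plus i.i.d. additive uniform noise on
$\pm$`noise_frac`$\times 255$ (clamped to $[0,255]$), with the ground-truth
nested masks returned alongside. The reference study condition used by the
tests and the acceptance script is $128\times128$, levels 40/100/160/220,
5% noise, fixed seed. What the phantoms do **not** emulate: textured or
cluttered backgrounds, blurred edges, intensity gradients within regions,
or correlated noise — so passing recovery tests here demonstrates the
mechanics of the recursion, not mammogram-grade robustness. Full-scale
mammograms ($1024\times1024$) run the same code path but are not part of
the test suite.

## Known limitations

- **The signed-distance band saturates at strong edges.** After a
  converged pass, $|\nabla\phi| \approx 1$ holds in the band $|\phi| < 3$
  only where the region forces are weak (e.g. when bisecting a noisy
  near-homogeneous plateau, where we measure band medians of 1.18–1.34).
  At high-contrast structural contours the region force exceeds the
  penalty's restoring force by roughly four orders of magnitude and pins
  $\phi$ to $\pm\rho$ on either side of the crossing, leaving the band
  empty: the converged field is a (clamped) sign pattern, not a distance
  map. The contour position is unaffected; only the distance-map
  interpretation of $\phi$ is lost there.
- **Iteration counts** on noisy images typically run to the per-pass cap
  (200) because borderline pixels keep flickering below the quiescence
  tolerance; on clean images passes converge in a handful of iterations.
- **TV preprocessing trades contrast for smoothness**; the `kappa`-based
  degeneracy stop therefore rarely fires on noisy data, and termination
  falls to the contrast floor described above.
- The inclusion tree is a path by construction (only inner regions are
  re-split); images whose interesting structure is side-by-side rather
  than nested need several runs on sub-masks, which the API supports via
  `evolve_pass()` but the driver does not automate.

## Problem sizes

The test suite runs entirely on generated fixtures: $16\times16$ random
configurations for the oracle and gradient checks, $41$–$101$ pixel
analytic signed-distance fields for the operator checks, $48$–$96$ pixel
phantoms for the driver tests, and the $128\times128$ reference phantom
for end-to-end recovery; the whole suite completes in well under a minute.
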