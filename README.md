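# PlanarCollagen

Quantifies the planar organization of collagen fibers in second harmonic
generation (SHG) z-stacks of soft tissue — built for mitral valve leaflets,
where the depth profile of fiber alignment separates healthy tissue from the
two phenotypes of degenerative mitral valve disease (fibroelastic
deficiency, FED, and Barlow's disease, BD). It is aimed at researchers in
cardiovascular biomechanics and microscopy image analysis who have depth-
resolved grayscale stacks and need per-depth fiber statistics and
between-group comparisons.

## The method

Each optical slice is converted to an axial fiber-orientation density on a
1° grid: subtract the mean, apply a 2D Tukey window, compute the Fourier
power spectrum, sum spectral energy in 1°-wide double wedges inside a radial
annulus (fiber angle = spectral angle + 90°), smooth with a 7° circular
moving average, and normalize to unit integral over the half turn. The
density is parameterized by a two-family π-periodic von Mises mixture

ρ(θ) = w · exp{a₁ cos[2(θ − α₁)]}/(π I₀(a₁))
     + (1 − w) · exp{a₂ cos[2(θ − α₂)]}/(π I₀(a₂)),

fitted by least squares, giving two preferred orientations α₁ ≥ α₂
(degrees from the circumferential direction), concentrations a₁, a₂, a
weight w, and the average alignment parameter **ā = a₁w + a₂(1 − w)** —
higher ā, more aligned fibers; isotropic layers get ā = 0. Depth profiles
are summarized in 100-µm bins, stacked into angle-by-depth distribution
maps, and coupled across depths by the bivariate correlation C(z, z′)
(Pearson, across samples, complete pairs per cell). Group inference uses
per-patient averages with one-way ANOVA (linear variables) and the
Watson–Williams circular test (orientations).

A synthetic fiber-phantom generator with exact von Mises ground truth
(straight anti-aliased segments, blur, noise, depth templates for
control-like / FED-like / BD-like architecture) makes every stage testable
without microscopy data.

## A worked example

```r
library(PlanarCollagen)

spec <- stackSpec("control_like", nSlices = 8, zStepUm = 75,
                  imageSizePx = 512, nFibers = 600, alpha0Deg = 20, seed = 75)
st   <- renderStack(spec)
prof <- fitStack(st$stack, keepDistributions = FALSE)
prof
#> DepthProfile 'control_like' (patient P1, group control): 8 depths, 0-525 um
#>   mean aBar 5.32 (0 isotropic layers)
head(fits(prof)[, c("depth_um", "a_bar", "alpha1_deg", "alpha2_deg", "w")], 4)
#>   depth_um     a_bar alpha1_deg alpha2_deg          w
#> 1        0  7.262058   19.26838   18.92953 0.06430995
#> 2       75  5.891175   22.14598   22.03729 0.75639754
#> 3      150 10.216629   20.60444   20.32722 0.13910051
#> 4      225  5.613668   18.97095   18.74423 0.36278925
```

The generator truth here is a single fiber family at 20° with a = 6 over
the first 300 µm (the collagen-dense fibrosa) and a = 2 below. The fitted
orientations sit within about 2° of 20°; the two nearly coincident
"families" are the least-squares mixture's way of describing one family
from a single noisy slice, and their combined ā is high in the fibrosa and
drops below 300 µm — the depth step that distinguishes healthy from
BD-like tissue. Single-slice ā values scatter around the truth by 15–20
percent (see the methods vignette for why); binned and group averages are
where the precision comes from. `binByDepth(prof)` reduces this
to 100-µm bin summaries and `buildTable1()` assembles the
nine-bins-by-group report with its Average row.

(The numbers above are from this exact seeded call; your output is
identical because all generator randomness is seed-derived.)

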