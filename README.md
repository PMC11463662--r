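# LMSFilter

Background identification and removal in fluorescence microscopy images
with the **local mean suppression filter (LMSF)**. The package is aimed
at people processing fluorescence images of tissue — nuclei stains,
membrane markers, multiplexed panels — who need a reliable, unsupervised
foreground/background split as a preprocessing step for quantification
or instance segmentation, especially when the foreground is dense and
partly low-contrast.

## The method

LMSF is a pixel-wise nonlinear filter. For an image $I(k,m)$ it computes
the adaptive local mean $\bar I(k,m)$ over a $(2n+1)\times(2n+1)$ window
(clipped to the image near borders, dividing by the count of available
pixels — no padding) and suppresses the pixel when it is sufficiently
dimmer than its neighbourhood:

$$
\hat I(k,m) =
\begin{cases}
0, & I(k,m)/\bar I(k,m) < \theta \\
I(k,m), & \text{otherwise.}
\end{cases}
$$

Foreground pixels are returned **bit-identical** to the input; the
filter labels, it never smooths. The half-window is bounded by
$n_{\max} = \lfloor\min(K,M)/2\rfloor - 1$. The cumulative multi-scale
method runs the filter at a family of scales $N$ on the original image
and unions the per-scale background masks: small scales catch narrow
gaps between crowded nuclei, large scales catch wide, gradually varying
background. $\theta = 0.5$ is a good default; `selectScales()`
implements the rule of thumb for choosing $N$ (half the maximal narrow
gap width, halved recursively, plus $n_{\max}$ for images with extended
background).

Applications included: per-channel filtering of multiplexed stacks
combined into a $2^C$-class co-localization map (`colocalize()`),
background-zeroing denoising ahead of instance segmenters
(`denoiseImage()`), and a display-only gamma transform
(`gammaDisplay()`). A deterministic synthetic nuclei-scene generator
with ground-truth masks (`simNucleiImage()`, `scenePreset()`) backs the
validation suite. See `vignettes/lmsf-methods.Rmd` for the full account.

## Worked example

```r
library(LMSFilter)

spec <- scenePreset("large-background")   # frozen synthetic regime
scn  <- simNucleiImage(spec)              # image + ground truth
res  <- cumulativeLMSF(sceneImage(scn), scales = spec@scales,
                       theta = spec@theta)
res
#> LMSFResult: 192 x 192 image
#>   theta:  0.5
#>   scales: {5, 10, 20, 40, 95}
#>   background: 29491 px (80.0%)
backgroundF1(backgroundMask(res), trueBackground(scn))
#> [1] 0.9371729
```

The filter labelled 80% of the scene as background; against the
generator's ground-truth mask that recovery has a pixelwise F1 of 0.937
(1.0 would be a perfect match of background pixels). A two-channel
co-localization map and its class areas:

```r
cm <- colocalize(list(nuc = sceneImage(scn),
                      mem = sceneImage(simNucleiImage(scenePreset("large-foreground")))),
                 theta = 0.5, scales = c(5, 10, 20, 40))
classAreaTable(cm)
#>   label channels count  fraction
#> 1     0     none 14909 0.4044325
#> 2     1      nuc  8542 0.2317166
#> 3     2      mem  6777 0.1838379
#> 4     3  nuc+mem  6636 0.1800130
```

Each label's bits record which channels are foreground at that pixel
(channel 1 = least significant bit), so label 3 marks pixels foreground
in both channels.

## Command line

A thin wrapper around the same functions ships in `inst/scripts/lmsf`:

```sh
Rscript inst/scripts/lmsf background image.tif --theta 0.5 --scales 5,10,20,40 --out out/
Rscript inst/scripts/lmsf coloc stack.tif --theta 0.5,0.95,0.6 --scales 5,10,20,40 --out out/
Rscript inst/scripts/lmsf fixtures --preset large-background --seed 7 --out fixtures/
```

Every run writes a JSON manifest with parameters and output checksums;
identical inputs and flags reproduce identical files.

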