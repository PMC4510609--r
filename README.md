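# rhodomap

Maps the spatial distribution of rod rhodopsin optical density across the
human retina from standard clinical 488 nm autofluorescence imaging. The
input is a registered one-minute movie from a confocal scanning laser
ophthalmoscope: a dark-adapted retina starts dim because unbleached
rhodopsin absorbs roughly half the double-pass light, and brightens as the
rhodopsin bleaches. The per-pixel brightening follows

    AF(t) = α · exp(−γ · exp(−β t))

with α the fully bleached amplitude (attenuated by macular pigment),
β = I/L the bleaching rate, and γ the double-path rhodopsin optical density
at 488 nm — the quantity being mapped. The package is aimed at vision
scientists and methodologists working on quantitative fundus
autofluorescence: it provides the biophysical forward model, macular
pigment densitometry from multi-spectral image sets, a per-pixel
variational fitter, model-derived vessel detection, wavelet
Ginzburg–Landau inpainting of vessel occlusions, and a synthetic retinal
phantom generator with ground truth so the whole pipeline can be validated
without clinical data.

## The method in brief

1. **Macular pigment**: from n wavelength-tagged AF images with zero-sum
   weights ω,
   `D_MP(460) = Σ ω_j ln(AF_p/AF_f) / Σ ω_j (k_MP(Λ_j)+k_MP(λ_j))` —
   the zero-sum weights cancel the fluorophore-efficiency ratio.
2. **Initialization**: a 3-parameter fit of the 5–8° annulus-averaged
   curve, and a histogram of per-pixel rates whose mode fixes b₀ (the rate
   is a photochemical constant, spatially invariant).
3. **Per-pixel fit**: minimize the mean-square-log energy
   `E(p,b,c) = Σ |ln f(tᵢ) − p + c e^(−b tᵢ)|² Δtᵢ` (p = ln a) by a
   semi-explicit scheme with closed-form implicit updates; for fixed b > 0
   the energy is strictly convex, so the unique critical point is the
   global minimum. The ĉ field is the preliminary rhodopsin map.
4. **Vessel detection** from the fit itself: slow-convergence regions of
   the iteration-count map N(x,y) and high L1 model residuals ΔAF(x,y),
   union, dilation, and a smooth mask χ ∈ [0,1].
5. **Inpainting**: per bit plane, minimize the wavelet Ginzburg–Landau
   energy `w_f∫χ|u−g|² + (1/2εμ)∫u²(u−1)² + εμ|u|_B²`; three (ε, μ)
   variants are averaged and adaptively wavelet-thresholded.

## Worked example

```r
library(rhodomap)

spec <- phantom_spec(shape = c(96, 96), fov_deg = 24, frame_rate = 8,
                     duration = 30, seed = 42)
ph <- generate_movie(spec)
ph$movie
#> af_movie: 96 x 96 pixels, 240 frames, t = [0, 29.9] s, fov 24 deg

bands <- list(spectral_band(460, 620), spectral_band(488, 640),
              spectral_band(520, 660), spectral_band(550, 680))
mp <- generate_mp_set(spec, bands, weights = c(1, 1, -1, -1), noise_sd = 0.5)

res <- run_pipeline(ph$movie, mp_set = mp$mpset)
res
#> rhodopsin_map: 96 x 96, gamma in [0.0519, 0.594] (relative units), 18.80% inpainted
res$init$b0
#> 0.3195        # estimated bleaching rate, 1/s; the phantom's true rate is 0.32
res$inpaint
#> inpaint_result: 96 x 96, 8-bit, amplitude deviation 0.196%,
#> relative MSE 0.000205% outside the mask

sel <- !ph$truth$vessel_field
cor(res$gamma[sel], ph$truth$gamma_map[sel])
#> 0.987         # recovered map vs ground-truth rhodopsin field
```

`res$gamma` is the final inpainted rhodopsin optical density map in
relative units (absolute amplitudes depend on uncorrected image
background, so only the distribution is claimed); `res$fit$c_hat` is the
preliminary map, `res$mask` the vessel mask, and
`radial_profiles(res$gamma, center)` gives stripe-averaged
horizontal/vertical profiles through the fovea. A thin command-line front
end (`inst/scripts/rhodomap.R simulate | run-all`) wraps the same
functions for shell use, reading and writing float TIFFs with YAML
manifests.

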