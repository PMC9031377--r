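# resharp

Spectral sharpening and resonance-frequency estimation for microwave
resonant sensors.

## What problem this solves

Resonant microwave sensors — the motivating case is a patch-antenna
biosensor immersed in a water–glucose solution for non-invasive glucose
monitoring — encode their measurand in the position of the maximum of the
return loss

    RL(f) = −20 · log10 |Γ(f)|     [dB]

where Γ(f) is the one-port reflection coefficient (S11).  Low sensor
quality factors make the resonance lobe broad, and the instrument samples
the band coarsely: with Nf points on [fmin, fMAX] the acquisition step is
Δf = (fMAX − fmin)/(Nf − 1), e.g. 10 MHz for 101 points on 2–3 GHz.  The
raw "largest sample" estimate is therefore both coarse and easily fooled.

`resharp` implements three numerical sharpening estimators that localise
the resonance to a small fraction of Δf, for people building or
benchmarking such sensors:

* **single-step** — one pair of discrete-time Fourier transforms: the
  phase φ(t) of the inverse-transformed return loss is almost linear with
  slope 2π·f_res on its magnitude main lobe; the magnitude of the forward
  DTFT of e^{jφ(t)} over that lobe is a much tighter peak, and its argmax
  is the estimate;
* **iterative** — repeats the transform pair, re-transforming the
  *squared* sharpened curve until the time-domain magnitude stays above
  the support threshold over the whole window;
* **MUSIC** — the pseudospectrum P(f) = (aᴴa)/(aᴴṼṼᴴa) of the rank-1
  correlation matrix of the unit-modulus phase vector, scanned over the
  retained band (a(f) is the steering vector, Ṽ the noise subspace).

All three share a preprocessing chain (sweep averaging, endpoint
flattening and baseline removal, α-band selection in frequency, β-support
selection in time) controlled by the quintuple (α, β, Nt, N̂f) plus the
acquired Nf.  The package also provides an asymmetric-Gaussian synthetic
trace generator with an acquisition-noise model, Monte Carlo benchmarking
by percentage error PE = |f_true − f_est|/f_true × 100, blind dispersion
characterisation for measured traces, CSV/Touchstone(.s1p) readers, and a
CLI.  The methods vignette (`vignettes/methods.Rmd`) documents the model,
the numerical choices and the design decisions.

## Worked example

```r
library(resharp)

# reference synthetic resonance: peak 20 dB at 2.25 GHz, asymmetric
# flanks 0.07/0.10 GHz, 101 samples on 2-3 GHz (step 10 MHz)
tr <- synth_return_loss(synthetic_model(ftrue = 2.25e9), Nf = 101)
tr
#> <return_loss_trace> Nf = 101, band [2, 3] GHz, uniform step 10 MHz
#>   RL range [2, 20] dB, peak at 2.25 GHz

est <- estimate(tr, sharpen_params(alpha = 0.1, beta = 0.05,
                                   Nt = 512, N_hat_f = 512))
est
#> <estimation_result> single_step: f_est = 2.2513307 GHz (grid step 724.1 kHz)
#>   alpha band [2.1, 2.47] GHz, support samples 52, 1 iteration(s)

percentage_error(2.25e9, est$f_est)
#> [1] 0.05914329
```

The estimate misses the true resonance by 1.33 MHz (0.059 %) — about 7×
finer than the 10 MHz acquisition step — and the sharpened curve is
evaluated on a 724 kHz grid inside the retained band.  Benchmarking the
three algorithms over random settings (β pinned to 0.05, the
high-accuracy regime):

```r
run_monte_carlo(mc_config(n_reps = 100, seed = 1,
                          fixed = list(beta = 0.05)))
#> <mc_report> pe mode, 100 rep(s), seed 1
#>   single_step  mean 0.0811386  sd 0.0766  median 0.0711509  P5 0.00416791  P95 0.230701  [% (PE)]
#>   iterative    mean 0.148315  sd 0.199  median 0.0700013  P5 0.0078671  P95 0.643782  [% (PE)]
#>   music        mean 0.0811386  sd 0.0766  median 0.0711509  P5 0.00416791  P95 0.230701  [% (PE)]
```

Single-step and MUSIC report identical statistics — under this package's
shared preprocessing the rank-1 pseudospectrum is a monotone transform of
the single-step curve, so their argmax coincides (see the vignette) — and
both keep 95 % of errors near 0.2 %, while the iterative variant trades
accuracy for an even tighter final curve.

## Command line

```sh
Rscript inst/scripts/resharp simulate --ftrue-ghz 2.25 --nf 101 --out trace.csv
Rscript inst/scripts/resharp sharpen --input trace.csv --unit hz --algorithm music
Rscript inst/scripts/resharp benchmark --n-reps 500 --seed 1 --fix-beta 0.05 \
        --output-dir results
Rscript inst/scripts/resharp characterize --input trace.csv --unit hz \
        --n-reps 500 --output-dir results
```

Preset JSON configurations for the three reference experiments live in
`inst/extdata/` (`--config <file>`); flags override config values.

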