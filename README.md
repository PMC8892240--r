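# mbcc — multi-band collaborative classification

`mbcc` implements a classifier for multi-frequency-band signal data,
the motivating case being EEG emotion recognition from band-power
features. Each trial is observed as one feature vector per frequency
band (delta, theta, alpha, …); bands are coupled views of the same
event. The model learns, jointly:

* a **shared-plus-specific projection** per band,
  `G^m = (1 − σ)·G0 + σ·G̃^m`, mapping every band into a common
  low-dimensional subspace while letting each band keep its own
  component; and
* a **shared class-structured dictionary** in that subspace, trained
  under a Fisher-style criterion on coding-reconstruction residuals:
  projections and dictionary are chosen so each sample is reconstructed
  well by its own class's atoms and poorly by the other classes',
  with a variance-retention reward keeping the shared component
  anchored to directions that carry data energy.

The projection step is solved as an orthonormal trace-ratio problem by
a damped-Newton root iteration with a bisection safeguard
(`solve_projection()`); the dictionary step is a backtracking gradient
descent on the residual Fisher ratio. Classification is per-band
nearest-class-subspace on residuals followed by a majority vote across
bands. `fit_opfddl()` provides the per-band baseline without the
shared component, and `make_synthetic()` generates benchmark problems
with known ground truth (including an oracle classifier as a
performance ceiling). The accompanying vignette
(`vignettes/mbcc-methods.Rmd`) documents the model, the numerical
choices — including two deliberate reformulations of the projection
step and the reasons for them — and the limitations.

## Worked example

Fit the model on a synthetic 3-band, 3-class benchmark and evaluate on
held-out data:

```r
library(mbcc)

# a separable 3-band, 3-class benchmark with ground truth
syn <- make_synthetic(separable_preset(seed = 42))
syn$train
#> <multiband_dataset> 3 band(s) x 20 features x 120 samples, 3 class(es)
#>   bands:  band1, band2, band3
#>   classes: 1 (n=40), 2 (n=40), 3 (n=40)

cfg <- mbcc_config(p = 10, atoms_per_class = 5)
fit <- fit_mbcc(syn$train, cfg)
fit
#> <mbcc_model> method = mbcc, 3 band(s), d = 20, p = 10, 3 classes
#>   dictionary: 15 atoms (5 per class)
#>   50 iteration(s); final objective 0.0641044, rho 0.735349

evaluate(fit, syn$test)
#> <mbcc_eval> accuracy 1.0000 on 120 samples
#>   per-band accuracy: band1 1.000, band2 1.000, band3 1.000
#>   confusion (rows = true):
#>     predicted
#> true  1  2  3
#>    1 40  0  0
#>    2  0 40  0
#>    3  0  0 40
```

Under increasing observation noise, accuracy degrades gracefully and
the shared component keeps the collaborative model at or above the
independent per-band baseline, with the generator-truth oracle as the
ceiling:

```r
for (ns in c(0.3, 1.0, 2.0, 3.0)) {
  syn <- make_synthetic(separable_preset(seed = 42, noise_sd = ns))
  acc  <- evaluate(fit_mbcc(syn$train, cfg), syn$test)$accuracy
  accb <- evaluate(fit_opfddl(syn$train, cfg), syn$test)$accuracy
  acco <- mean(oracle_predict(syn$truth, syn$test) == syn$test$labels)
  cat(sprintf("noise %.1f: mbcc %.3f  opfddl %.3f  oracle %.3f\n",
              ns, acc, accb, acco))
}
#> noise 0.3: mbcc 0.958  opfddl 0.950  oracle 1.000
#> noise 1.0: mbcc 0.383  opfddl 0.375  oracle 0.733
#> noise 2.0: mbcc 0.417  opfddl 0.283  oracle 0.467
#> noise 3.0: mbcc 0.350  opfddl 0.333  oracle 0.392
```

For raw multichannel recordings, the feature pipeline slices the
signal into epochs and extracts per-channel Welch band power; a 10 Hz
tone planted on channel 1 shows up as elevated alpha log-power on that
channel only:

```r
set.seed(7)
rate <- 128
x <- matrix(rnorm(4 * 10 * rate), nrow = 4)   # 4 channels, 10 s of signal
x[1, ] <- x[1, ] + 3 * sin(2 * pi * 10 * seq_len(ncol(x)) / rate)

ep <- slice_epochs(x, rate, label = 1, window_s = 2)
ds <- extract_multiband(ep, bands = default_bands()[1:4, ], log_power = TRUE)
ds
#> <multiband_dataset> 4 band(s) x 4 features x 5 samples, 1 class(es)
#>   bands:  delta, theta, alpha, beta
#>   classes: 1 (n=5)
round(ds$Z$alpha[, 1:3], 2)
#>       [,1]  [,2]  [,3]
#> [1,]  1.54  1.58  1.51
#> [2,] -1.94 -2.53 -2.14
#> [3,] -1.91 -2.16 -2.75
#> [4,] -2.27 -3.09 -2.43
```

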