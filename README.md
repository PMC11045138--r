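# bpwp — basis pursuit denoising with polynomial detrending

`bpwp` recovers narrowband oscillations and slow polynomial trends from
sparsely and irregularly sampled long-term timeseries. The motivating signal
is the hourly rate of inter-ictal epileptiform discharges (IEDs) recorded
from human hippocampus by implanted devices: IED rates carry circadian and
multidien (multi-day) cycles, but storage and telemetry limits mean only a
few irregular samples per day may survive. Classical spectral estimators
need dense regular sampling; `bpwp` does not.

## The model

Observed samples `y` (length m) are modeled as a subsampled sum of
oscillations, a trend, and noise:

    y = A x + B z + eps,   A = Phi Psi,  B = Phi T

where `Psi` is an N x N DCT-II dictionary on a nonuniform frequency grid
(fractional frequency indices densify the multi-day period range), `T` is a
Vandermonde polynomial basis on normalized time, and `Phi` selects the m
observed rows. Estimation solves

    min_{x,z} || y - A x - B z ||_2^2   s.t.  || x ||_1 <= delta

by variable projection: eliminate `z` with the projector `P = I - B B^+`,
solve the L1-ball-constrained least squares for `x` (accelerated projected
gradient with exact ball projection), then recover `z = B^+ (y - A x)`.
The budget `delta` is selected by repeated random-split (10-fold, 75/25)
cross-validation; spectral peaks are tested against a noise floor built by
shuffling the observed values over the fixed sample times and refitting
(99th percentile, per coefficient).

## Worked example

Simulate a year of hourly IED rates with cycles at 1, 7, 15, 21, 30, 50 and
100 days plus a rising trend, keep 5 random samples per day, and recover the
cycles:

```r
library(bpwp)
res <- cycle_recovery_experiment(seed = 7)
res
#> <cycle_recovery> N = 8760 dense, m = 1800 sparse samples, delta = 6341.1
#>     1.0-day cycle: recovered (nearest significant 1.00 days)
#>     7.0-day cycle: recovered (nearest significant 7.00 days)
#>    15.0-day cycle: recovered (nearest significant 15.00 days)
#>    21.0-day cycle: recovered (nearest significant 21.00 days)
#>    30.0-day cycle: recovered (nearest significant 30.00 days)
#>    50.0-day cycle: recovered (nearest significant 50.00 days)
#>   100.0-day cycle: recovered (nearest significant 100.00 days)
#>   longest significant period: 101.00 days
```

Each line reports whether a generator cycle has a significant narrowband
peak within 10% of its period after the full pipeline (sampling, delta
cross-validation, fit, 25-iteration shuffle null); the last line is the
longest period the method calls significant — the 100-day component, not a
spurious slower cycle, because the polynomial block absorbs the trend.

Lower-level pieces compose the same way on real data:

```r
d  <- read_series("ied_rates_dense.csv")          # dense record, or
s  <- read_series("ied_rates_sparse.csv")         # sparse samples
s  <- attach_grid(s, N = 26280, dt = 1/72)        # align to analysis grid
g  <- build_frequency_mapping(26280, 1/72)        # remapped DCT grid
an <- bpwp(s, g, n_shuffle = 100, seed = 1)       # CV + fit + null
significant_periods(an)
rec <- reconstruct(an$fit, g, an$poly,
                   keep = an$spectrum$significant & an$spectrum$period_days > 2)
phase_analysis(rec, read_events("seizures.csv"))  # event-phase histograms
```

A command-line front end wrapping these functions is installed at
`inst/cli/bpwp.R` (`Rscript bpwp.R simulate|sample|cv|fit|significance|
reconstruct|phase|evaluate-density|evaluate-bands|detect-experiment ...`).

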