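# vactraffic

Kinetic analysis of cargo traffic to the yeast vacuole from 4D (time-lapse
3D) confocal fluorescence movies — with a ground-truthed synthetic movie
generator for validating every step of the analysis.

## The problem

In *Saccharomyces cerevisiae*, a biosynthetic vacuolar cargo travels
ER → Golgi → prevacuolar endosome (PVE) → vacuole. Two kinetic questions
drive the analyses in this package:

* **Golgi exit timing.** Yeast Golgi cisternae mature individually: an early
  marker (Vrg4) gives way to a late marker (Sec7). Vacuolar cargo is sorted
  by the Vps10 receptor into GGA-coated vesicles, and the GGA adaptors
  arrive at the early-to-late transition — so cargo should begin to exit
  near the *midpoint* of maturation, well before the cisterna dissolves.
  AP-1 (Apl2), which arrives tens of seconds later, should be dispensable.
* **PVE → vacuole transfer.** PVE compartments are stable organelles that
  never disappear by full fusion. Cargo reaches the vacuole gradually,
  punctuated by **kiss-and-run bursts**: intervals in which a transient
  fusion pore transfers a large fraction of the remaining cargo at once.

The package implements the measurement procedures used on such movies, and a
compartment-level simulator that encodes the published study conditions so
each procedure can be tested against known ground truth.

## The statistics at the core

For a PVE cargo trace resampled at 10 s boundaries with remaining cargo
$R_i$, the per-interval transfer fraction is

$$f_i = \frac{\max(0,\; R_{i-1} - R_i)}{R_{i-1}},$$

and interval $i$ is scored a **burst** when $f_i > 0.15$ (with a floor guard
once $R_{i-1}$ falls below 2% of $R_0$). Summaries report burst frequency
(events/min), the mean per-burst fraction, and the share of total net
transfer carried by bursts.

For maturation, each marker trace is normalized to the mean of its three
highest values; the **transition midpoint** is the interpolated time where
the normalized late-marker trace first crosses above the early-marker trace.
Traces are re-normalized to their first six (cargo, early marker) or last
six (late marker) values, aligned at the midpoint, and averaged with SEM.
First appearance of cargo in the vacuole is the earliest frame reaching 5%
of the cell's final (last-three-frame mean) value.

## Worked example

Simulate six 10-minute PVE transfer movies at the default (wild-type)
kinetics and run the burst analysis:

```r
library(vactraffic)
library(dplyr)

kin <- kinetic_config()                      # wild-type defaults
bm  <- simulate_burst_movies(6, kin, seed = 42, n_pve = 1)
ba  <- burst_analysis(bm$traces, interval = 10, threshold = 0.15)
ba$pooled
#> # A tibble: 1 × 7
#>   n_structures n_bursts total_duration_min frequency_per_min
#>          <int>    <int>              <dbl>             <dbl>
#> 1            6        6                 60               0.1
#>   mean_fraction_per_burst mean_fraction_per_movie total_fraction_in_bursts
#> 1                   0.279                   0.253                    0.447
```

Six movies is deliberately few — at this sample size the frequency and
fraction estimates scatter widely around the generator's truth (one burst
per 5 min on average, ~0.4 mean fraction); `scripts/acceptance.R` runs the
same analysis at 40 movies. The detected events, their sizes, and the
remaining-cargo timeline for any compartment come from
`ba$tables` / `plot_burst_timeline()`.

Maturation: 21 tracked cisternal maturation events, midpoint-aligned and
averaged:

```r
ev <- simulate_maturation_events(21, kin, seed = 42, noise_sd = 0.02)
ma <- maturation_analysis(ev$traces)
tidy(ma$average) |> filter(role == "cargo", rel_time_s %in% c(-40, 0, 44))
#> # A tibble: 3 × 5
#>   role  rel_time_s  mean     sem     n
#>   <chr>      <dbl> <dbl>   <dbl> <int>
#> 1 cargo        -40 0.999 0.00438    21
#> 2 cargo          0 0.984 0.00408    21
#> 3 cargo         44 0.419 0.00436    21
```

The averaged cargo curve sits at its plateau before the transition midpoint
(rel_time 0) and has fallen to ~0.42 of the plateau 44 s later —
maturation-coupled cargo exit beginning at the midpoint. Running the same
pipeline with `kinetic_config(mode = "gga_null")` leaves the curve ≥ 0.9
throughout: without GGAs the cargo cannot leave the Golgi.
`autoplot(ma$average)` draws the aligned averages with SEM ribbons.

Rendered movies work the same way end to end:

```r
tl <- simulate_timeline(kin, optics_config(), n_cisternae = 2, n_pve = 1, seed = 1)
mv <- render_movie(tl, noise = TRUE)
write_movie(mv, "movie.tiff", truth = tl$truth)   # 16-bit TIFF + JSON sidecar
tr <- extract_traces(mv, mask_role = "pve", measure_roles = "cargo", dilate = 2)
```

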