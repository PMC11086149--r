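# gaitoverlap

Does gait measured in the lab represent gait in the real world? Wearable
running sensors record a gait pattern once per second — running speed
(m/s), step length (m), vertical oscillation (m), stance time (s) and leg
stiffness (kN/m) — so a run is a point cloud in K = 5 dimensions, and the
question becomes one of distributional overlap between a reference cloud
D (e.g. a runner's treadmill session) and a new cloud D\* (their
free-living training).

`gaitoverlap` implements both overlap statistics used for this question,
together with everything around them:

* **Univariate quantile coverage** — per metric, the fraction of D\*
  inside the central 95% interval
  \[q<sub>0.025</sub>(D), q<sub>0.975</sub>(D)\] of the reference
  (linear-interpolation quantiles).
* **Half-space (Tukey) depth overlap** — the depth of d relative to D is
  the smallest fraction of D in any closed half-space containing d; the
  95% depth region of D is everything at least as deep as the
  tie-inclusive 5% quantile of D's self-depths, and the depth overlap is
  the fraction of D\* inside that region. Depth is computed with the
  random-direction approximation (minimum over 1000 random projections of
  the 1-D rank depth min(#{x ≤ d}, #{x ≥ d})/n), validated against an
  exact 2-D rotating-line oracle.
* **Synthetic study generator** — two cohorts of runners with
  within/between-subject multivariate Gaussian structure, treadmill
  speed-ladder sessions (with belt-ramp artifacts), free-living runs with
  AR(1) pace and walking bouts, a configurable in-lab → real-world
  distributional shift (mean, covariance scale, and a correlation
  rotation that reverses the speed–step-length coupling while leaving
  every marginal untouched), and GNSS traces over courses with known
  flat/straight, turn, incline and decline segments plus Gaussian jitter.
* **GNSS segmentation** — heading, turn rate (left positive, central
  differences with angle unwrap) and grade from trackpoints; data-driven
  flat-and-straight thresholds that retain ≥ 99% of a known flat/straight
  calibration segment; bounding-box segment extraction.
* **IO and preprocessing** — GPX 1.1 read/write, delimited gait tables,
  timestamp alignment, walking/standing exclusion (speed < 1.56 m/s or
  cadence < 100 strides/min), treadmill trial trimming (first 25 s, last
  15 s), and the 25% tractability subsample used before depth
  computation.
* **Analysis pipeline** — four subject-wise reference/new-data
  comparisons (own in-lab; leave-one-subject-out pooled in-lab; pooled
  in-lab vs a second cohort; pooled real-world vs a second cohort), each
  under all-terrain and flat/straight-only stratification, aggregated
  with a percentile bootstrap over subjects, plus a metric-subset
  sensitivity analysis.

## A worked example

Simulate a small two-cohort study whose real-world condition reverses the
speed–step-length correlation (a shift invisible to any single metric),
then compare each runner's real-world data against their own in-lab data:

```r
library(gaitoverlap)

cfg <- study_config(n_cohort1 = 5, n_cohort2 = 4, n_real_world_runs = 1,
                    in_lab_duration = 1200, real_world_duration = 900,
                    n_directions = 250, n_bootstrap = 2000,
                    min_subject_points = 50, seed = 42,
                    shift = shift_spec(correlation_rotation = 1))
st <- simulate_study(cfg)
print(st)
#> Synthetic gait study
#>   cohort 1: 5 subjects; cohort 2: 4 subjects
#>   11236 analysis-ready seconds
#> Flat-and-straight segmentation thresholds
#>   |turn rate| <= 6.520 deg/s, |grade| <= 2.858 %
#>   calibration: n = 2404, retained 99.04% (target 99%)
#> Filter report: 14100 in, 524 walking excluded, 2340 trimmed, 11236 out (20.3% excluded)

run_comparison(st, 1)
#> Overlap result (analysis 1, all)
#>                method  mean ci_lower ci_upper n_subjects
#>                 depth 0.510    0.447    0.587          5
#>                 speed 0.974    0.955    0.994          5
#>           step_length 0.989    0.983    0.995          5
#>  vertical_oscillation 0.964    0.954    0.970          5
#>           stance_time 0.978    0.971    0.985          5
#>         leg_stiffness 0.961    0.955    0.967          5
```

Reading the output: the flat/straight thresholds were derived from the
cohort's measured-course runs (retaining 99.04% of the known
flat/straight calibration points); every single-metric overlap sits near
the 95% null, yet the joint five-dimensional depth overlap collapses to
0.51 — the runners' gait *relationships* changed even though no metric's
range did. `run_full_study(cfg)` runs all four comparisons under both
stratifications plus the sensitivity analysis and can write the results
table and a seed log to disk; configs can also be given as YAML files.

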