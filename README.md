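# chirpgait

Multipath-tolerant ultrasonic chirp ranging and wearable gait analysis, in
simulation.

Wearable gait-analysis systems localize a single ultrasonic transmitter on
the lower limb from times of flight to four fixed anchor receivers.
Narrowband 40 kHz transducers leave only ~2 kHz of chirp bandwidth, so the
range resolution of a matched-filter receiver is v/B ≈ 172 mm — and any
indoor echo whose extra path is shorter than that merges with the
direct-path correlation peak and drags it along the time axis. `chirpgait`
implements and evaluates the remedy: **earliest-1/m fractional-peak
detection**, which times the upward crossing of 1/m of the earliest envelope
peak's height P0 instead of the peak itself. Echoes arrive later than the
direct path and corrupt mostly the falling side of the merged lobe, so the
rising-edge crossing is far more stable; its constant early bias cancels in
differential ranges.

The package covers the full chain:

* windowed up/down chirp generation (linear, logarithmic, quadratic sweeps)
  and matched-filter pulse compression with analytic-signal envelopes;
* an acoustic channel simulator: delay, exponential attenuation
  (γ Np/m), multipath superposition, Doppler time-scaling, calibrated AWGN;
* classical peak, earliest-peak and fractional-peak ToA detectors;
* 40 ms up/down-chirp ranging cycles with range–Doppler compensation
  R0 = (R1 + R2)/2 and Doppler-velocity estimation;
* a paired Monte-Carlo study of improvement/degradation vs the classical
  receiver (Iav, Dav, Imax, Dmax, N(I), N(D), R = Iav/Dav), the R-vs-m
  sweep, error ECDFs, and a sweep-law Doppler comparison;
* UKF + unscented RTS smoother localization from four anchors, 10 Hz
  zero-phase Butterworth smoothing;
* spatiotemporal gait parameters per cycle (stride time/length, swing and
  stance time, maximum foot clearance);
* a synthetic gait-trajectory generator with exact ground truth, so the
  whole pipeline runs without recorded data.

## Worked example

A 1 m line-of-sight path with one close echo (extra path 60 mm, reflection
coefficient 0.9) at 10 dB SNR:

```r
library(chirpgait)

tx <- make_chirp(chirp_spec(39e3, 41e3, 7e-3, 125e3))
ch <- channel_spec(1.0, paths = list(path_component(0.06, 0.9)),
                   snr_db = 10)
tr <- matched_filter(propagate(tx, ch, noise_seed = 1), tx)

detect_peak(tr)
#> <toa_estimate> peak: toa 3.00800 ms (peak 17.38 at 3.00800 ms, threshold 17.38)
detect_fractional_peak(tr, toa_config(m = 2))
#> <toa_estimate> fractional_peak: toa 2.63992 ms (peak 17.71 at 2.95351 ms, threshold 8.855)
```

The true arrival is 1/345.3 s = 2.896 ms. The classical peak lands at
3.008 ms — the merged echo shifted it by ~39 mm of range. The half-peak
crossing at 2.640 ms sits a *constant* 0.26 ms before the true arrival (the
envelope's left half-height width); that offset cancels between two
positions, or is removed once by `calibrate_offset()`.

The paired Monte-Carlo comparison (here a small run; the study uses 10,000
iterations):

```r
run <- run_mc(mc_config(n_iter = 500, seed = 1))
mc_metrics_table(run)
#>        window m     i_av     d_av    i_max    d_max n_improve n_degrade    ratio
#> 1 rectangular 2 13.64704 7.008260 46.89145 29.26268       328       172 1.947279
#> 2 rectangular 3 14.11272 7.604907 50.22018 34.39202       339       161 1.855738
#> 3 rectangular 4 14.75994 7.919766 52.09928 41.82763       334       166 1.863684
```

Columns: average/maximum improvement and degradation of the absolute
differential-range error in mm, counts of improving/degrading iterations,
and the headline ratio R = Iav/Dav — about 1.9 at the recommended m = 2
under one unresolvable echo per position.

End-to-end synthetic gait:

```r
sg <- synth_gait_spec(stride_length = 1000, stride_time = 1.2,
                      n_strides = 12, range_noise_std = 5)
gen <- generate_trajectory(sg)
r <- trajectory_to_ranges(gen$trajectory, anchor_array(), sg)
traj <- lowpass(track(r, anchor_array(),
                      state_space_config(
                        process_noise_scale = swing_peak_acceleration(sg))),
                cutoff = 10)
gait_summary(compute_parameters(traj, detect_events(traj)))
```

which recovers the generator's stride length, stride/swing/stance times and
foot clearance to within a few percent.

A thin CLI over the same functions lives at `inst/cli/chirpgait`
(`make-chirp`, `simulate-table1`, `sweep-m`, `ecdf`, `compare-sweeps`,
`synth-gait`, `run-pipeline` with a YAML config).

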