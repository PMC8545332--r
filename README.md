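# facetouch

Offline toolkit for **wrist-worn face-touch detection**. People touch their
face about twenty times an hour, mostly unawares — a problem both for
respiratory-pathogen self-inoculation and for habit disorders treated with
habit-reversal therapy. This package implements and evaluates a
smartwatch-based monitoring pipeline for researchers in wearable sensing and
digital health: two streaming detectors over 100 Hz accelerometer +
magnetometer streams, their calibration procedures, a physics-based
simulator that stands in for the watch and wearer, and the evaluation /
statistics layer for comparing detector variants.

## The algorithms

**Orientation gate.** From the sensed gravity triplet,
roll `θ = atan2(a_y, a_z)·180/π` and pitch
`φ = atan2(−a_x, √(a_y²+a_z²))·180/π`. An orientation is *unsafe*
(face-touch compatible) when strictly inside an empirical box, by default
`−90° < θ < 70°`, `30° < φ < 100°` (right-handed wearer; mirrored for
left-handed).

**Magnetometer detector.** A necklace of five N42 disc magnets creates a
virtual magnetic barrier. While the wrist is safe, the field magnitude
`Φ = √(m_x²+m_y²+m_z²)` feeds a 200-sample ring buffer (rolling mean over
the newest 50, spread over the full buffer). While unsafe the background
freezes, and an alert fires when `|Φ − Φ̄| / σ_Φ > α`. A 5-second two-phase
calibration (2 s far from the magnets, 3 s approaching to ~20 cm) sets
`α = |Φ̂ − Φ̄| / σ_Φ` from the running maximum `Φ̂`.

**Accelerometer-only detector.** For watches without a magnetometer:
per-sample pitch differences above a still-arm threshold `β = 3·σ_φ̇` push
`+1` into a 50-long slope ring (else `−1`); the hand is *rising* when the
ring mean is positive, and the alert is `unsafe AND rising`.

**Evaluation.** Alert runs become events; events shorter than 1 s are Touch
Attempts (TA — gesture aborted in time), longer ones Happened Contacts (HC,
recording the excess over 1 s). Detection metrics score labelled benchmarks;
the statistics layer provides paired t-tests, Shapiro–Wilk gating with
square-root fallback, and noncentral-t post-hoc power.

## Worked example

```r
library(facetouch)

cfg  <- sim_config(seed = 11L)          # 100 Hz, Earth field 45 uT, default noise
neck <- necklace_model()                # 5 magnets, 4.5 cm apart, ~420 uT at 5 cm

## five-second calibration movement, then the two-phase calibration
cal <- mag_calibrate(make_calibration_stream(neck, cfg))
cal
#> Magnetometer calibration: phi_bar = 46.219 uT, sigma_phi = 1.0359 uT,
#>   phi_hat = 60.868 uT, alpha = 14.141 (buffer of 200 samples)

imu_cal <- imu_calibrate(generate_stream(script_rest(), NULL, cfg, seed = 5L))
imu_cal
#> Inertial calibration: beta = 0.5063 deg/sample (3 x sigma_phidot = 3 x 0.1688)

## simulated protocol: 10 face-touches + 10 daily-living confounders
bench <- make_benchmark(10, 10, neck, cfg, seed = 21L)
evaluate_benchmark(bench, new_mag_detector(cal))
#> Detection metrics over 10 face-touch + 10 ADL trials (50.4 s monitored):
#>   correct detections 100.0%   false positives 0.0%
#>   0.0 TA/hour   714.1 HC/hour
evaluate_benchmark(bench, new_imu_detector(imu_cal))
#> Detection metrics over 10 face-touch + 10 ADL trials (50.4 s monitored):
#>   correct detections 100.0%   false positives 80.0%
#>   1285.5 TA/hour   0.0 HC/hour
```

Reading: the calibrated threshold multiplier `alpha ≈ 14` means the
necklace must push the field magnitude about fourteen baseline standard
deviations away before an unsafe-oriented wrist triggers an alert — ambient
noise alone (three sigmas for a Gaussian) stays far below it. On the
benchmark the magnetometer detector catches every simulated face-touch with
no false alarms, while the inertial fallback also catches the touches but
alerts on 80% of eating/drinking/combing gestures: the structural
trade-off that motivates preferring the magnetometer variant whenever the
sensor exists. (Per-hour rates are high only because benchmark streams are
a few seconds long.)

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","facetouch.R",package="facetouch"))')
Rscript $CLI simulate  --seed 1 --out streams/
Rscript $CLI calibrate --algo mag --input streams/calibration_stream.csv --output cal.json
Rscript $CLI detect    --algo mag --calibration cal.json \
                       --input streams/stream_001.csv --output events.log
```

Stream CSVs use the header `t,ax,ay,az,mx,my,mz` (seconds, m/s², μT); the
magnetometer columns may be absent, in which case only the inertial
detector applies.

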