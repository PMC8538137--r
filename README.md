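# imufall

Fall detection from a body-worn network of nine inertial measurement
units (IMUs), for researchers and engineers building wearable safety
systems for workers — firefighters in protective clothing being the
motivating case — where a fall must be recognized from low-rate (15 Hz)
accelerometer/gyroscope/magnetometer streams on the chest, elbows,
wrists, thighs and ankles.

The package implements the complete processing chain as tested R code:

* **Synthetic motion generator** — labeled multi-node recordings of six
  fall types (forward on knees/hands, lateral left/right, backward, slow
  fall with crouch) and three fall-like stressors (crouch, sit, stooped
  walking), built on inverted-pendulum kinematics with articulated
  limbs, random headings and mounting orientations, and realistic
  sensor noise. Only the early-fall phase (trunk rate above 20 deg/s up
  to first ground contact) is labeled positive.
* **Global calibration** — per-node TRIAD rotation into a shared
  north-east-up (NEU) frame from the gravity vector V_acc and magnetic
  vector V_mag, each averaged over the first 1 s (15 samples) of a
  static stance.
* **Orientation** — Mahony AHRS (proportional-integral correction on
  the cross products of measured vs. predicted gravity and magnetic
  directions), yielding per-sample quaternions q = w + xi + yj + zk and
  Z-Y'-X'' Euler angles.
* **Features** — per node, 13 channels × 4 window statistics over
  0.5 s windows hopped by 0.1 s:
  μ = Σx/N, R = max − min, σ = √(Σ(x−μ)²/N), MAD = Σ|x−μ|/N —
  52 features per IMU, 468 for all nine.
* **Classifier** — stacked LSTM (128/32/16 units) + dense-8 ReLU +
  softmax-2, trained with Adam (lr 0.01, batch 10) on sparse
  categorical cross-entropy over sequences of 10 consecutive windows,
  with a trial-level stratified 80/20 split. The LSTM core (forward,
  backpropagation through time, Adam) is implemented in RcppArmadillo
  and verified against finite-difference gradients.
* **Evaluation** — Se = TP/(TP+FN), Sp = TN/(TN+FP),
  Ac = (TP+TN)/total, ROC/AUC, per-activity tables, and the
  sensor-placement ablation over the 30 standard combinations of the
  placement codes C/E/W/T/A.

## Worked example

```r
library(imufall)
recs <- generate_dataset(n_subjects = 4, seed = 7)   # 4 x 35 trials
recs[[1]]
#> <fall_recording> subject 1, activity F1 (fall), trial 1
#>   120 samples at 15 Hz over 9 nodes; 9 fall-labeled samples

features <- pipeline_features(recs)  # calibrate -> AHRS -> window stats
features
#> <feature_matrix> 7980 windows x 468 features (876 fall-labeled)

model <- fall_lstm(features, model_config(epochs = 30,
                                          sequence_stride = 4, seed = 7))
model
#> <fall_lstm> 128-32-16-8-2, 1368 train / 312 test sequences
#>   final training loss 0.0000, accuracy 1.000

evaluate_detector(model)
#> <fall_eval> [CEWTA]  Se 1.0000  Sp 0.9963  Ac 0.9968  AUC 1.0000
#>   activity se     sp     ac  n
#> 1       F1  1 1.0000 1.0000 48
#> 2       F2  1 1.0000 1.0000 48
#> ...
#> 8      FL2  0 1.0000 1.0000 36
#> 9      FL3  0 0.9583 0.9583 24
```

The held-out report reads like the field's standard tables: sensitivity
(fall recall), specificity (non-fall recall) and accuracy overall and
per activity. Fall-like activities contain no true falls, so their
sensitivity is 0 by convention and specificity equals accuracy. On this
small 4-subject run the synthetic classes separate almost perfectly;
the full 14-subject protocol with its harder split lands around 96-99%
held-out accuracy depending on seed, with the residual errors
concentrated in the slow fall F5 and the fall-like stressors — clean
separation on simulated kinematics says nothing about real-world rates,
only that the pipeline's signal path works end to end.

A command-line interface over the same stages (CSV + JSON manifest
formats, YAML configuration) ships in `inst/cli/imufall`:

```sh
Rscript inst/cli/imufall simulate --subjects 2 --trials-per-activity 1 \
    --seed 7 --out raw/
Rscript inst/cli/imufall calibrate --in raw/ --out cal/
Rscript inst/cli/imufall featurize --in cal/ --out features.csv
Rscript inst/cli/imufall train --features features.csv --out model.rds
Rscript inst/cli/imufall evaluate --model model.rds --out eval.json
Rscript inst/cli/imufall ablate --features features.csv \
    --combinations C,CA,CEWTA --out ablation.csv
```

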