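# emgrip

Surface-EMG gesture classification and myoelectric gripper control in R.

`emgrip` implements, end to end, the signal chain of a three-channel
myoelectric prosthesis controller: forearm surface electromyography (sEMG)
sampled at 1 kHz is smoothed, normalized, reduced to time-domain features,
classified by a small multilayer perceptron into one of three muscle tasks
— wrist flexion (class 1), fist (class 2), wrist extension (class 3) — and
the classification, when confident enough, is turned into a motor command
for a virtual two-axis gripper. Because the matching public recordings are
not bundled, the package ships a protocol-driven synthetic sEMG generator
with known ground truth, so every stage is testable offline.

It is aimed at researchers and students in myoelectric control who want a
small, fully reproducible, dependency-light reference pipeline to probe
(window lengths, feature sets, confidence gates) rather than a
deep-learning framework.

## The pipeline

For each analysis window `x` of 2 s (per channel):

1. **RMS envelope** — non-overlapping 50 ms blocks of N samples are each
   reduced to `sqrt(sum(x_n^2) / N)`, smoothing the interference pattern
   while keeping the activation time-course.
2. **Peak-dynamic normalization** — `X_norm = X / X_peak` per channel over
   the window, bounding values to [0, 1].
3. **Features** — either the RMS of four consecutive 500 ms subwindows per
   channel (12 features, the default), or six amplitude statistics per
   channel (MAV, MAV1, MAV2, median |x|, variance, SD).
4. **Classifier** — a five-layer MLP, `dense(32) → dropout(0.2) →
   dense(16) → dropout(0.2) → dense(K)`, softmax output (or a single
   sigmoid unit for the two-class flexion/extension variant), trained with
   Adam (lr 0.001, 300 epochs, batch 8) on a stratified 60/20/20 split.
5. **Gate and actuate** — a prediction is executed only if its confidence
   exceeds 0.70: flexion closes the gripper (+20°), extension opens it
   (−20°), a fist turns the base (+30°).

Evaluation mirrors the original protocol: stratified 10-fold
cross-validation with pooled test predictions, macro-averaged precision
and recall, confusion analysis, a window-duration sweep and an
RMS-vs-statistical feature comparison on shared folds.

## Worked example

```r
library(emgrip)

protocol <- protocol_config()                  # 3 tasks x 10 cues, 5 s + 10 s rest
sched    <- build_schedule(protocol, seed = 1)
gen      <- generator_config(class2_overlap = 0.8, seed = 1)
session  <- synthesize_recording(sched, protocol, gen)
session
#> emg_recording: 450000 samples x (3 EMG + 6 IMU) @ 1000 Hz (450.00 s)

windows <- segment_recording(session, sched, window_duration = 2)
report  <- kfold_cv(windows, k = 10, seed = 1)
report
#> 10-fold CV: accuracy 0.8667, precision 0.8694, recall 0.8667, loss 0.3795
#> confusion (rows = true, cols = predicted):
#>      predicted
#> truth  1  2  3
#>     1 10  0  0
#>     2  2  7  1
#>     3  0  1  9
report$per_class
#>   class precision recall
#> 1     1 0.8333333    1.0
#> 2     2 0.8750000    0.7
#> 3     3 0.9000000    0.9
```

With the fist class's channel-gain pattern mixed 80% toward the
flexion/extension patterns (`class2_overlap = 0.8`), the fist is the
worst-recovered class (recall 0.70 here) while the two wrist tasks stay
high — the confusion structure reported for the real recordings, where the
amputee subject's fist activated nearly the same muscles as the wrist
tasks. At `class2_overlap = 0` the same pipeline reaches ≥ 0.90 accuracy.

Streaming the session through the trained model and the 0.70 gate:

```r
ds  <- feature_dataset(windows)
fit <- train_mlp(build_mlp(ncol(ds$X), classes = ds$levels, seed = 1),
                 ds, training_config(seed = 1, split = c(train = 1)))
log <- stream_classify(session, fit$model, window_duration = 2)
head(subset(log$steps, !is.na(target)), 4)
#>   window time class confidence  target delta_angle gripper_angle base_angle
#> 1      1    0     3  0.9193817 gripper         -20            25         90
#> 2      2    2     3  0.8697844 gripper         -20             5         90
#> 3      3    4     3  0.9948030 gripper         -20             0         90
#> 5      5    8     2  0.7140596    base          30             0        120
```

Each row is one 2 s decision: the predicted class, its confidence, the
motor command it mapped to (rows whose confidence fell below the gate emit
none) and the gripper/base angles after applying it.

## Command line

A launcher is installed at `inst/exec/emgrip`; the same entry point is
callable as `emgrip_main()`:

```sh
Rscript inst/exec/emgrip generate --out data/ --seed 7
Rscript inst/exec/emgrip evaluate --data data/ --out report/ --seed 7
Rscript inst/exec/emgrip train --data data/ --out model.json --seed 7
Rscript inst/exec/emgrip stream --recording data/class1_t01.csv \
    --model model.json --out decisions.csv
```

Every artifact-producing run writes a JSON config echo and a log beside
its outputs.

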