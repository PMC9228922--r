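# skelact

Frame-wise human action recognition from 2D skeleton streams, with a
rule-based crisis-behaviour layer for surveillance analysis.

`skelact` is aimed at researchers building video-surveillance behaviour
analysis — in particular early detection of crisis behaviours that precede
suicide attempts at monitored public sites. It consumes the output of an
upstream detection / tracking / pose-estimation stack (per-frame 2D
keypoints with track IDs and boxes) and provides everything downstream:
feature extraction, window classification, action tubes, crisis alerts and
evaluation, plus a synthetic skeleton-motion generator so the entire
pipeline can be exercised and tested without any video data.

## The model

Each tracked person's pose at frame *t* is a set of 18 joints (BODY-18
layout; COCO-17 input is accepted and the neck synthesised from the
shoulders). Skeletons are canonicalised: coordinates are divided by the
image width, eyes/ears dropped (14 joints remain), the neck made the
origin, and everything divided by the body height *h* = ‖neck − hip
midpoint‖. From the canonical skeleton three feature families are
extracted per frame:

* **static** (28-d): the 14 canonical (x, y) coordinates;
* **motion** (68-d): 28 joint velocities in body coordinates, plus the
  2-d body (neck) velocity and the 2-d tracked-box velocity, each
  replicated 10× to up-weight whole-body movement;
* **geometric** (62-d): 13 limb orientations atan2(Δy, Δx), 13 limb
  lengths, 13 inner angles at adjacent-joint triples, 13 long lengths
  (outer-joint distances of those triples) and 10 end-joint pairwise
  distances (nose, wrists, ankles).

A frame is classified from the 30-frame window centred on it (14 before,
15 after). Branch A consumes the 30×96 static‖motion sequence, branch B the
30×62 geometric sequence; each branch is a fully connected layer, two
stacked LSTM layers (standard gates

f_t = σ(W_f·[h_{t−1}, x_t] + b_f),  i_t, o_t analogous,
c_t = f_t ⊙ c_{t−1} + i_t ⊙ tanh(W_c·[h_{t−1}, x_t] + b_c),
h_t = o_t ⊙ tanh(c_t)

) and a final fully connected + softmax layer on the last time step.
Branches are trained with Adam (batch 32), weighted cross-entropy
(inverse class-frequency weights) and a halve-the-learning-rate schedule.
Scores are fused by element-wise multiplication followed by softmax; when
branch A's validation accuracy exceeds branch B's by more than 20
percentage points, branch A is used alone. Frames whose best combined
probability falls below a confidence floor are left unlabelled ("void").

The logic layer merges consecutive same-label frames (bridging short void
gaps) into action tubes, counts each tube once, and raises three kinds of
crisis alert: unit actions (Crouch, LeanHead, Place), long-duration
Sit or Lean/Stand spans (threshold 100 s), and repetitive mixed-action
patterns that include Sit or Walk. Evaluation covers frame-wise
classification metrics, temporal-detection AP/mAP over IoU thresholds, and
clip-level crisis identification. A companion grouping module classifies
tracked pedestrians into groups vs singletons from pairwise
distance/velocity/scale similarity.

## Worked example

Simulate a scripted scenario, train the recognizer on generator output, and
run recognition plus the logic layer end to end:

```r
library(skelact)

script <- data.frame(class   = c("Walk", "Stand", "Crouch", "Walk", "Sit"),
                     start_s = c(0, 6, 12, 15, 21),
                     end_s   = c(6, 12, 15, 21, 27))
res <- run_pipeline(script, out_dir = "out",
                    classes = c("Crouch", "Sit", "Stand", "Walk"),
                    windows_per_class = 60, seed = 1)
print(res$model)
#> Two-branch skeleton action recognizer
#>   classes: Crouch, Sit, Stand, Walk
#>   branch A (static+motion, 96-d): validation accuracy 100.00%
#>   branch B (geometric, 62-d):     validation accuracy 100.00%
#>   fusion policy: fuse (gap 0.00, threshold 20)
#>   confidence floor: 0.50

res$tubes[, c("label", "start_s", "end_s", "score")]
#>    label start_s end_s score
#> 1   Walk     0.0  5.93 0.718
#> 2  Stand     6.2 11.83 0.624
#> 3 Crouch    12.1 15.00 0.881
#> 4   Walk    15.1 20.83 0.719
#> 5    Sit    21.1 26.97 0.737

res$alerts$description
#> [1] "'Crouch' at timepoint 12.07 s"
```

The recovered tubes match the script (five tubes, frame accuracy 0.970
against the scripted ground truth, temporal-detection mAP@0.5 of 100 on
this clip), and the crouch — a unit crisis indicator — raises an alert at
its start time. `out/` now contains the pose stream (JSONL), the frame
timeline (CSV), tubes/alerts (JSON), the per-class action-graph segments
and the AP grid.

A thin command-line wrapper with `simulate`, `extract`, `train`,
`predict`, `analyze`, `evaluate` and `pipeline` subcommands is installed at
`inst/cli/skelact.R`.

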