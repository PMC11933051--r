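# pestnet

Lightweight, re-parameterizable object-detection networks for forestry pest
imagery, in R.

Monitoring forestry pests needs detectors that fit on small devices: many
visually similar classes, small dense targets, and hard budgets on
parameters, FLOPs and weight size. `pestnet` implements a family of
anchor-free detectors around a YOLOv8-nano-style baseline for 29 pest
classes, plus the tooling to make them light and to measure them:

* **Building blocks** — HGStem, re-parameterizable `RepConv`/`RepLightConv`
  (train as 3x3 + 1x1 + identity-BN branches, fuse to one 3x3 conv for
  inference), dense-aggregation Rep-HGBlocks, GSConv / GSbottleneck /
  VoVGSCSP slim-neck modules, and a dynamic detection-head tower with
  scale-, spatial- and task-aware attention:
  - scale: `pi_L(F) . F = sigma(f(mean_{S,C} F)) . F`, hard sigmoid
    `sigma(x) = max(0, min(1, (x+1)/2))`
  - spatial: `pi_S(F) . F = (1/L) sum_l sum_k w_{l,k} F(l; p_k + dp_k; c) dm_k`
  - task: `pi_C(F) . F = max(alpha1 F_c + beta1, alpha2 F_c + beta2)`
* **Structural re-parameterization** — exact BN folding
  (`w' = w gamma / sqrt(var + eps)`, `b' = beta - mu gamma / sqrt(var + eps)`),
  1x1-to-3x3 lifting, Dirac identity kernels, whole-model fusion with
  equivalence reports.
* **LAMP channel pruning** — layer-adaptive magnitude scores
  `score(u; W) = W[u]^2 / sum_{v >= u} W[v]^2` on ascending-sorted
  magnitudes, per-channel aggregation, coupled-group tracing through
  concat/add/shuffle/depthwise junctions, and a greedy global plan to a
  FLOPs speed-up target (`speed_up = FLOPs_before / FLOPs_after`).
* **Metrics** — precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, AP as the area
  under the precision-recall envelope, mAP@0.5:0.95 over the IoU grid
  0.50:0.05:0.95, confusion matrices.
* **Synthetic data** — a deterministic 29-class pest-scene generator with
  YOLO-format labels and 7:2:1 splits, standing in for the undeposited
  forestry-pest dataset.
* **Training** — a CPU smoke-scale harness (task-aligned assignment,
  CIoU + BCE + distribution-focal loss with hand-derived gradients, SGD with
  warmup and mosaic-off-at-the-end scheduling).

The network engine is a flat DAG of primitive layers with forward and
backward passes in R and C++ (RcppArmadillo); no deep-learning framework is
required.

## Worked example

```r
library(pestnet)

# the baseline and the improved full model, for 29 classes
base <- build_model(model_config("baseline", nc = 29), seed = 0)
rsd  <- build_model(model_config("rsd", nc = 29), seed = 0)

count_params(base) / 1e6   # 3.016487
count_flops(base, 640)     # 8.11 GFLOPs
count_params(rsd) / 1e6    # 2.578017
count_flops(rsd, 640)      # 7.61 GFLOPs

# fuse the multi-branch blocks for inference (exact; report verifies it)
f <- reparameterize_model(rsd, n_probes = 2, img_size = 96)
f$report$max_abs_diff      # ~1.8e-15
count_params(f$net) / 1e6  # 2.565153

# LAMP channel pruning to a 1.5x FLOPs speed-up
plan <- plan_pruning(rsd, speed_up = 1.5, img_size = 640)
plan                       # GFLOPs 7.61 -> 5.02 (x1.51, target x1.50)
pruned <- apply_pruning(rsd, plan)
count_flops(pruned, 640)   # 5.02 GFLOPs

# synthetic scenes with YOLO labels
man <- generate_dataset(64, scene_spec(img_size = 160, preset = "easy",
                                       seed = 0), "data")
table(man$split)           # test 13, train 45, val 6
```

The parameter counts and FLOPs printed above reproduce the family's
published accounting: baseline 3.01 M / 8.1 G; backbone swap 2.34 M;
slim neck 2.80 M; head addition 3.49 M; full model 2.61 M / 7.6 G; pruned
full model at 1.5x below 5.2 G (all parameter totals within about 1%).

A thin command-line front end ships in `inst/cli/pestnet`
(`build`, `shapes`, `analyze`, `reparam`, `prune`, `synth`, `train-smoke`,
`eval`).

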