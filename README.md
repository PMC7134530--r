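# mvttseg

Joint segmentation of the left atrium and atrial scar from 3D late gadolinium
enhanced (LGE) cardiac MR, with a multiview two-task (MVTT) recursive attention
network — plus a synthetic phantom generator, unsupervised scar baselines, and
the full evaluation/agreement panel, so the whole pipeline runs and is tested
without any clinical data.

## The problem and the model

LGE CMR nulls healthy myocardium and enhances fibrosis, so atrial scar appears
as small bright patches in a ~2.25 mm thin atrial wall whose boundaries are
themselves hard to see. Stratifying atrial-fibrillation patients needs both the
left-atrium (LA) anatomy (endocardial cavity + proximal pulmonary veins) and the
scar, segmented from the same volume.

The MVTT model processes a volume as ordered 2D slice stacks along the three
orthogonal views:

* an axial **sequence-learning subnetwork** — per-slice convolutional encoders
  feeding a convolutional LSTM with ReLU state activation and Hadamard peephole
  weights:
  `f_t = σ(Wxf∗x_t + Whf∗h_(t−1) + Wcf∘c_(t−1) + bf)`, `i_t` analogous,
  `c_t = f_t∘c_(t−1) + i_t∘ReLU(Wxc∗x_t + Whc∗h_(t−1) + bc)`,
  `o_t = σ(Wxo∗x_t + Who∗h_(t−1) + Wco∘c_t + bo)`, `h_t = o_t∘ReLU(c_t)`;
* sagittal and coronal **dilated residual subnetworks** built from hybrid
  dilated convolution (HDC) blocks with rate cycle (1, 2, 5);
* **multiview fusion** `Fv = Fa + T(Fc) + T(Fs)`, `T` the exact axis
  permutation onto axial ordering;
* a **dilated attention network** producing a sigmoid mask `AM ∈ (0,1)` from
  the raw axial slices, gating the scar branch by `O = (1 + AM) ∘ Fv`;
* two task heads (two 3×3 conv(16)+BN+ReLU layers, 32-channel concatenation,
  final 3×3 — anatomy — or 1×1 — scar — convolution + sigmoid), trained with
  the hybrid soft Dice loss `L = δ(m_l, g_l) + δ(m_as, g_as)`.

Every published model variant (single-view, no ConvLSTM, no attention,
single-task, 5×5 kernels, tanh activation, undilated convolutions) is a
configuration switch. Training uses Adam with the decayed schedule
`lr = 0.001 · 0.98^epoch`, early stopping, and k-fold splitting utilities.
Scar burden is quantified as the percentage of the atrial wall compartment
(fixed 2.25 mm wall) occupied by scar, with Pearson and Bland–Altman agreement
statistics. The unsupervised comparators (2-SD thresholding, k-means, fuzzy
c-means over wall intensities) are included.

There is no deep-learning framework underneath: the network, its reverse-mode
gradients and the optimizer are implemented in this package (R plus compiled
convolution kernels).

## Worked example

```r
library(mvttseg)

# a 40-phantom synthetic LGE-like cohort: 48^3 voxels at 1.25 mm, ellipsoidal
# atrium + pulmonary-vein tubes, ~10% scar burden in a 2.25 mm wall shell
cohort <- generateCohort(phantomSpec(), 40, seed = 100)

fit <- trainMVTT(mvttConfig(), cohort,
                 trainConfig(maxEpochs = 4, seed = 1), valIdx = 35:40)
tail(fit$history, 1)
#>   epoch          lr train_loss  val_loss val_dice_anatomy val_dice_scar
#> 4     3 0.000941192  0.5677955 0.4947651        0.9621176      0.812961

# segment a held-out phantom and quantify its scar burden
s <- cohort[[35]]
out <- predictVolume(fit$model, s@image)
scarPercentage(binarizeProb(out@scarProb), s@anatomy)   # estimated, %
#> [1] 8.483755
100 * trueScarFraction(s)                               # ground truth, %
#> [1] 9.819495

# unsupervised 2-SD baseline on the same wall shell
ws <- wallIntensitySample(s@image, s@anatomy)
segmentationMetrics(confusionCounts(twoSDThreshold(ws), s@scar))$dice
#> [1] 0.6562054
```

After four epochs on one CPU the trained model reaches held-out anatomy Dice
≈ 0.96 and scar Dice ≈ 0.81 on this synthetic cohort, while 2-SD thresholding
sits near 0.66: the phantom's scattered scar-like noise interference in the
wall is indistinguishable from true scar by intensity alone, so rules without
spatial context over-call it — the qualitative ordering reported for the
clinical comparison.

A thin command-line dispatcher ships at `inst/cli/mvttseg.R`
(`generate`, `train`, `predict`, `evaluate`, `ablate` subcommands, YAML
configs, NIfTI/NRRD volumes, CSV/JSON reports and run manifests).

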