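# mvdenoise

Unpaired multi-view low-dose CT denoising by knowledge transfer, in R.

## The problem

Low-dose CT (LDCT) images carry strong quantum noise and streak
artefacts, and the paired low/high-dose scans that supervised denoisers
need are rarely obtainable in practice. `mvdenoise` implements a
two-stage framework that learns from **unpaired** low- and high-dose 3D
volumes and exploits all three anatomical views:

1. **Stage 1 — multi-view teachers.** The unpaired volumes are split
   into axial, sagittal and coronal 2D slice pools, and one
   CycleGAN-style translation model is trained per view: generators
   `G_xy` (low→high) and `G_yx`, two PatchGAN discriminators,
   least-squares adversarial losses and an L1 cycle-consistency loss
   weighted by λ = 10. Denoising a volume along each view, restacking,
   and re-splitting axially yields three *view-complementary
   predictions* per axial slice.
2. **Fusion.** The three predictions are fused per pixel by
   *cycle-consistency weighting*: each prediction is mapped back to the
   input domain with the student's current inverse generator, its
   absolute reconstruction error `diff_v` is computed, and with
   `Diff = diff_a + diff_s + diff_c` the weights are
   `w_s = (diff_a + diff_c) / (2 Diff)`,
   `w_c = (diff_a + diff_s) / (2 Diff)`, `w_a = 1 − w_s − w_c` — the
   most cycle-consistent view gets the largest weight. The fused image
   is a per-pixel convex combination of the three predictions.
3. **Stage 2 — single-view student.** An axial-view student (RED-CNN
   generators) trains on the unpaired axial pools with an added
   pseudo-supervised L1 term toward the fused pseudo-targets,
   `L = 1·GAN + 10·cycle + 5·pseudo`. Inference needs only the
   student's `G_xy` — one 2D network per axial slice.

The package also ships a synthetic-data module (anisotropic CT phantoms;
projection-domain Poisson noise via a parallel-beam radon transform and
filtered back-projection), a compact CPU neural-network engine
(im2col/GEMM convolutions, transposed convolutions, instance
normalisation, tape-based autodiff, Adam) built on RcppArmadillo, and
PSNR / SSIM / RMAE evaluation utilities.

## Worked example

```r
library(mvdenoise)

# a tiny synthetic world: 3 phantoms, quarter-dose projection noise
hd <- lapply(1:3, function(i)
  generate_phantom(phantom_spec(shape = c(16, 48, 48), seed = i)))
ld <- lapply(1:3, function(i)
  simulate_low_dose(hd[[i]], dose_spec(dose_factor = 0.25, seed = 100 + i)))

# unpaired axial pools (pairing destroyed by shuffling)
ds <- build_unpaired_dataset(ld[1:2], hd[1:2], "axial", shuffle_seed = 1)
ds
#> <unpaired axial dataset: 32 low-dose / 32 high-dose slices>

# a tiny view model, briefly trained
cfg <- stage1_config(patch_size = 24, batch_size = 2,
                     patches_per_iteration = 2, epochs = 1,
                     learning_rate = 1e-3, iters_per_epoch = 10, seed = 7)
m <- train_view_model(ds, cfg,
                      generator_spec("rescnn", base_channels = c(4, 8, 16),
                                     n_residual_blocks = 1,
                                     global_skip = TRUE,
                                     out_init_gain = 0.1),
                      discriminator_spec(2, 8))
round(tail(m$history, 1), 4)
#>    iter  cycle  gan_g  gan_d  total
#> 10   10 0.1158 0.6757 1.0257 1.8333

# held-out evaluation: per-slice PSNR / SSIM / RMAE vs the paired truth
res <- evaluate_testset(m, list(list(low = ld[[3]], high = hd[[3]])))
res$summary
#>   metric       mean          sd
#> 1   psnr 27.1294617  0.45791587
#> 2   ssim  0.5999562  0.04907548
#> 3   rmae 26.8164056 28.29034331
```

(`cycle` is the L1 cycle-consistency loss, `gan_g`/`gan_d` the LSGAN
generator/discriminator losses, `total` the λ-weighted stage-1
objective; the summary rows are mean ± SD over held-out axial slices.)

The full scaled-down pipeline — three teachers, fusion, student — is one
call:

```r
r <- desk_experiment(seed = 1, verbose = TRUE)   # ~7 min on one CPU
r$psnr   # input / axial / sagittal / coronal / baseline / student, dB
```

A command-line interface covers simulation, training, fusion inspection,
denoising and evaluation; see `exec/mvdenoise` and `?mv_cli`.

## Scope

Desk-scale verification on synthetic phantoms only: reference-scale
training (512×512 clinical volumes, 100 GPU-epochs) and the published
quantitative results are explicitly out of scope. See
`vignettes/methods.Rmd` for the model, the synthetic-world assumptions,
and every numerical design choice.
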