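# hffen — high-frequency feature enhancement for plant image super-resolution

`hffen` is an R implementation of a single-image super-resolution (SR)
network for plant imagery with an explicit, plug-and-play high-frequency
pathway, plus the complete experimental protocol around it. It is aimed at
plant-science image analysts who care about the thin, branching structures
that generic SR models over-smooth — leaf venation, 1–2 px lesion rims,
serrated margins, frond edges — and at method developers who want a fully
inspectable, dependency-light reference of this architecture family
(the network, backprop and training loop are implemented from first
principles in R/Rcpp; no deep-learning framework is required).

## The model

For a low-resolution RGB image `I_LR` (normalised to [0,1]):

```
F0   = Conv3x3(I_LR)                          shallow feature extraction
F_n  = F_SR + F_HF,        n = 1..N           cascaded modules
         F_SR = Backbone(F_{n-1})             EDSR-style residual stack
         F_HF = HA( R( L * F_{n-1} ) )        the HF-FE branch
F_D  = Conv3x3(F_N)                           aggregation
I_SR = Upsample(F_D + F0)                     global skip + pixel shuffle
```

where `L` is a **fixed** (never trained) depthwise Laplacian stencil that
passes only edge/texture content, `R` is a stack of residual blocks, and
`HA` is a hybrid attention unit: windowed multi-head self-attention and
squeeze-and-excitation channel gating in parallel,
`HA(x) = MLP(Norm(MSA(x) + CA(x)))`. The branch attaches to any
shape-preserving backbone (`register_backbone()`), and disabling it yields
*exactly* the bare backbone cascade — the testable meaning of plug-and-play.

Around the network, the package implements the full protocol: seeded 80/20
splits with a test-leakage audit, random HR patch extraction with dihedral
augmentation, bicubic (Catmull-Rom, antialiased) degradation at ×2/×3/×4,
L1/Adam training with a step-halving LR schedule and gradient-norm clipping
(seeded, checkpointed, bit-for-bit resumable), Y-channel PSNR/SSIM
evaluation, an analytic parameter/FLOPs counter, an ablation harness, and a
procedural generator of venation/lesion/serration-rich synthetic leaves so
that everything runs with zero downloads.

## Worked example

Train a desk-scale ×2 model on synthetic leaves and compare it with plain
bicubic upsampling on the held-out split (about three CPU-minutes):

```r
library(hffen)
imgs <- synth_images(50, base_seed = 1)          # 50 procedural leaves, 96 px
man  <- split_dataset(names(imgs), seed = 1)     # seeded 80/20 split
cfg  <- hffen_profile(2, "mini")                 # x2 model, desk-scale size
net  <- hffen_net(cfg, seed = 1, init = "sr")
print(net)
#> HFFEN network
#>   scale x2, channels 16, modules 2, backbone resstack(2 blocks)
#>   HF-FE: on (HIEM on depth 2 lap4, HA on heads=4 window=8)
#>   parameters: 54,085
tcfg <- train_config(2, "mini", seed = 1)
fit  <- train_hffen(net, imgs, man, tcfg)        # 400 iterations
evaluate_sr("bicubic", imgs, man$test_ids, scale = 2)
#> x2 SR evaluation over 10 images (Y bt601, border 2)
#>   mean PSNR 30.936 dB, mean SSIM 0.8400
evaluate_sr(fit$net, imgs, man$test_ids, scale = 2)
#> x2 SR evaluation over 10 images (Y bt601, border 2)
#>   mean PSNR 31.934 dB, mean SSIM 0.8910
```

The trained model beats bicubic by ~1 dB Y-PSNR on this synthetic cohort.
PSNR/SSIM are computed on the luma channel (BT.601 studio range by
default), with a `scale`-pixel border crop — the conventions are embedded
in every report, because cross-implementation comparability hinges on them.

The analytic complexity of the reference (paper-scale) architecture, and
the cost of the plug-in branch:

```r
ov <- hf_fe_overhead(hffen_profile(2, "paper"), c(192, 192))
ov$flops_overhead     # ~0.077: the full HF-FE branch adds < 10% multiply-adds
```

`run_ablation()` trains the `baseline` / `+HIEM` / `+HA` / `+HIEM+HA`
variants under one shared batch schedule and initialisation seed and emits
a table of per-variant PSNR/SSIM/params/FLOPs.

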