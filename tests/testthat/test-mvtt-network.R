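test_that("multiview fusion reduces to its closed forms", {
    set.seed(20)
    n <- 4L
    Fa <- array(rnorm(n^3 * 2), dim = c(n, n, 2, n))
    zero <- array(0, dim = c(n, n, 2, n))
    # zero complements: Fv = Fa
    expect_equal(fuseViews(Fa, zero, zero), Fa)
    # zero axial, equal complements v: Fv is the sum of the two transpositions;
    # for a volume's own identity features both transpositions agree, so Fv = 2 T(v)
    v <- array(rnorm(n^3 * 2), dim = c(n, n, 2, n))
    expect_equal(fuseViews(zero, v, v),
                 transposeToAxial(v, "sagittal") + transposeToAxial(v, "coronal"))
    set.seed(22)
    vol <- array(rnorm(n^3), dim = c(n, n, n))
    vd <- decomposeViews(vol)
    expect_equal(fuseViews(vd@axial * 0, vd@sagittal, vd@coronal),
                 2 * transposeToAxial(vd@sagittal, "sagittal"))
    expect_error(fuseViews(Fa, array(0, dim = c(n, n, 2, n + 1)), zero), "shape|cubic")
})

test_that("fusion of identity features is permutation-equivariant", {
    # with identity (intensity) features, Fv = 3 x axial stack of the volume;
    # permuting the volume's voxel values permutes Fv identically (3^3 grid)
    set.seed(21)
    v <- array(rnorm(27), dim = c(3, 3, 3))
    fuse_vol <- function(vol) {
        vd <- decomposeViews(vol)
        fuseViews(vd@axial, vd@sagittal, vd@coronal)
    }
    f1 <- fuse_vol(v)
    expect_equal(f1, 3 * decomposeViews(v)@axial)
    perm <- sample(27)
    vp <- array(as.vector(v)[perm], dim = c(3, 3, 3))
    f2 <- fuse_vol(vp)
    expect_equal(f2, 3 * decomposeViews(vp)@axial)
})

test_that("a zero-head model emits uniform 0.5 probability maps", {
    cfg <- tiny_mvtt_config(8L)
    m <- mvttModel(cfg, seed = 1, zeroHead = TRUE)
    vox <- array(rnorm(8^3), dim = c(8, 8, 8))
    fw <- mvttForward(m, vox, mode = "infer")
    expect_equal(as.vector(fw$anatomy$value), rep(0.5, 8^3))
    expect_equal(as.vector(fw$scar$value), rep(0.5, 8^3))
})

test_that("heads concatenate 16+16 kernels into a 32-channel input", {
    cfg <- mvttConfig(cubeEdge = 8L, baseChannels = 2L)
    m <- mvttModel(cfg, seed = 2)
    expect_identical(dim(m$par[["head_l3.W"]]$value)[3], 32L)
    expect_identical(dim(m$par[["head_s3.W"]]$value)[3], 32L)
    # scar head's final kernel is 1x1: no spatial mixing in the last layer
    expect_identical(dim(m$par[["head_s3.W"]]$value)[1:2], c(1L, 1L))
    # anatomy head's final kernel is spatial (3x3 by default)
    expect_identical(dim(m$par[["head_l3.W"]]$value)[1:2], c(3L, 3L))

    # the split application of the stored 32-channel kernel equals convolving
    # the explicit channel concatenation
    ns <- asNamespace("mvttseg")
    set.seed(3)
    h1 <- array(rnorm(8 * 8 * 16 * 2), dim = c(8, 8, 16, 2))
    h2 <- array(rnorm(8 * 8 * 16 * 2), dim = c(8, 8, 16, 2))
    w <- m$par[["head_s3.W"]]$value
    cat12 <- array(0, dim = c(8, 8, 32, 2))
    cat12[, , 1:16, ] <- h1; cat12[, , 17:32, ] <- h2
    full <- ns$.conv2d_fwd(cat12, w, 1L)
    split <- ns$.conv2d_fwd(h1, w[, , 1:16, , drop = FALSE], 1L) +
             ns$.conv2d_fwd(h2, w[, , 17:32, , drop = FALSE], 1L)
    expect_equal(split, full, tolerance = 1e-12)
})

test_that("a 1x1 final kernel has single-voxel impulse support", {
    ns <- asNamespace("mvttseg")
    set.seed(4)
    w <- array(rnorm(32), dim = c(1, 1, 32, 1))
    x <- array(0, dim = c(9, 9, 32, 1))
    x[5, 4, , 1] <- rnorm(32)
    y <- ns$.conv2d_fwd(x, w, 1L)
    nz <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
    expect_identical(nrow(nz), 1L)
    expect_identical(as.integer(nz), c(5L, 4L))
})

test_that("forward pass honours its output contract and is deterministic", {
    cfg <- tiny_mvtt_config(8L)
    m <- mvttModel(cfg, seed = 5)
    set.seed(6)
    vox <- array(rnorm(8^3), dim = c(8, 8, 8))
    fw1 <- mvttForward(m, vox, mode = "infer")
    expect_identical(dim(fw1$anatomy$value), c(8L, 8L, 1L, 8L))
    expect_identical(dim(fw1$scar$value), c(8L, 8L, 1L, 8L))
    expect_true(all(fw1$anatomy$value > 0 & fw1$anatomy$value < 1))
    expect_true(all(fw1$scar$value > 0 & fw1$scar$value < 1))
    fw2 <- mvttForward(m, vox, mode = "infer")
    expect_identical(fw1$anatomy$value, fw2$anatomy$value)
    expect_identical(fw1$scar$value, fw2$scar$value)
    expect_error(mvttForward(m, array(0, dim = c(8, 8, 9))), "cubic|48|8")
})

test_that("disabling attention reduces the scar branch input to Fv exactly", {
    cfg <- tiny_mvtt_config(8L, useAttention = FALSE)
    m <- mvttModel(cfg, seed = 7)
    vox <- array(rnorm(8^3), dim = c(8, 8, 8))
    fw <- mvttForward(m, vox, mode = "infer", returnFeatures = TRUE)
    expect_identical(fw$O$value, fw$Fv$value)
    expect_null(fw$AM)
    expect_false("theta_am" %in% names(parameterGroups(m)))
    # attention masks, when enabled, lie strictly in (0,1)
    m2 <- mvttModel(tiny_mvtt_config(8L), seed = 7)
    fw2 <- mvttForward(m2, vox, mode = "infer", returnFeatures = TRUE)
    expect_true(all(fw2$AM$value > 0 & fw2$AM$value < 1))
    expect_equal(fw2$O$value, (1 + fw2$AM$value) * fw2$Fv$value, tolerance = 1e-12)
})

test_that("every ablation flag changes the parameter registry as documented", {
    base <- mvttModel(tiny_mvtt_config(8L), seed = 1)
    g0 <- names(parameterGroups(base))
    expect_setequal(g0, c("theta_a", "theta_s", "theta_c", "theta_am",
                          "theta_l", "theta_as"))

    no_mv <- mvttModel(tiny_mvtt_config(8L, useMultiview = FALSE), seed = 1)
    expect_false(any(c("theta_s", "theta_c") %in% names(parameterGroups(no_mv))))

    no_at <- mvttModel(tiny_mvtt_config(8L, useAttention = FALSE), seed = 1)
    expect_false("theta_am" %in% names(parameterGroups(no_at)))
    expect_lt(mvttParameterCount(no_at), mvttParameterCount(base))

    no_cl <- mvttModel(tiny_mvtt_config(8L, useConvLSTM = FALSE), seed = 1)
    expect_false(any(grepl("clstm", names(mvttParameters(no_cl)))))

    s_la <- mvttModel(tiny_mvtt_config(8L, tasks = "anatomy_only"), seed = 1)
    expect_false("theta_as" %in% names(parameterGroups(s_la)))
    s_sc <- mvttModel(tiny_mvtt_config(8L, tasks = "scar_only"), seed = 1)
    expect_false("theta_l" %in% names(parameterGroups(s_sc)))

    k5 <- mvttModel(tiny_mvtt_config(8L, kernelSize = 5L), seed = 1)
    expect_identical(dim(mvttParameters(k5)[["enc_a1.W"]]$value)[1:2], c(5L, 5L))
})

test_that("soft Dice loss matches its closed forms", {
    g <- array(rbinom(64, 1, 0.4), dim = c(4, 4, 4))
    expect_equal(diceLoss(g, g), 0)                      # perfect (eps cancels)
    m <- 1 - g                                           # disjoint supports
    expect_gt(diceLoss(m, g), 1 - 2 / sum(m + g))
    half <- array(rep(c(0, 1), 32), dim = c(4, 4, 4))
    expect_equal(diceLoss(array(0.5, dim = c(4, 4, 4)), half, eps = 0), 0.5)
    expect_error(diceLoss(array(0.5, c(2, 2)), array(0.7, c(2, 2))), "binary")
    expect_error(diceLoss(array(0.5, c(2, 2)), array(1, c(3, 2))), "shape")
})

test_that("the hybrid loss is the exact sum of the two task losses", {
    set.seed(8)
    ml <- array(runif(64), dim = c(4, 4, 4))
    mas <- array(runif(64), dim = c(4, 4, 4))
    gl <- array(rbinom(64, 1, 0.5), dim = c(4, 4, 4))
    gas <- array(rbinom(64, 1, 0.1), dim = c(4, 4, 4))
    expect_equal(hybridLoss(ml, mas, gl, gas),
                 diceLoss(ml, gl) + diceLoss(mas, gas))
    expect_equal(hybridLoss(gl, gas, gl, gas), 0)
    # anatomy perfect, scar disjoint: loss approaches 1
    expect_gt(hybridLoss(gl, 1 - gas, gl, gas), 0.9)
    expect_error(hybridLoss(NULL, mas, gl, gas), "both task")
})

test_that("both task losses propagate gradients into the shared subnetworks", {
    ns <- asNamespace("mvttseg")
    cfg <- tiny_mvtt_config(8L)
    m <- mvttModel(cfg, seed = 9)
    set.seed(10)
    vox <- array(rnorm(8^3), dim = c(8, 8, 8))
    gl <- array(rbinom(8^3, 1, 0.4), dim = c(8, 8, 1, 8))
    gas <- array(rbinom(8^3, 1, 0.1), dim = c(8, 8, 1, 8))
    shared <- unlist(parameterGroups(m)[c("theta_a", "theta_s", "theta_c")])
    for (task in c("anatomy", "scar")) {
        ns$ad_zero_grad(m$par)
        fw <- mvttForward(m, vox, mode = "train")
        loss <- if (task == "anatomy") ns$ad_dice(fw$anatomy, gl)
                else ns$ad_dice(fw$scar, gas)
        ns$ad_backward(loss)
        gnorm <- vapply(shared, function(nm) {
            g <- m$par[[nm]]$grad
            if (is.null(g)) 0 else max(abs(g))
        }, numeric(1))
        expect_true(all(gnorm > 0),
                    info = paste(task, "loss reaches all shared parameters"))
    }
})

test_that("loss is invariant to consistent in-plane permutation with 1x1 kernels", {
    ns <- asNamespace("mvttseg")
    cfg <- tiny_mvtt_config(8L, kernelSize = 1L)
    m <- mvttModel(cfg, seed = 11)
    # the ConvLSTM peephole weights are per-location by design and are the one
    # deliberately position-dependent component; zero them so the remaining
    # (1x1-convolutional + per-channel BN) computation is permutation-covariant
    for (nm in c("clstm.Wcf", "clstm.Wci", "clstm.Wco")) m$par[[nm]]$value[] <- 0
    set.seed(12)
    vox <- array(rnorm(8^3), dim = c(8, 8, 8))
    gl <- array(rbinom(8^3, 1, 0.4), dim = c(8, 8, 1, 8))
    gas <- array(rbinom(8^3, 1, 0.1), dim = c(8, 8, 1, 8))
    loss0 <- ns$ad_add(ns$ad_dice(mvttForward(m, vox, "train")$anatomy, gl),
                       ns$ad_dice(mvttForward(m, vox, "train")$scar, gas))$value
    # one in-plane (y, x) permutation applied to every axial slice of inputs
    # and targets alike
    p <- sample(64)
    permute_plane <- function(a3) {  # (z, y, x) volume
        for (k in 1:8) {
            pl <- a3[k, , ]
            a3[k, , ] <- matrix(as.vector(pl)[p], 8, 8)
        }
        a3
    }
    voxp <- permute_plane(vox)
    permute_stack <- function(s4) {  # (y, x, 1, z) target stacks
        for (k in 1:8) {
            pl <- s4[, , 1, k]
            s4[, , 1, k] <- matrix(as.vector(pl)[p], 8, 8)
        }
        s4
    }
    m2 <- mvttModel(cfg, seed = 11)
    for (nm in c("clstm.Wcf", "clstm.Wci", "clstm.Wco")) m2$par[[nm]]$value[] <- 0
    lossp <- ns$ad_add(ns$ad_dice(mvttForward(m2, voxp, "train")$anatomy,
                                  permute_stack(gl)),
                       ns$ad_dice(mvttForward(m2, voxp, "train")$scar,
                                  permute_stack(gas)))$value
    expect_equal(lossp, loss0, tolerance = 1e-9)
})

test_that("checkpoints round-trip parameters, config and BN statistics", {
    cfg <- tiny_mvtt_config(8L)
    m <- mvttModel(cfg, seed = 13)
    vox <- array(rnorm(8^3), dim = c(8, 8, 8))
    invisible(mvttForward(m, vox, mode = "train"))  # move the running stats
    path <- tempfile(fileext = ".rds")
    saveCheckpoint(m, path)
    m2 <- loadCheckpoint(path)
    expect_identical(lapply(mvttParameters(m), function(p) p$value),
                     lapply(mvttParameters(m2), function(p) p$value))
    fw1 <- mvttForward(m, vox, mode = "infer")
    fw2 <- mvttForward(m2, vox, mode = "infer")
    expect_identical(fw1$scar$value, fw2$scar$value)
    unlink(path)
})
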