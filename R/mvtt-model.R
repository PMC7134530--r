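#' Create an MVTT model configuration
#'
#' @param useMultiview include sagittal/coronal dilated residual subnetworks
#'   (FALSE = the single-view "SV" variants).
#' @param useConvLSTM axial sequence learning via ConvLSTM (FALSE = "MV" variant,
#'   per-slice convolutions instead).
#' @param useAttention attention-gate the scar branch (FALSE = "MV+CLSTM").
#' @param kernelSize 3 (default) or 5 ("K5" variant).
#' @param convlstmActivation "relu" (default) or "tanh" ("AFT" variant).
#' @param convMode "hdc" (default) or "plain" ("NDC" variant: all dilations 1).
#' @param tasks "both" (hybrid loss), "anatomy_only" ("S-LA/PV") or
#'   "scar_only" ("S-Scar").
#' @param cubeEdge isotropic processing grid edge.
#' @param baseChannels feature width of the subnetworks.
#' @param dilationCycle HDC dilation rates (no common divisor, anti-gridding).
#' @return an \code{\linkS4class{MVTTConfig}}.
#' @export
mvttConfig <- function(useMultiview = TRUE, useConvLSTM = TRUE,
                       useAttention = TRUE, kernelSize = 3L,
                       convlstmActivation = "relu", convMode = "hdc",
                       tasks = "both", cubeEdge = 48L, baseChannels = 4L,
                       dilationCycle = c(1L, 2L, 5L)) {
    new("MVTTConfig", useMultiview = useMultiview, useConvLSTM = useConvLSTM,
        useAttention = useAttention, kernelSize = as.integer(kernelSize),
        convlstmActivation = convlstmActivation, convMode = convMode,
        tasks = tasks, cubeEdge = as.integer(cubeEdge),
        baseChannels = as.integer(baseChannels),
        dilationCycle = as.integer(dilationCycle))
}

# number of HDC blocks per sagittal/coronal branch
.N_HDC_BLOCKS <- 3L
# kernels per head layer (the two pre-concatenation layers)
.HEAD_CHANNELS <- 16L
# initial bias of the scar head's final sigmoid, logit of a ~5% lesion prior
.SCAR_BIAS_INIT <- -3

.conv_init <- function(k, ci, co, zero = FALSE) {
    n <- k * k * ci * co
    array(if (zero) numeric(n) else rnorm(n, 0, sqrt(2 / (k * k * ci))),
          dim = c(k, k, ci, co))
}

# conv + BN unit; the convolution carries no bias (the BN shift absorbs it)
.conv_unit <- function(model, name, k, ci, co, zero = FALSE) {
    model$par[[paste0(name, ".W")]] <- ad_param(.conv_init(k, ci, co, zero))
    model$par[[paste0(name, ".gamma")]] <- ad_param(rep(1, co))
    model$par[[paste0(name, ".beta")]] <- ad_param(numeric(co))
    model$bn[[name]] <- .bn_layer(co)
    invisible(model)
}

.conv_plain <- function(model, name, k, ci, co, zero = FALSE) {
    model$par[[paste0(name, ".W")]] <- ad_param(.conv_init(k, ci, co, zero))
    model$par[[paste0(name, ".b")]] <- ad_param(numeric(co))
    invisible(model)
}

#' Build an MVTT model
#'
#' Assembles the configured subnetworks and initializes parameters with
#' fan-in-scaled random values under the given seed. Parameters are registered
#' in named groups: \code{theta_a} (axial sequence subnetwork), \code{theta_s}
#' and \code{theta_c} (sagittal/coronal dilated residual subnetworks),
#' \code{theta_am} (attention mask branch), \code{theta_l} (anatomy head) and
#' \code{theta_as} (scar head).
#'
#' @param config an \code{MVTTConfig}.
#' @param seed initialization seed.
#' @param zeroHead initialize the final head convolutions to zero (a fresh
#'   model then emits uniform 0.5 probability maps).
#' @return a model environment.
#' @export
mvttModel <- function(config, seed = 1L, zeroHead = FALSE) {
    validObject(config)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    m <- new.env(parent = emptyenv())
    m$config <- config
    m$seed <- as.integer(seed)
    m$par <- list()
    m$bn <- list()
    m$groups <- list()
    k <- config@kernelSize
    C <- config@baseChannels
    E <- config@cubeEdge
    cyc <- if (config@convMode == "hdc") config@dilationCycle
           else rep(1L, length(config@dilationCycle))
    m$cycle <- cyc

    reg <- function(group, names) m$groups[[group]] <<- c(m$groups[[group]], names)
    pnames <- function() names(m$par)

    # axial encoder + sequence subnetwork (theta_a)
    before <- pnames()
    .conv_unit(m, "enc_a1", k, 1L, C)
    .conv_unit(m, "enc_a2", k, C, C)
    if (config@useConvLSTM) {
        lp <- convLSTMParams(E, E, C, C, kernelSize = k, init = "random")
        for (nm in names(lp)) m$par[[paste0("clstm.", nm)]] <- ad_param(lp[[nm]])
    } else {
        .conv_unit(m, "seq_conv", k, C, C)
    }
    reg("theta_a", setdiff(pnames(), before))

    if (config@useMultiview) {
        for (v in c("s", "c")) {
            before <- pnames()
            .conv_unit(m, paste0("proj_", v), k, 1L, C)
            for (b in seq_len(.N_HDC_BLOCKS))
                for (i in seq_along(cyc))
                    .conv_unit(m, sprintf("hdc_%s%d_%d", v, b, i), k, C, C)
            reg(paste0("theta_", v), setdiff(pnames(), before))
        }
    }

    if (config@useAttention) {
        before <- pnames()
        for (i in seq_along(cyc))
            .conv_unit(m, paste0("attn", i), k, if (i == 1L) 1L else C, C)
        .conv_plain(m, "attn_proj", 1L, C, C)
        reg("theta_am", setdiff(pnames(), before))
    }

    if (config@tasks != "scar_only") {
        before <- pnames()
        .conv_unit(m, "head_l1", k, C, .HEAD_CHANNELS)
        .conv_unit(m, "head_l2", k, .HEAD_CHANNELS, .HEAD_CHANNELS)
        .conv_plain(m, "head_l3", k, 2L * .HEAD_CHANNELS, 1L, zero = zeroHead)
        reg("theta_l", setdiff(pnames(), before))
    }
    if (config@tasks != "anatomy_only") {
        before <- pnames()
        .conv_unit(m, "head_s1", k, C, .HEAD_CHANNELS)
        .conv_unit(m, "head_s2", k, .HEAD_CHANNELS, .HEAD_CHANNELS)
        .conv_plain(m, "head_s3", 1L, 2L * .HEAD_CHANNELS, 1L, zero = zeroHead)
        # scar occupies a tiny voxel fraction: start the final sigmoid near a
        # small lesion prior so the Dice loss does not spend its early updates
        # suppressing a half-on background (prior-matched bias initialization)
        if (!zeroHead) m$par[["head_s3.b"]]$value <- .SCAR_BIAS_INIT
        reg("theta_as", setdiff(pnames(), before))
    }
    class(m) <- "mvtt_model"
    m
}

#' Named parameter nodes of a model
#' @param model an MVTT model.
#' @return named list of parameter nodes.
#' @export
mvttParameters <- function(model) model$par

#' Parameter registry groups (theta_a, theta_s, theta_c, theta_am, theta_l, theta_as)
#' @param model an MVTT model.
#' @return named list mapping group to parameter names.
#' @export
parameterGroups <- function(model) model$groups

#' Total number of scalar parameters
#' @param model an MVTT model.
#' @return integer count.
#' @export
mvttParameterCount <- function(model)
    sum(vapply(model$par, function(p) length(p$value), numeric(1)))

# conv + BN + ReLU node unit (fused BN/ReLU kernels)
.unit_fwd <- function(model, name, x, dilation = 1L, mode = "train") {
    p <- model$par
    z <- ad_conv2d(x, p[[paste0(name, ".W")]], dilation = dilation)
    ad_bn_relu(z, p[[paste0(name, ".gamma")]], p[[paste0(name, ".beta")]],
               model$bn[[name]], mode = mode)
}

# axial/sagittal/coronal input stacks (E,E,1,E) from a cubic (z,y,x) array
.view_stacks <- function(vox) {
    E <- dim(vox)[1]
    shape <- function(a) { dim(a) <- c(E, E, 1L, E); a }
    list(axial = shape(aperm(vox, c(2, 3, 1))),
         sagittal = shape(vox),
         coronal = shape(aperm(vox, c(1, 3, 2))))
}

#' Forward pass of the MVTT model
#'
#' Runs the axial sequence subnetwork (ConvLSTM over ordered axial slices, or
#' per-slice convolutions when disabled), the sagittal/coronal dilated residual
#' subnetworks, multiview fusion Fv = Fa + T(Fc) + T(Fs), the attention-gated
#' scar branch O = (1 + AM) o Fv, and both task heads in a single pass.
#'
#' @param model from \code{mvttModel}.
#' @param vox cubic (z, y, x) array, already slice-normalized.
#' @param mode "infer" (running BN statistics; deterministic) or "train".
#' @param returnFeatures also return intermediate feature nodes (Fa, Fv, AM, O).
#' @return list with nodes \code{anatomy} and \code{scar} — probability stacks
#'   (E, E, 1, E) in axial order — and optionally the intermediates.
#' @export
mvttForward <- function(model, vox, mode = "infer", returnFeatures = FALSE) {
    cfg <- model$config
    E <- cfg@cubeEdge
    if (!all(dim(vox) == E))
        stop("input must be a cubic ", E, "^3 volume; got ",
             paste(dim(vox), collapse = "x"))
    st <- .view_stacks(vox)
    x_a <- ad_const(st$axial)
    cyc <- model$cycle

    # axial branch
    e <- .unit_fwd(model, "enc_a2", .unit_fwd(model, "enc_a1", x_a, mode = mode),
                   mode = mode)
    if (cfg@useConvLSTM) {
        lp <- model$par[paste0("clstm.", c("Wxf", "Whf", "Wxi", "Whi", "Wxc", "Whc",
                                           "Wxo", "Who", "Wcf", "Wci", "Wco",
                                           "bf", "bi", "bc", "bo"))]
        names(lp) <- sub("^clstm\\.", "", names(lp))
        # gate convolutions are fused: the four input-to-gate kernels run once,
        # batched over the whole ordered stack; the recurrence itself (one
        # recurrent convolution per step plus the gate arithmetic) runs as a
        # single compiled forward/backward-through-time operation
        gx <- ad_conv2d(e, ad_kcat(list(lp$Wxf, lp$Wxi, lp$Wxc, lp$Wxo)))
        Wh <- ad_kcat(list(lp$Whf, lp$Whi, lp$Whc, lp$Who))
        Fa <- ad_convlstm(gx, Wh, lp$Wcf, lp$Wci, lp$Wco,
                          lp$bf, lp$bi, lp$bc, lp$bo,
                          activation = cfg@convlstmActivation)
    } else {
        Fa <- .unit_fwd(model, "seq_conv", e, mode = mode)
    }

    # sagittal / coronal branches + fusion
    if (cfg@useMultiview) {
        branch <- function(v, xs) {
            f <- .unit_fwd(model, paste0("proj_", v), ad_const(xs), mode = mode)
            for (b in seq_len(.N_HDC_BLOCKS)) {
                inp <- f
                for (i in seq_along(cyc))
                    f <- .unit_fwd(model, sprintf("hdc_%s%d_%d", v, b, i), f,
                                   dilation = cyc[i], mode = mode)
                f <- ad_add(f, inp)  # residual shortcut
            }
            f
        }
        Fs <- branch("s", st$sagittal)
        Fc <- branch("c", st$coronal)
        Fv <- ad_add(Fa, ad_add(ad_aperm(Fc, c(4, 2, 3, 1)),
                                ad_aperm(Fs, c(2, 4, 3, 1))))
    } else {
        Fv <- Fa
    }

    out <- list()
    if (cfg@tasks != "scar_only")
        out$anatomy <- .head_fwd(model, "head_l", Fv, finalDilation = 1L,
                                 mode = mode)

    AM <- NULL
    if (cfg@tasks != "anatomy_only") {
        if (cfg@useAttention) {
            a <- x_a
            for (i in seq_along(cyc))
                a <- .unit_fwd(model, paste0("attn", i), a, dilation = cyc[i],
                               mode = mode)
            AM <- ad_sigmoid(ad_bias(ad_conv2d(a, model$par[["attn_proj.W"]]),
                                     model$par[["attn_proj.b"]]))
            O <- ad_add(Fv, ad_mul(AM, Fv))  # (1 + AM) o F
        } else {
            O <- Fv
        }
        out$scar <- .head_fwd(model, "head_s", O, finalDilation = 1L, mode = mode)
    }
    if (returnFeatures)
        out <- c(out, list(Fa = Fa, Fv = Fv, AM = AM,
                           O = if (cfg@tasks != "anatomy_only") O else NULL))
    out
}

# Two conv(16)+BN+ReLU layers, channel concatenation (32), final conv(1) +
# sigmoid. The final convolution stores one 32-input-channel kernel but is
# applied to the two 16-channel maps separately and summed, which is
# arithmetically identical to convolving their concatenation and avoids
# materializing the 32-channel stack.
.head_fwd <- function(model, prefix, x, finalDilation = 1L, mode = "train") {
    h1 <- .unit_fwd(model, paste0(prefix, "1"), x, mode = mode)
    h2 <- .unit_fwd(model, paste0(prefix, "2"), h1, mode = mode)
    w3 <- model$par[[paste0(prefix, "3.W")]]
    nc <- dim(h1$value)[3]
    z <- ad_add(ad_conv2d(h1, ad_kslice(w3, 1L, nc), dilation = finalDilation),
                ad_conv2d(h2, ad_kslice(w3, nc + 1L, 2L * nc),
                          dilation = finalDilation))
    ad_sigmoid(ad_bias(z, model$par[[paste0(prefix, "3.b")]]))
}

#' Multiview feature fusion
#'
#' Fv = Fa + T(Fc) + T(Fs): the sagittal and coronal feature stacks are
#' transposed to axial ordering and summed elementwise with the axial stack.
#'
#' @param Fa axial feature stack (H, W, C, N), N = number of axial planes.
#' @param Fs sagittal feature stack ((z, y) planes indexed by x).
#' @param Fc coronal feature stack ((z, x) planes indexed by y).
#' @return fused stack in axial ordering.
#' @export
fuseViews <- function(Fa, Fs, Fc) {
    # a 3D input is an (H, W, N) slice stack from decomposeViews: insert the
    # singleton channel axis (not a singleton batch axis)
    stack4 <- function(s) {
        d <- dim(s)
        if (length(d) == 3L) dim(s) <- c(d[1], d[2], 1L, d[3])
        s
    }
    was3d <- length(dim(Fa)) == 3L
    Fa <- stack4(Fa); Fs <- stack4(Fs); Fc <- stack4(Fc)
    Ts <- transposeToAxial(Fs, "sagittal")
    Tc <- transposeToAxial(Fc, "coronal")
    if (!identical(dim(Fa), dim(Ts)) || !identical(dim(Fa), dim(Tc)))
        stop("view stacks are not shape-compatible after transposition")
    out <- Fa + Tc + Ts
    if (was3d) { d <- dim(out); dim(out) <- d[c(1, 2, 4)] }
    out
}

#' Soft Dice loss
#'
#' delta(m, g) = 1 - (2 * sum(m g) + eps) / (sum(m) + sum(g) + eps), the
#' probabilistic overlap complement; eps = 1 avoids 0/0 on empty masks.
#'
#' @param m probability map in [0, 1].
#' @param g binary ground-truth map of the same shape.
#' @param eps smoothing constant.
#' @return nonnegative scalar.
#' @export
diceLoss <- function(m, g, eps = 1) {
    if (!identical(dim(m), dim(g))) stop("shape mismatch between m and g")
    if (!all(g %in% c(0, 1))) stop("g must be binary")
    1 - (2 * sum(m * g) + eps) / (sum(m) + sum(g) + eps)
}

#' Hybrid two-task loss
#'
#' L = diceLoss(ml, gl) + diceLoss(mas, gas): the sum of the anatomy and scar
#' soft Dice losses, coupling both tasks through the shared multiview features.
#'
#' @param ml,mas predicted probability maps for anatomy and scar.
#' @param gl,gas binary ground truths.
#' @param eps smoothing constant.
#' @return nonnegative scalar.
#' @export
hybridLoss <- function(ml, mas, gl, gas, eps = 1) {
    if (is.null(ml) || is.null(mas)) stop("hybrid loss requires both task outputs")
    diceLoss(ml, gl, eps) + diceLoss(mas, gas, eps)
}

#' Segment a volume with a trained model
#'
#' Applies slice-wise normalization, resamples to the model's cube edge, runs a
#' forward pass in inference mode and reassembles the axial probability stacks
#' into volumes.
#'
#' @param model a (trained) MVTT model.
#' @param volume a \code{Volume}.
#' @param normalize apply slice-wise mean normalization first.
#' @return a \code{\linkS4class{SegmentationOutput}}.
#' @export
predictVolume <- function(model, volume, normalize = TRUE) {
    stopifnot(is(volume, "Volume"))
    v <- if (normalize) normalizeSlicewise(volume) else volume
    v <- resampleToCube(v, model$config@cubeEdge)
    fw <- mvttForward(model, v@voxels, mode = "infer")
    tovol <- function(node) {
        if (is.null(node)) return(NULL)
        a <- node$value  # (y, x, 1, z)
        dim(a) <- dim(a)[c(1, 2, 4)]
        Volume(aperm(a, c(3, 1, 2)), spacing = v@spacing, origin = v@origin)
    }
    new("SegmentationOutput", anatomyProb = tovol(fw$anatomy),
        scarProb = tovol(fw$scar))
}

#' Binarize a probability volume
#'
#' @param prob a probability \code{Volume}.
#' @param threshold decision threshold (default 0.5).
#' @return a \code{LabelVolume}.
#' @export
binarizeProb <- function(prob, threshold = 0.5) {
    stopifnot(is(prob, "Volume"))
    LabelVolume(array(as.integer(prob@voxels >= threshold), dim = dim(prob@voxels)),
                spacing = prob@spacing, origin = prob@origin)
}

#' Save a model checkpoint (named tensors + config)
#' @param model an MVTT model.
#' @param path output .rds path.
#' @return path, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
    ck <- list(config = .config_to_list(model$config), seed = model$seed,
               par = lapply(model$par, ad_value),
               bn = lapply(model$bn, function(b)
                   list(mean = b$running_mean, var = b$running_var)))
    saveRDS(ck, path)
    invisible(path)
}

#' Load a model checkpoint
#' @param path .rds path from \code{saveCheckpoint}.
#' @return an MVTT model.
#' @export
loadCheckpoint <- function(path) {
    if (!file.exists(path)) stop("checkpoint not found: ", path)
    ck <- readRDS(path)
    model <- mvttModel(do.call(mvttConfig, ck$config), seed = ck$seed)
    for (nm in names(ck$par)) model$par[[nm]]$value <- ck$par[[nm]]
    for (nm in names(ck$bn)) {
        model$bn[[nm]]$running_mean <- ck$bn[[nm]]$mean
        model$bn[[nm]]$running_var <- ck$bn[[nm]]$var
    }
    model
}

.config_to_list <- function(cfg) list(
    useMultiview = cfg@useMultiview, useConvLSTM = cfg@useConvLSTM,
    useAttention = cfg@useAttention, kernelSize = cfg@kernelSize,
    convlstmActivation = cfg@convlstmActivation, convMode = cfg@convMode,
    tasks = cfg@tasks, cubeEdge = cfg@cubeEdge,
    baseChannels = cfg@baseChannels, dilationCycle = cfg@dilationCycle)
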