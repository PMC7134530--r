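#' Create a training configuration
#'
#' @param lrInit initial Adam learning rate (default 0.001).
#' @param lrDecay multiplicative decay per epoch (default 0.98).
#' @param maxEpochs maximum number of epochs.
#' @param earlyStopPatience epochs without validation-loss improvement before
#'   stopping; the best-validation checkpoint is returned.
#' @param batchSize volumes per gradient step; each volume contributes its full
#'   ordered slice stacks (the sequence subnetwork needs the whole axial stack).
#' @param seed seed for initialization and shuffling.
#' @param kFolds folds for cross-validation splitting.
#' @return a \code{\linkS4class{TrainConfig}}.
#' @export
trainConfig <- function(lrInit = 0.001, lrDecay = 0.98, maxEpochs = 30L,
                        earlyStopPatience = 5L, batchSize = 1L, seed = 1L,
                        kFolds = 10L) {
    new("TrainConfig", lrInit = lrInit, lrDecay = lrDecay,
        maxEpochs = as.integer(maxEpochs),
        earlyStopPatience = as.integer(earlyStopPatience),
        batchSize = as.integer(batchSize), seed = as.integer(seed),
        kFolds = as.integer(kFolds))
}

#' Decayed learning-rate schedule
#'
#' lr(epoch) = lrInit * lrDecay^epoch, epoch counted from 0.
#'
#' @param config a \code{TrainConfig}.
#' @param epoch epoch index (>= 0).
#' @return the learning rate.
#' @export
lrSchedule <- function(config, epoch) {
    if (any(epoch < 0)) stop("epoch must be >= 0")
    config@lrInit * config@lrDecay^epoch
}

#' Random k-fold partition of case identifiers
#'
#' Folds are disjoint, cover all ids, differ in size by at most one and are
#' deterministic given the seed.
#'
#' @param ids vector of case identifiers.
#' @param k number of folds.
#' @param seed seed.
#' @return list of k elements, each \code{list(train, validation)}.
#' @export
makeKFoldSplits <- function(ids, k, seed = 1L) {
    k <- as.integer(k)
    if (k > length(ids)) stop("k must not exceed the number of ids")
    if (k < 2L) stop("k must be >= 2")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    perm <- sample(ids)
    fold <- rep(seq_len(k), length.out = length(ids))  # sizes differ by <= 1
    lapply(seq_len(k), function(f)
        list(train = perm[fold != f], validation = perm[fold == f]))
}

# Adam optimizer state over a named parameter list.
.adam_init <- function(params) {
    st <- new.env(parent = emptyenv())
    st$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
    st$v <- st$m
    st$t <- 0L
    st
}

.adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    st$t <- st$t + 1L
    b1t <- 1 - beta1^st$t
    b2t <- 1 - beta2^st$t
    for (nm in names(params)) {
        p <- params[[nm]]
        if (is.null(p$grad)) next
        g <- p$grad
        st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
        st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
        p$value <- p$value - lr * (st$m[[nm]] / b1t) /
            (sqrt(st$v[[nm]] / b2t) + eps)
    }
    invisible(st)
}

# Axial input/target stacks for one phantom sample at the model's cube edge.
.prep_sample <- function(sample, edge) {
    img <- normalizeSlicewise(sample@image)
    img <- resampleToCube(img, edge)
    resamp_mask <- function(lv) {
        if (all(dim(lv@labels) == edge)) return(lv@labels)
        v <- resampleToCube(Volume(lv@labels + 0, spacing = lv@spacing), edge)
        (v@voxels >= 0.5) + 0L
    }
    ax <- function(a) { x <- aperm(a, c(2, 3, 1)); dim(x) <- c(edge, edge, 1L, edge); x }
    list(x = img@voxels,
         gl = ax(resamp_mask(sample@anatomy)),
         gas = ax(resamp_mask(sample@scar)))
}

.sample_loss_node <- function(model, prep, mode = "train") {
    fw <- mvttForward(model, prep$x, mode = mode)
    cfg <- model$config
    if (cfg@tasks == "both")
        ad_add(ad_dice(fw$anatomy, prep$gl), ad_dice(fw$scar, prep$gas))
    else if (cfg@tasks == "anatomy_only") ad_dice(fw$anatomy, prep$gl)
    else ad_dice(fw$scar, prep$gas)
}

#' Train an MVTT model on a phantom cohort
#'
#' Minimizes the hybrid Dice loss (or the single-task Dice loss for the
#' single-task variants) with Adam under the decayed learning-rate schedule,
#' one volume's slice stacks per gradient step. Training stops early when the
#' validation loss has not improved for \code{earlyStopPatience} epochs; the
#' parameters of the best-validation epoch are restored.
#'
#' @param config an \code{MVTTConfig}.
#' @param cohort list of \code{PhantomSample}.
#' @param trainCfg a \code{TrainConfig}.
#' @param valIdx indices of cohort elements held out for validation; NULL
#'   trains on everything and monitors the training loss instead.
#' @param validateEvery run the validation pass every this many epochs (the
#'   final epoch is always validated); early stopping needs 1.
#' @param preps optional pre-computed slice stacks from an earlier run on the
#'   same cohort and cube edge (reused across ablation variants).
#' @param stopAtTrainLoss optional target: stop as soon as the mean training
#'   loss of an epoch falls below it (used by memorization sanity checks).
#' @return list(model, history) where history is a per-epoch data.frame with
#'   the recorded learning rate, losses and validation Dice per task.
#' @export
trainMVTT <- function(config, cohort, trainCfg, valIdx = NULL,
                      validateEvery = 1L, preps = NULL,
                      stopAtTrainLoss = NULL) {
    if (!length(cohort)) stop("cohort is empty")
    model <- mvttModel(config, seed = trainCfg@seed)
    if (is.null(preps))
        preps <- lapply(cohort, .prep_sample, edge = config@cubeEdge)
    tr_idx <- setdiff(seq_along(cohort), valIdx)
    opt <- .adam_init(model$par)
    hist <- data.frame()
    best <- list(loss = Inf, par = NULL, bn = NULL, epoch = -1L)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(trainCfg@seed + 1L)

    for (epoch in 0:(trainCfg@maxEpochs - 1L)) {
        lr <- lrSchedule(trainCfg, epoch)
        tl <- 0
        for (i in sample(tr_idx)) {
            ad_zero_grad(model$par)
            loss <- .sample_loss_node(model, preps[[i]], mode = "train")
            if (!is.finite(loss$value))
                stop("training diverged: non-finite loss at epoch ", epoch,
                     ", sample ", i)
            ad_backward(loss)
            .adam_step(model$par, opt, lr)
            tl <- tl + loss$value
        }
        tl <- tl / length(tr_idx)

        if (epoch %% validateEvery == 0L || epoch == trainCfg@maxEpochs - 1L) {
            vstats <- .validate(model, preps, if (length(valIdx)) valIdx else tr_idx)
        } else {
            vstats <- list(loss = tl, dice_anatomy = NA_real_, dice_scar = NA_real_)
        }
        hist <- rbind(hist, data.frame(
            epoch = epoch, lr = lr, train_loss = tl, val_loss = vstats$loss,
            val_dice_anatomy = vstats$dice_anatomy,
            val_dice_scar = vstats$dice_scar))

        if (vstats$loss < best$loss - 1e-9) {
            best$loss <- vstats$loss
            best$epoch <- epoch
            best$par <- lapply(model$par, ad_value)
            best$bn <- lapply(model$bn, function(b)
                list(mean = b$running_mean, var = b$running_var))
        } else if (epoch - best$epoch >= trainCfg@earlyStopPatience) {
            break
        }
        if (!is.null(stopAtTrainLoss) && tl < stopAtTrainLoss) {
            best$par <- lapply(model$par, ad_value)
            best$bn <- lapply(model$bn, function(b)
                list(mean = b$running_mean, var = b$running_var))
            break
        }
    }
    if (!is.null(best$par)) {
        for (nm in names(best$par)) model$par[[nm]]$value <- best$par[[nm]]
        for (nm in names(best$bn)) {
            model$bn[[nm]]$running_mean <- best$bn[[nm]]$mean
            model$bn[[nm]]$running_var <- best$bn[[nm]]$var
        }
    }
    list(model = model, history = hist)
}

.validate <- function(model, preps, idx) {
    cfg <- model$config
    loss <- 0; da <- numeric(0); ds <- numeric(0)
    for (i in idx) {
        p <- preps[[i]]
        fw <- mvttForward(model, p$x, mode = "infer")
        l <- 0
        if (!is.null(fw$anatomy)) {
            l <- l + diceLoss(fw$anatomy$value, p$gl)
            da <- c(da, .hard_dice(fw$anatomy$value, p$gl))
        }
        if (!is.null(fw$scar)) {
            l <- l + diceLoss(fw$scar$value, p$gas)
            ds <- c(ds, .hard_dice(fw$scar$value, p$gas))
        }
        loss <- loss + l
    }
    list(loss = loss / length(idx),
         dice_anatomy = if (length(da)) mean(da) else NA_real_,
         dice_scar = if (length(ds)) mean(ds) else NA_real_)
}

# Dice of the 0.5-binarized prediction.
.hard_dice <- function(prob, g) {
    p <- prob >= 0.5
    denom <- sum(p) + sum(g)
    if (denom == 0) return(1)
    2 * sum(p & (g > 0)) / denom
}

#' Run the model-variant ablation suite
#'
#' Trains every variant on identical splits and seeds and reports per-variant
#' segmentation metrics (accuracy, sensitivity, specificity, Dice) for each
#' task on the held-out cases.
#'
#' @param cohort list of \code{PhantomSample}.
#' @param variants named list of \code{MVTTConfig} (>= 2).
#' @param trainCfg a \code{TrainConfig}; its seed fixes the shared split.
#' @param valFraction held-out fraction of the cohort.
#' @return data.frame with one row per variant and task.
#' @export
runAblationSuite <- function(cohort, variants, trainCfg, valFraction = 0.2) {
    if (length(variants) < 2L) stop("need at least two variants")
    n <- length(cohort)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(trainCfg@seed)
    valIdx <- sort(sample(n, max(1L, round(valFraction * n))))
    res <- data.frame()
    for (vn in names(variants)) {
        fit <- trainMVTT(variants[[vn]], cohort, trainCfg, valIdx = valIdx)
        for (task in c("anatomy", "scar")) {
            cfg <- variants[[vn]]
            if (task == "anatomy" && cfg@tasks == "scar_only") next
            if (task == "scar" && cfg@tasks == "anatomy_only") next
            mets <- sapply(valIdx, function(i) {
                so <- predictVolume(fit$model, cohort[[i]]@image)
                pv <- if (task == "anatomy") so@anatomyProb else so@scarProb
                truth <- if (task == "anatomy") cohort[[i]]@anatomy
                         else cohort[[i]]@scar
                cm <- confusionCounts(binarizeProb(pv), truth)
                unlist(segmentationMetrics(cm))
            })
            mm <- rowMeans(mets)
            res <- rbind(res, data.frame(
                variant = vn, task = task, accuracy = mm["accuracy"],
                sensitivity = mm["sensitivity"], specificity = mm["specificity"],
                dice = mm["dice"], row.names = NULL))
        }
    }
    res
}
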