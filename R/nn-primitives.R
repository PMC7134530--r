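# Building blocks of the MVTT network: the ConvLSTM cell with ReLU state
# activation and per-location Hadamard peephole weights, hybrid dilated
# convolution (HDC) residual blocks, and the sigmoid attention mask with
# (1 + AM) * F skip-sum modulation.
#
# Public functions take and return plain numeric arrays; the same node-level
# code paths are reused inside the trainable model.

#' Create a ConvLSTM parameter set
#'
#' Kernels are (kh, kw, in, out); the peephole weights Wcf, Wci, Wco are
#' per-location, per-channel Hadamard maps matching the state's spatial shape,
#' literally implementing the elementwise-product terms of the gate equations.
#'
#' @param height,width spatial size of the state maps.
#' @param inChannels,outChannels channel counts.
#' @param kernelSize odd kernel size.
#' @param init "zero" or "random" (fan-in scaled).
#' @return named list of numeric arrays.
#' @export
convLSTMParams <- function(height, width, inChannels, outChannels,
                           kernelSize = 3L, init = c("zero", "random")) {
    init <- match.arg(init)
    k <- as.integer(kernelSize)
    # gates are sigmoids, so Xavier-style 1/fan-in scaling; the recurrent
    # kernels get an extra conservative factor — with a ReLU state activation
    # the memory cell is unbounded and hot recurrent weights make it grow
    # geometrically over a long ordered slice sequence
    mk <- function(ci, co, gain = 1) {
        n <- k * k * ci * co
        vals <- if (init == "zero") numeric(n)
                else rnorm(n, 0, gain * sqrt(1 / (k * k * ci)))
        array(vals, dim = c(k, k, ci, co))
    }
    mkr <- function(ci, co) mk(ci, co, gain = 0.25)
    mkmap <- function() {
        n <- height * width * outChannels
        vals <- if (init == "zero") numeric(n) else rnorm(n, 0, 0.01)
        array(vals, dim = c(height, width, outChannels))
    }
    list(Wxf = mk(inChannels, outChannels), Whf = mkr(outChannels, outChannels),
         Wxi = mk(inChannels, outChannels), Whi = mkr(outChannels, outChannels),
         Wxc = mk(inChannels, outChannels), Whc = mkr(outChannels, outChannels),
         Wxo = mk(inChannels, outChannels), Who = mkr(outChannels, outChannels),
         Wcf = mkmap(), Wci = mkmap(), Wco = mkmap(),
         bf = numeric(outChannels), bi = numeric(outChannels),
         bc = numeric(outChannels), bo = numeric(outChannels))
}

# Node-level ConvLSTM step shared by the public API and the model.
# x, h, c are (H, W, C, 1) nodes; params a named list of nodes (or arrays).
.convlstm_step_node <- function(params, x, h, c, activation = "relu") {
    act <- if (activation == "tanh") ad_tanh else ad_relu
    gate <- function(Wx, Wh, Wc, b, cell) {
        z <- ad_add(ad_conv2d(x, params[[Wx]]), ad_conv2d(h, params[[Wh]]))
        if (!is.null(Wc)) z <- ad_add(z, ad_mulmap(cell, params[[Wc]]))
        ad_sigmoid(ad_bias(z, params[[b]]))
    }
    f <- gate("Wxf", "Whf", "Wcf", "bf", c)
    i <- gate("Wxi", "Whi", "Wci", "bi", c)
    cand <- act(ad_bias(ad_add(ad_conv2d(x, params$Wxc), ad_conv2d(h, params$Whc)),
                        params$bc))
    cnew <- ad_add(ad_mul(f, c), ad_mul(i, cand))
    o <- gate("Wxo", "Who", "Wco", "bo", cnew)
    hnew <- ad_mul(o, act(cnew))
    list(h = hnew, c = cnew)
}

.as_hwcn <- function(x) {
    d <- dim(x)
    if (is.null(d)) stop("expected an array")
    if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    x
}

#' One ConvLSTM step
#'
#' Gates: f_t = sigma(Wxf*x + Whf*h + Wcf o c + bf), i_t analogous;
#' c_t = f_t o c + i_t o act(Wxc*x + Whc*h + bc);
#' o_t = sigma(Wxo*x + Who*h + Wco o c_t + bo); h_t = o_t o act(c_t),
#' with act = ReLU by default (tanh available as a model variant) and o the
#' Hadamard product.
#'
#' @param params list from \code{convLSTMParams}.
#' @param x input feature map (H, W, Cin) or (H, W, Cin, 1).
#' @param state list(h, c) of (H, W, Cout[, 1]) arrays; NULL for a zero state.
#' @param activation "relu" or "tanh".
#' @return list(h, c) numeric arrays (H, W, Cout, 1).
#' @export
convLSTMStep <- function(params, x, state = NULL, activation = "relu") {
    x <- .as_hwcn(x)
    co <- dim(params$Wxf)[4]
    d <- c(dim(x)[1:2], co, 1L)
    if (is.null(state))
        state <- list(h = array(0, dim = d), c = array(0, dim = d))
    h <- ad_const(.as_hwcn(state$h))
    c <- ad_const(.as_hwcn(state$c))
    pn <- lapply(params, ad_const)
    st <- .convlstm_step_node(pn, ad_const(x), h, c, activation)
    list(h = st$h$value, c = st$c$value)
}

#' Run a ConvLSTM over an ordered slice sequence
#'
#' Iterates \code{convLSTMStep} from a zero initial state in ascending slice
#' order and returns all hidden maps.
#'
#' @param params list from \code{convLSTMParams}.
#' @param slices (H, W, Cin, N) array or list of (H, W, Cin) maps.
#' @param activation "relu" or "tanh".
#' @return (H, W, Cout, N) array of hidden states.
#' @export
convLSTMSequence <- function(params, slices, activation = "relu") {
    if (is.list(slices)) {
        n <- length(slices)
        if (!n) stop("empty slice sequence")
        d <- dim(.as_hwcn(slices[[1]]))
        arr <- array(0, dim = c(d[1], d[2], d[3], n))
        for (i in seq_len(n)) arr[, , , i] <- slices[[i]]
        slices <- arr
    }
    slices <- .as_hwcn(slices)
    n <- dim(slices)[4]
    if (!n) stop("empty slice sequence")
    st <- NULL
    co <- dim(params$Wxf)[4]
    out <- array(0, dim = c(dim(slices)[1:2], co, n))
    for (t in seq_len(n)) {
        st <- convLSTMStep(params, slices[, , , t, drop = FALSE], st, activation)
        out[, , , t] <- st$h
    }
    out
}

#' Configure a hybrid dilated convolution block
#'
#' A sequence of same-padded convolutions whose dilation rates cycle through
#' \code{dilationCycle} (default 1, 2, 5 — rates without a common divisor, so
#' the stacked receptive field has no periodic gaps), each followed by batch
#' normalization and ReLU, with an optional residual shortcut. Spatial size is
#' unchanged at every rate.
#'
#' @param kernelSize odd kernel size.
#' @param channels channel count (in = out).
#' @param dilationCycle positive integer dilation rates.
#' @param residual add the block input to the output.
#' @return a config list.
#' @export
hdcBlockConfig <- function(kernelSize = 3L, channels = 4L,
                           dilationCycle = c(1L, 2L, 5L), residual = TRUE) {
    stopifnot(kernelSize %% 2L == 1L, length(dilationCycle) >= 1L,
              all(dilationCycle >= 1L))
    list(kernelSize = as.integer(kernelSize), channels = as.integer(channels),
         dilationCycle = as.integer(dilationCycle), residual = isTRUE(residual))
}

#' Create parameters for an HDC block
#'
#' @param config from \code{hdcBlockConfig}.
#' @param init "zero" or "random".
#' @return list with per-convolution kernels, biases and BN parameters.
#' @export
hdcBlockParams <- function(config, init = c("zero", "random")) {
    init <- match.arg(init)
    k <- config$kernelSize; C <- config$channels
    lapply(seq_along(config$dilationCycle), function(i) {
        n <- k * k * C * C
        list(W = array(if (init == "zero") numeric(n)
                       else rnorm(n, 0, sqrt(2 / (k * k * C))), dim = c(k, k, C, C)),
             b = numeric(C), gamma = rep(1, C), beta = numeric(C))
    })
}

# Node-level HDC block. params: list per conv of node lists (W, b, gamma, beta);
# bn_layers: list of BN state environments.
.hdc_block_node <- function(config, params, bn_layers, x, bn_mode = "train") {
    out <- x
    for (i in seq_along(config$dilationCycle)) {
        d <- config$dilationCycle[i]
        p <- params[[i]]
        out <- ad_bias(ad_conv2d(out, p$W, dilation = d), p$b)
        out <- ad_batchnorm(out, p$gamma, p$beta, bn_layers[[i]], mode = bn_mode)
        out <- ad_relu(out)
    }
    if (config$residual) out <- ad_add(out, x)
    out
}

#' Apply an HDC block to a feature stack
#'
#' @param config from \code{hdcBlockConfig}.
#' @param params from \code{hdcBlockParams}.
#' @param x (H, W, C[, N]) feature stack.
#' @param bnMode "identity" (unit variance, gamma=1, beta=0; the unit-test
#'   mode), "train" (batch statistics) or "infer".
#' @return feature stack of identical shape.
#' @export
hdcBlock <- function(config, params, x, bnMode = "identity") {
    x4 <- .as_hwcn(x)
    if (dim(x4)[3] != config$channels)
        stop("channel mismatch: stack has ", dim(x4)[3], ", block expects ",
             config$channels)
    pn <- lapply(params, function(p) lapply(p, ad_param))
    bl <- lapply(seq_along(params), function(i) .bn_layer(config$channels))
    out <- .hdc_block_node(config, pn, bl, ad_const(x4), bn_mode = bnMode)
    v <- out$value
    if (length(dim(x)) < 4L) dim(v) <- dim(x)
    v
}

#' Sigmoid attention mask
#'
#' Normalizes a feature map into (0, 1) elementwise for every channel and
#' spatial position: AM = 1 / (1 + exp(-x)).
#'
#' @param x numeric array.
#' @return array of the same shape, values strictly in (0, 1).
#' @export
sigmoidMask <- function(x) 1 / (1 + exp(-x))

#' Attention modulation with skip sum
#'
#' O = (1 + AM) * F elementwise: the mask amplifies trunk responses while the
#' skip term preserves the trunk when the mask is uninformative.
#'
#' @param mask attention map in [0, 1].
#' @param trunk feature map of the same shape.
#' @return modulated feature map.
#' @export
attentionModulate <- function(mask, trunk) {
    if (!identical(dim(mask), dim(trunk)))
        stop("mask and trunk shapes differ")
    (1 + mask) * trunk
}
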