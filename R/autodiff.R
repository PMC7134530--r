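# Minimal reverse-mode automatic differentiation over dense arrays.
#
# Feature tensors are numeric arrays dim (H, W, C, N) where N indexes ordered 2D
# slices. A node wraps a value plus the closure that maps its output gradient to
# the gradients of its parents; backward() walks the graph in reverse topological
# order. Internal machinery — not exported.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$n <- 0L

.ad_node <- function(value, parents = list(), backfn = NULL, requires_grad = FALSE) {
    e <- new.env(parent = emptyenv())
    e$value <- value
    e$parents <- parents
    e$backfn <- backfn
    e$requires_grad <- requires_grad ||
        any(vapply(parents, function(p) p$requires_grad, logical(1)))
    e$grad <- NULL
    .ad_counter$n <- .ad_counter$n + 1L
    e$id <- .ad_counter$n
    class(e) <- "ad_node"
    e
}

ad_const <- function(v) .ad_node(v)
ad_param <- function(v) .ad_node(v, requires_grad = TRUE)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x
.as_node <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

# Reverse topological order by iterative DFS (graphs include 60+ ConvLSTM steps,
# so no recursion).
.ad_topo <- function(root) {
    topo <- vector("list", 256L)
    nt <- 0L
    seen <- new.env(parent = emptyenv())
    stack <- list(list(node = root, stage = 1L))
    while (length(stack)) {
        fr <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        nd <- fr$node
        key <- as.character(nd$id)
        if (fr$stage == 1L) {
            if (!is.null(seen[[key]])) next
            seen[[key]] <- TRUE
            stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
            for (p in nd$parents)
                if (p$requires_grad && is.null(seen[[as.character(p$id)]]))
                    stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        } else {
            nt <- nt + 1L
            if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
            topo[[nt]] <- nd
        }
    }
    topo[seq_len(nt)]
}

ad_backward <- function(loss) {
    stopifnot(inherits(loss, "ad_node"))
    loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
    if (is.null(dim(loss$value))) loss$grad <- 1
    topo <- .ad_topo(loss)
    for (i in rev(seq_along(topo))) {
        nd <- topo[[i]]
        if (is.null(nd$backfn) || !length(nd$parents)) next
        grads <- nd$backfn(nd$grad, nd)
        for (j in seq_along(nd$parents)) {
            p <- nd$parents[[j]]
            g <- grads[[j]]
            if (is.null(g) || !p$requires_grad) next
            if (inherits(g, "ad_slice_grad")) {
                if (is.null(p$grad)) p$grad <- array(0, dim = g$dim)
                p$grad[, , , g$n] <- p$grad[, , , g$n, drop = FALSE] + g$g
            } else {
                p$grad <- if (is.null(p$grad)) g else p$grad + g
            }
        }
    }
    invisible(loss)
}

ad_zero_grad <- function(params) {
    for (p in params) p$grad <- NULL
    invisible(params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise ops --------------------------------------------------------

ad_add <- function(a, b) {
    a <- .as_node(a); b <- .as_node(b)
    .ad_node(a$value + b$value, list(a, b),
             function(g, nd) list(g, g))
}

ad_sub <- function(a, b) {
    a <- .as_node(a); b <- .as_node(b)
    .ad_node(a$value - b$value, list(a, b),
             function(g, nd) list(g, -g))
}

ad_mul <- function(a, b) {
    a <- .as_node(a); b <- .as_node(b)
    .ad_node(a$value * b$value, list(a, b),
             function(g, nd) list(g * nd$parents[[2]]$value,
                                  g * nd$parents[[1]]$value))
}

ad_scale <- function(a, k) {
    a <- .as_node(a)
    .ad_node(a$value * k, list(a), function(g, nd) list(g * k))
}

ad_sigmoid <- function(a) {
    a <- .as_node(a)
    s <- 1 / (1 + exp(-a$value))
    nd <- .ad_node(s, list(a), function(g, nd) list(g * nd$value * (1 - nd$value)))
    nd
}

ad_relu <- function(a) {
    a <- .as_node(a)
    .ad_node(pmax(a$value, 0), list(a),
             function(g, nd) list(g * (nd$parents[[1]]$value > 0)))
}

ad_tanh <- function(a) {
    a <- .as_node(a)
    nd <- .ad_node(tanh(a$value), list(a),
                   function(g, nd) list(g * (1 - nd$value^2)))
    nd
}

## ---- structural ops ---------------------------------------------------------

.inv_perm <- function(perm) order(perm)

ad_aperm <- function(a, perm) {
    a <- .as_node(a)
    .ad_node(aperm(a$value, perm), list(a),
             function(g, nd) list(aperm(g, .inv_perm(perm))))
}

# Concatenate two (H,W,C,N) stacks along the channel axis.
ad_concat_c <- function(a, b) {
    a <- .as_node(a); b <- .as_node(b)
    da <- dim(a$value); db <- dim(b$value)
    v <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
    v[, , seq_len(da[3]), ] <- a$value
    v[, , da[3] + seq_len(db[3]), ] <- b$value
    .ad_node(v, list(a, b), function(g, nd) {
        list(g[, , seq_len(da[3]), , drop = FALSE],
             g[, , da[3] + seq_len(db[3]), , drop = FALSE])
    })
}

# Extract slice n of the batch axis, keeping dims (H,W,C,1). The gradient is
# returned as a sparse slice marker so that accumulation touches only the slice,
# not a freshly zero-filled full stack (N slices would otherwise cost N full
# array allocations per sequence).
ad_slice_n <- function(a, n) {
    a <- .as_node(a)
    d <- dim(a$value)
    .ad_node(a$value[, , , n, drop = FALSE], list(a), function(g, nd) {
        list(structure(list(g = g, n = n, dim = d), class = "ad_slice_grad"))
    })
}

# Channel-range slice (small arrays; used to split fused gate convolutions).
ad_cslice <- function(a, from, to) {
    a <- .as_node(a)
    d <- dim(a$value)
    .ad_node(a$value[, , from:to, , drop = FALSE], list(a), function(g, nd) {
        out <- array(0, dim = d)
        out[, , from:to, ] <- g
        list(out)
    })
}

# Concatenate convolution kernels along the output-channel axis (tiny arrays;
# lets the four ConvLSTM gate convolutions run as one GEMM).
ad_kcat <- function(ws) {
    ws <- lapply(ws, .as_node)
    ds <- lapply(ws, function(w) dim(w$value))
    co <- vapply(ds, function(d) d[4], numeric(1))
    d1 <- ds[[1]]
    v <- array(0, dim = c(d1[1], d1[2], d1[3], sum(co)))
    off <- 0L
    for (i in seq_along(ws)) {
        v[, , , off + seq_len(co[i])] <- ws[[i]]$value
        off <- off + co[i]
    }
    .ad_node(v, ws, function(g, nd) {
        out <- vector("list", length(ws))
        off <- 0L
        for (i in seq_along(ws)) {
            out[[i]] <- g[, , , off + seq_len(co[i]), drop = FALSE]
            off <- off + co[i]
        }
        out
    })
}

# Bind a list of (H,W,C,1) nodes into one (H,W,C,N) stack.
ad_stack_n <- function(nodes) {
    d <- dim(nodes[[1]]$value)
    N <- length(nodes)
    v <- array(0, dim = c(d[1], d[2], d[3], N))
    for (i in seq_len(N)) v[, , , i] <- nodes[[i]]$value
    .ad_node(v, nodes, function(g, nd) {
        lapply(seq_len(N), function(i) g[, , , i, drop = FALSE])
    })
}

# Hadamard product with a per-location weight map (H,W,C), broadcast over N.
ad_mulmap <- function(a, w) {
    a <- .as_node(a); w <- .as_node(w)
    d <- dim(a$value)
    wv <- array(w$value, dim = d)  # recycles over N
    .ad_node(a$value * wv, list(a, w), function(g, nd) {
        gw <- g * nd$parents[[1]]$value
        if (d[4] > 1L) {
            dim(gw) <- c(prod(d[1:3]), d[4])
            gw <- array(rowSums(gw), dim = d[1:3])
        } else dim(gw) <- d[1:3]
        list(g * array(nd$parents[[2]]$value, dim = d), gw)
    })
}

# Per-channel bias add on (H,W,C,N).
ad_bias <- function(a, b) {
    a <- .as_node(a); b <- .as_node(b)
    d <- dim(a$value)
    ones <- rep(1, d[3])
    .ad_node(.cscale_shift(a$value, ones, b$value), list(a, b), function(g, nd) {
        list(g, .csum(g))
    })
}

# Per-channel sums of an (H,W,C,N) array -> length C vector.
.csum <- function(x) as.numeric(.csum_c(x))

## ---- convolution ------------------------------------------------------------

.flip_kernel <- function(w) {
    d <- dim(w)  # (kh, kw, Cin, Cout)
    wf <- w[rev(seq_len(d[1])), rev(seq_len(d[2])), , , drop = FALSE]
    aperm(wf, c(1, 2, 4, 3))  # swap in/out channels
}

ad_conv2d <- function(x, w, dilation = 1L) {
    x <- .as_node(x); w <- .as_node(w)
    wd <- dim(w$value)
    y <- .conv2d_fwd(x$value, w$value, as.integer(dilation))
    .ad_node(y, list(x, w), function(g, nd) {
        xv <- nd$parents[[1]]$value
        wv <- nd$parents[[2]]$value
        gx <- if (nd$parents[[1]]$requires_grad)
            .conv2d_fwd(g, .flip_kernel(wv), as.integer(dilation)) else NULL
        gw <- if (nd$parents[[2]]$requires_grad)
            .conv2d_gradw(xv, g, dim(wv)[1], dim(wv)[2], as.integer(dilation)) else NULL
        list(gx, gw)
    })
}

# Fused ConvLSTM sequence: gx is the batched input-path gate pre-activation
# stack (H, W, 4C, N) with channel blocks ordered (f, i, c, o); Wh the
# concatenated recurrent kernel. Forward and backprop-through-time run in
# compiled code; the node caches the gate/cell states.
ad_convlstm <- function(gx, Wh, Wcf, Wci, Wco, bf, bi, bc, bo,
                        activation = "relu") {
    act <- if (activation == "tanh") 1L else 0L
    fw <- .convlstm_fwd(gx$value, Wh$value, Wcf$value, Wci$value, Wco$value,
                        bf$value, bi$value, bc$value, bo$value, act)
    .ad_node(fw$h, list(gx, Wh, Wcf, Wci, Wco, bf, bi, bc, bo),
             function(g, nd) {
        bw <- .convlstm_bwd(g, fw, Wh$value, Wcf$value, Wci$value, Wco$value, act)
        list(bw$dgx, bw$dWh, bw$dWcf, bw$dWci, bw$dWco,
             as.numeric(bw$dbf), as.numeric(bw$dbi), as.numeric(bw$dbc),
             as.numeric(bw$dbo))
    })
}

## ---- batch normalization ----------------------------------------------------

# Per-channel batch normalization over (H, W, N). `layer` is an environment that
# carries running statistics; mode "train" uses batch moments and updates the
# running averages, "infer" uses the stored averages, "identity" standardizes
# with mu = 0, var = 1 (exposed for unit tests).
ad_batchnorm <- function(x, gamma, beta, layer, mode = "train", eps = 1e-5,
                         momentum = 0.1) {
    x <- .as_node(x)
    d <- dim(x$value)
    m <- d[1] * d[2] * d[4]
    if (mode == "train") {
        mu <- .csum(x$value) / m
        v <- pmax(as.numeric(.cdot_c(x$value, x$value)) / m - mu^2, 0)
        layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
        layer$running_var <- (1 - momentum) * layer$running_var + momentum * v
    } else if (mode == "infer") {
        mu <- layer$running_mean
        v <- layer$running_var
    } else {  # identity
        mu <- numeric(d[3])
        v <- rep(1, d[3])
    }
    ivar <- 1 / sqrt(v + eps)
    a <- gamma$value * ivar
    y <- .cscale_shift(x$value, a, beta$value - mu * a)
    batch_mode <- (mode == "train")
    zr <- numeric(d[3])
    .ad_node(y, list(x, gamma, beta), function(g, nd) {
        xv <- nd$parents[[1]]$value
        xhat <- .cscale_shift(xv, ivar, -mu * ivar)
        gg <- as.numeric(.cdot_c(g, xhat))
        gb <- .csum(g)
        if (batch_mode) {
            # standard batch-norm backward through the batch moments
            dxhat_s1 <- gb * gamma$value          # csum of dxhat
            dxhat_s2 <- gg * gamma$value          # cdot(dxhat, xhat)
            dx <- .cscale_shift(g, gamma$value * ivar, -dxhat_s1 * ivar / m) -
                  .cscale_shift(xhat, dxhat_s2 * ivar / m, zr)
        } else {
            dx <- .cscale_shift(g, gamma$value * ivar, zr)
        }
        list(dx, gg, gb)
    })
}

# Fused batch normalization + ReLU (one kernel per direction; the backward pass
# recomputes xhat from the stored input instead of materializing it).
ad_bn_relu <- function(x, gamma, beta, layer, mode = "train", eps = 1e-5,
                       momentum = 0.1) {
    x <- .as_node(x)
    d <- dim(x$value)
    m <- d[1] * d[2] * d[4]
    if (mode == "train") {
        mo <- .cmoments(x$value)
        mu <- mo[1, ] / m
        v <- pmax(mo[2, ] / m - mu^2, 0)
        layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
        layer$running_var <- (1 - momentum) * layer$running_var + momentum * v
    } else if (mode == "infer") {
        mu <- layer$running_mean
        v <- layer$running_var
    } else {
        mu <- numeric(d[3])
        v <- rep(1, d[3])
    }
    ivar <- 1 / sqrt(v + eps)
    a <- gamma$value * ivar
    y <- .cscale_shift_relu(x$value, a, beta$value - mu * a)
    batch_mode <- (mode == "train")
    nd <- .ad_node(y, list(x, gamma, beta), function(g, nd) {
        bw <- .bnrelu_bwd(g, nd$value, nd$parents[[1]]$value, gamma$value,
                          ivar, mu, batch_mode)
        list(bw$dx, as.numeric(bw$dgamma), as.numeric(bw$dbeta))
    })
    nd
}

# Slice a kernel's input-channel range (tiny arrays; used to apply one stored
# kernel to two feature stacks as an implicit channel concatenation).
ad_kslice <- function(w, from, to) {
    w <- .as_node(w)
    d <- dim(w$value)
    .ad_node(w$value[, , from:to, , drop = FALSE], list(w), function(g, nd) {
        out <- array(0, dim = d)
        out[, , from:to, ] <- g
        list(out)
    })
}

.bn_layer <- function(channels) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- numeric(channels)
    e$running_var <- rep(1, channels)
    e
}

## ---- loss -------------------------------------------------------------------

# Soft Dice loss 1 - (2*sum(m*g) + eps) / (sum(m) + sum(g) + eps) as a scalar
# node with its analytic gradient.
ad_dice <- function(m, g, eps = 1) {
    m <- .as_node(m)
    gv <- ad_value(g)
    A <- sum(m$value * gv)
    B <- sum(m$value) + sum(gv)
    val <- 1 - (2 * A + eps) / (B + eps)
    .ad_node(val, list(m), function(gr, nd) {
        list(gr * (-(2 * gv * (B + eps) - (2 * A + eps)) / (B + eps)^2))
    })
}

ad_sum <- function(a) {
    a <- .as_node(a)
    d <- dim(a$value)
    .ad_node(sum(a$value), list(a), function(g, nd) list(array(g, dim = d)))
}
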