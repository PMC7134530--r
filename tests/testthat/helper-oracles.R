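# Independent oracles and small fixtures shared across tests.

# Scalar LSTM recurrence evaluated directly from the printed gate equations:
# f = sigma(wxf*x + whf*h + wcf*c + bf), i analogous,
# c' = f*c + i*act(wxc*x + whc*h + bc),
# o = sigma(wxo*x + who*h + wco*c' + bo), h' = o*act(c').
# Written without any package convolution code; at 1x1 spatial grids with 1x1
# kernels the ConvLSTM cell must reduce to exactly this.
scalar_lstm_step <- function(p, x, h, c, activation = "relu") {
    act <- if (activation == "tanh") tanh else function(z) max(z, 0)
    sig <- function(z) 1 / (1 + exp(-z))
    f <- sig(p$wxf * x + p$whf * h + p$wcf * c + p$bf)
    i <- sig(p$wxi * x + p$whi * h + p$wci * c + p$bi)
    cn <- f * c + i * act(p$wxc * x + p$whc * h + p$bc)
    o <- sig(p$wxo * x + p$who * h + p$wco * cn + p$bo)
    list(h = o * act(cn), c = cn)
}

# package ConvLSTM params at 1x1 spatial / 1x1 kernels from scalar weights
scalar_to_conv_params <- function(p) {
    k <- function(v) array(v, dim = c(1, 1, 1, 1))
    m <- function(v) array(v, dim = c(1, 1, 1))
    list(Wxf = k(p$wxf), Whf = k(p$whf), Wxi = k(p$wxi), Whi = k(p$whi),
         Wxc = k(p$wxc), Whc = k(p$whc), Wxo = k(p$wxo), Who = k(p$who),
         Wcf = m(p$wcf), Wci = m(p$wci), Wco = m(p$wco),
         bf = p$bf, bi = p$bi, bc = p$bc, bo = p$bo)
}

random_scalar_params <- function() {
    v <- stats::rnorm(15)
    names(v) <- c("wxf", "whf", "wcf", "bf", "wxi", "whi", "wci", "bi",
                  "wxc", "whc", "bc", "wxo", "who", "wco", "bo")
    as.list(v)
}

# Brute-force trilinear interpolation at one (z, y, x) 0-based coordinate.
trilinear_point <- function(vol, cz, cy, cx) {
    d <- dim(vol)
    z0 <- min(max(floor(cz), 0), d[1] - 2); tz <- cz - z0
    y0 <- min(max(floor(cy), 0), d[2] - 2); ty <- cy - y0
    x0 <- min(max(floor(cx), 0), d[3] - 2); tx <- cx - x0
    g <- function(dz, dy, dx) vol[z0 + dz + 1, y0 + dy + 1, x0 + dx + 1]
    g(0, 0, 0) * (1 - tz) * (1 - ty) * (1 - tx) + g(1, 0, 0) * tz * (1 - ty) * (1 - tx) +
    g(0, 1, 0) * (1 - tz) * ty * (1 - tx) + g(1, 1, 0) * tz * ty * (1 - tx) +
    g(0, 0, 1) * (1 - tz) * (1 - ty) * tx + g(1, 0, 1) * tz * (1 - ty) * tx +
    g(0, 1, 1) * (1 - tz) * ty * tx + g(1, 1, 1) * tz * ty * tx
}

# tiny fast phantom spec for training-contract tests (coarse grid, thick wall)
tiny_phantom_spec <- function(edge = 16L, seed = 1L)
    phantomSpec(gridEdge = edge, spacingMM = 60 / edge, wallThicknessMM = 60 / edge,
                laSemiAxesMM = c(16, 20, 18), nPVTubes = 2L, pvRadiusMM = 5,
                nScarPatches = 3L, scarAngularExtentDeg = 25, seed = seed)

# small model config for contract tests
tiny_mvtt_config <- function(edge = 16L, ...)
    mvttConfig(cubeEdge = as.integer(edge), baseChannels = 2L, ...)
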