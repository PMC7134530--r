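#' Construct a synthetic-phantom specification
#'
#' The phantom emulates the contrast regime of LGE CMR of the left atrium:
#' a bright blood pool (the LA cavity plus tubular pulmonary-vein lumens),
#' signal-nulled dark myocardium/background, and small high-intensity scar
#' patches confined to a thin atrial wall shell just outside the endocardial
#' boundary. Tissue intensities are i.i.d. Gaussian per class plus global
#' Gaussian noise.
#'
#' Defaults give a 48^3 grid at 1.25 mm spacing (60 mm field of view), an
#' ellipsoidal atrium with semi-axes (16, 20, 18) mm, four pulmonary-vein tubes
#' and four scar patches of 18 degrees angular radius — about 10% of the
#' 2.25 mm wall shell. The intensity model (blood 160 +/- 20, myocardium 40
#' +/- 15, scar 220 +/- 20, noise 5) keeps scar above the blood mean + 2 SD so
#' the 2-SD thresholding baseline is well posed, while the upper tail of the
#' blood pool still overlaps scar — the regime in which pure thresholding
#' over-calls and learned context is needed.
#'
#' @param gridEdge cube edge in voxels (>= 8).
#' @param spacingMM isotropic spacing in mm.
#' @param laSemiAxesMM ellipsoid semi-axes (z, y, x) in mm.
#' @param wallThicknessMM wall thickness in mm; 2.25 is the fixed-wall
#'   assumption used for scar-extent quantification.
#' @param nPVTubes number of pulmonary-vein tubes.
#' @param pvRadiusMM tube radius in mm.
#' @param nScarPatches number of scar patches.
#' @param scarAngularExtentDeg angular radius of each patch (degrees).
#' @param intensityModel named list of per-tissue Gaussian parameters.
#' @param noiseSD global additive noise SD.
#' @param noiseEnhancementRate fraction of non-scar wall voxels carrying
#'   isolated scar-like enhancement (noise interference / artefact).
#' @param seed integer seed.
#' @return a \code{\linkS4class{PhantomSpec}}.
#' @export
phantomSpec <- function(gridEdge = 48L, spacingMM = 1.25,
                        laSemiAxesMM = c(16, 20, 18), wallThicknessMM = 2.25,
                        nPVTubes = 4L, pvRadiusMM = 3,
                        nScarPatches = 4L, scarAngularExtentDeg = 18,
                        intensityModel = list(bloodMean = 160, bloodSD = 20,
                                              myoMean = 40, myoSD = 15,
                                              scarMean = 220, scarSD = 20),
                        noiseSD = 5, noiseEnhancementRate = 0.10, seed = 1L) {
    new("PhantomSpec", gridEdge = as.integer(gridEdge), spacingMM = spacingMM,
        laSemiAxesMM = laSemiAxesMM, wallThicknessMM = wallThicknessMM,
        nPVTubes = as.integer(nPVTubes), pvRadiusMM = pvRadiusMM,
        nScarPatches = as.integer(nScarPatches),
        scarAngularExtentDeg = scarAngularExtentDeg,
        intensityModel = intensityModel, noiseSD = noiseSD,
        noiseEnhancementRate = noiseEnhancementRate, seed = as.integer(seed))
}

#' Angular patch radius that targets a given scar fraction
#'
#' A patch is the set of wall-shell voxels within angular distance alpha of a
#' random center direction; on a near-spherical shell it covers a fraction
#' (1 - cos(alpha)) / 2 of the shell, so n non-overlapping patches cover
#' n * (1 - cos(alpha)) / 2.
#'
#' @param fraction target |scar| / |shell|.
#' @param nPatches number of patches.
#' @return angular radius in degrees.
#' @export
scarExtentForFraction <- function(fraction, nPatches) {
    stopifnot(fraction > 0, fraction < 1, nPatches >= 1)
    acos(1 - 2 * fraction / nPatches) * 180 / pi
}

# Voxel-center coordinates in mm relative to the cube center, per axis.
.axis_mm <- function(edge, sp) (seq_len(edge) - (edge + 1) / 2) * sp

#' Generate one synthetic phantom
#'
#' Deterministic given \code{spec@seed}: the anatomy is an ellipsoid with
#' pulmonary-vein tubes attached near its superior pole, the wall shell is the
#' set of outside voxels within \code{wallThicknessMM} of the anatomy, and scar
#' patches are contiguous angular sectors of that shell. The recorded
#' \code{trueScarFraction} is |scar| / |shell|.
#'
#' @param spec a \code{PhantomSpec}.
#' @return a \code{\linkS4class{PhantomSample}}.
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec@seed)

    e <- spec@gridEdge
    sp <- spec@spacingMM
    ax <- .axis_mm(e, sp)
    Z <- array(rep(ax, times = e * e), dim = c(e, e, e))
    Y <- array(rep(rep(ax, each = e), times = e), dim = c(e, e, e))
    X <- array(rep(ax, each = e * e), dim = c(e, e, e))

    s <- spec@laSemiAxesMM
    anatomy <- (Z / s[1])^2 + (Y / s[2])^2 + (X / s[3])^2 <= 1

    # PV tubes: cylinders leaving the superior pole region, tilted outward.
    if (spec@nPVTubes > 0L) {
        azim <- runif(spec@nPVTubes, 0, 2 * pi)
        polar <- runif(spec@nPVTubes, 25, 45) * pi / 180
        for (i in seq_len(spec@nPVTubes)) {
            dvec <- c(cos(polar[i]),
                      sin(polar[i]) * sin(azim[i]),
                      sin(polar[i]) * cos(azim[i]))  # (z, y, x), +z superior
            # start on the ellipsoid surface along dvec
            tsurf <- 1 / sqrt(sum((dvec / s)^2))
            p0 <- 0.9 * tsurf * dvec
            dz <- Z - p0[1]; dy <- Y - p0[2]; dx <- X - p0[3]
            tproj <- dz * dvec[1] + dy * dvec[2] + dx * dvec[3]
            r2 <- (dz - tproj * dvec[1])^2 + (dy - tproj * dvec[2])^2 +
                  (dx - tproj * dvec[3])^2
            anatomy <- anatomy | (tproj >= 0 & r2 <= spec@pvRadiusMM^2)
        }
    }

    shell <- .wall_shell_mask(anatomy, rep(sp, 3), spec@wallThicknessMM)

    scar <- array(FALSE, dim = dim(anatomy))
    if (spec@nScarPatches > 0L && any(shell)) {
        # each patch is a contiguous angular sector: the shell voxels angularly
        # nearest a random center direction, sized to the nominal spherical-cap
        # coverage (1 - cos(alpha)) / 2 of the shell. Directions are measured in
        # ellipsoid-normalized coordinates so coverage is uniform over the wall,
        # and sizing by voxel count keeps the realized fraction on target up to
        # rounding regardless of shell discretization.
        alpha <- spec@scarAngularExtentDeg * pi / 180
        npatch <- round((1 - cos(alpha)) / 2 * sum(shell))
        sidx <- which(shell)
        sdir <- cbind((Z[sidx] / s[1]), (Y[sidx] / s[2]), (X[sidx] / s[3]))
        sdir <- sdir / pmax(sqrt(rowSums(sdir^2)), 1e-12)
        centers <- matrix(0, 0, 3)
        tries <- 0L
        while (nrow(centers) < spec@nScarPatches && tries < 200L) {
            tries <- tries + 1L
            u <- rnorm(3)
            u <- u / sqrt(sum(u^2))
            # keep patch centers apart so the sectors stay disjoint
            if (nrow(centers) && any(acos(pmin(pmax(centers %*% u, -1), 1)) < 2 * alpha))
                next
            centers <- rbind(centers, u)
        }
        taken <- logical(length(sidx))
        for (i in seq_len(nrow(centers))) {
            ang <- acos(pmin(pmax(sdir %*% centers[i, ], -1), 1))
            ang[taken] <- Inf
            pick <- order(ang)[seq_len(min(npatch, sum(!taken)))]
            taken[pick] <- TRUE
            scar[sidx[pick]] <- TRUE
        }
    }

    im <- spec@intensityModel
    n <- length(anatomy)
    img <- rnorm(n, im$myoMean, im$myoSD)
    nb <- sum(anatomy)
    img[anatomy] <- rnorm(nb, im$bloodMean, im$bloodSD)
    ns <- sum(scar)
    if (ns) img[scar] <- rnorm(ns, im$scarMean, im$scarSD)
    # enhanced noise interference: isolated non-scar wall voxels carrying
    # scar-like intensity (nulling failures / artefacts). These are NOT scar in
    # the ground truth — an intensity rule cannot separate them, spatial
    # context can (scar forms contiguous sectors, interference is scattered).
    if (spec@noiseEnhancementRate > 0) {
        cand <- which(shell & !scar)
        nn <- round(spec@noiseEnhancementRate * length(cand))
        if (nn > 0) {
            pick <- sample(cand, nn)
            img[pick] <- rnorm(nn, im$scarMean, im$scarSD)
        }
    }
    if (spec@noiseSD > 0) img <- img + rnorm(n, 0, spec@noiseSD)
    img <- array(img, dim = dim(anatomy))

    frac <- if (any(shell)) sum(scar) / sum(shell) else 0

    stopifnot(!any(scar & !shell), !any(scar & anatomy))

    new("PhantomSample",
        image = Volume(img, spacing = rep(sp, 3)),
        anatomy = LabelVolume(array(as.integer(anatomy), dim = dim(anatomy)),
                              spacing = rep(sp, 3)),
        scar = LabelVolume(array(as.integer(scar), dim = dim(scar)),
                           spacing = rep(sp, 3)),
        trueScarFraction = frac, spec = spec)
}

#' Generate a reproducible cohort of phantoms
#'
#' Per-sample seeds are derived by fixed arithmetic (\code{seed + index}), so a
#' cohort is reproducible across platforms and samples have distinct scar
#' placements.
#'
#' @param spec template \code{PhantomSpec} (its own seed is ignored).
#' @param n cohort size (>= 1).
#' @param seed root seed.
#' @return list of \code{PhantomSample}.
#' @export
generateCohort <- function(spec, n, seed = spec@seed) {
    n <- as.integer(n)
    if (n < 1L) stop("n must be >= 1")
    lapply(seq_len(n), function(i) {
        s <- spec
        s@seed <- as.integer(seed + i)
        generatePhantom(s)
    })
}

#' Atrial wall shell at a fixed thickness
#'
#' The set of voxels outside the anatomy whose Euclidean distance to the
#' anatomy is at most \code{thicknessMM} — i.e. a spherical dilation of the
#' anatomy by the wall thickness, minus the anatomy itself.
#'
#' @param anatomy a \code{LabelVolume} (non-empty).
#' @param spacing voxel spacing in mm (z, y, x); defaults to the mask's.
#' @param thicknessMM wall thickness in mm (2.25 = fixed-wall assumption).
#' @return a \code{LabelVolume} of shell voxels.
#' @export
wallShell <- function(anatomy, spacing = NULL, thicknessMM = 2.25) {
    stopifnot(is(anatomy, "LabelVolume"))
    if (is.null(spacing)) spacing <- anatomy@spacing
    a <- anatomy@labels > 0
    if (!any(a)) stop("anatomy mask is empty")
    sh <- .wall_shell_mask(a, spacing, thicknessMM)
    LabelVolume(array(as.integer(sh), dim = dim(sh)), spacing = spacing,
                origin = anatomy@origin)
}

# Exact Euclidean dilation by enumerating all voxel offsets with
# ||offset * spacing|| <= thickness, then erasing the anatomy.
.wall_shell_mask <- function(a, spacing, thickness) {
    d <- dim(a)
    if (thickness <= 0) return(array(FALSE, dim = d))
    rmax <- floor(thickness / spacing)
    offs <- expand.grid(dz = -rmax[1]:rmax[1], dy = -rmax[2]:rmax[2],
                        dx = -rmax[3]:rmax[3])
    dist <- sqrt((offs$dz * spacing[1])^2 + (offs$dy * spacing[2])^2 +
                 (offs$dx * spacing[3])^2)
    offs <- offs[dist <= thickness, , drop = FALSE]
    dil <- array(FALSE, dim = d)
    for (i in seq_len(nrow(offs))) {
        oz <- offs$dz[i]; oy <- offs$dy[i]; ox <- offs$dx[i]
        src_z <- max(1, 1 - oz):min(d[1], d[1] - oz)
        src_y <- max(1, 1 - oy):min(d[2], d[2] - oy)
        src_x <- max(1, 1 - ox):min(d[3], d[3] - ox)
        dil[src_z + oz, src_y + oy, src_x + ox] <-
            dil[src_z + oz, src_y + oy, src_x + ox] | a[src_z, src_y, src_x]
    }
    dil & !a
}

# save/restore the global RNG state so generation is a pure function of seed
.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
    else NULL
}
.Random.seed_restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
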