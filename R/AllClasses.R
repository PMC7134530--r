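#' @import methods
NULL

#' Volume: a 3D scalar intensity grid with voxel spacing
#'
#' The unit of I/O and inference. Voxels are indexed \code{(z, y, x)} (axial =
#' fixed z, sagittal = fixed x, coronal = fixed y, matching transverse
#' acquisition), spacing and origin are in mm and follow the same axis order.
#'
#' @slot voxels 3D numeric array indexed (z, y, x), all values finite.
#' @slot spacing positive numeric length 3, mm per voxel along (z, y, x).
#' @slot origin numeric length 3, mm.
#' @export
setClass("Volume", representation(voxels = "array", spacing = "numeric",
                                  origin = "numeric"))

setValidity("Volume", function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3D array")
    if (any(dim(v) < 1L)) return("all grid dimensions must be >= 1")
    if (!all(is.finite(v))) return("all voxel values must be finite")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) return("spacing must be 3 strictly positive values")
    if (length(object@origin) != 3L) return("origin must have length 3")
    TRUE
})

#' @param voxels 3D numeric array indexed (z, y, x).
#' @param spacing voxel spacing in mm along (z, y, x).
#' @param origin grid origin in mm.
#' @rdname Volume-class
#' @export
Volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("Volume", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' LabelVolume: a binary mask aligned voxel-for-voxel with a Volume
#'
#' @slot labels 3D integer-valued array with values in \{0, 1\}.
#' @slot spacing,origin as in \code{\linkS4class{Volume}}.
#' @export
setClass("LabelVolume", representation(labels = "array", spacing = "numeric",
                                       origin = "numeric"))

setValidity("LabelVolume", function(object) {
    l <- object@labels
    if (length(dim(l)) != 3L) return("labels must be a 3D array")
    if (!all(l %in% c(0, 1))) return("labels must take values in {0, 1}")
    TRUE
})

#' @param labels 3D array of 0/1 values.
#' @param spacing,origin as in \code{Volume}.
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(labels) <- "integer"
    new("LabelVolume", labels = labels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' ViewDecomposition: ordered axial/sagittal/coronal 2D slice stacks
#'
#' Each stack is a 3D array (H, W, N): axial planes are (y, x) indexed by z,
#' sagittal planes are (z, y) indexed by x, coronal planes are (z, x) indexed
#' by y. Slicing is a pure re-indexing; recomposition is voxel-exact.
#'
#' @slot axial,sagittal,coronal 3D arrays of 2D planes.
#' @slot sourceDim the shape of the source grid.
#' @export
setClass("ViewDecomposition",
         representation(axial = "array", sagittal = "array", coronal = "array",
                        sourceDim = "integer"))

setValidity("ViewDecomposition", function(object) {
    d <- object@sourceDim
    if (dim(object@axial)[3] != d[1]) return("axial plane count must equal dim z")
    if (dim(object@sagittal)[3] != d[3]) return("sagittal plane count must equal dim x")
    if (dim(object@coronal)[3] != d[2]) return("coronal plane count must equal dim y")
    TRUE
})

#' PhantomSpec: parameters of the synthetic LGE-like phantom
#'
#' @slot gridEdge cube edge in voxels.
#' @slot spacingMM isotropic voxel spacing in mm.
#' @slot laSemiAxesMM semi-axes of the atrial ellipsoid (z, y, x) in mm.
#' @slot wallThicknessMM atrial wall thickness in mm (default 2.25).
#' @slot nPVTubes number of pulmonary-vein tubes attached near the superior pole.
#' @slot pvRadiusMM tube radius in mm.
#' @slot nScarPatches number of scar patches (contiguous angular sectors).
#' @slot scarAngularExtentDeg angular radius of each patch in degrees.
#' @slot intensityModel named list: bloodMean, bloodSD, myoMean, myoSD, scarMean,
#'   scarSD — per-tissue Gaussian intensity parameters.
#' @slot noiseSD global additive Gaussian noise.
#' @slot noiseEnhancementRate fraction of non-scar wall-shell voxels that carry
#'   scar-like enhanced intensity (isolated noise interferences / artefacts —
#'   the confound that makes pure intensity rules over-call scar).
#' @slot seed integer seed; generation is deterministic given the seed.
#' @export
setClass("PhantomSpec",
         representation(gridEdge = "integer", spacingMM = "numeric",
                        laSemiAxesMM = "numeric", wallThicknessMM = "numeric",
                        nPVTubes = "integer", pvRadiusMM = "numeric",
                        nScarPatches = "integer", scarAngularExtentDeg = "numeric",
                        intensityModel = "list", noiseSD = "numeric",
                        noiseEnhancementRate = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    im <- object@intensityModel
    need <- c("bloodMean", "bloodSD", "myoMean", "myoSD", "scarMean", "scarSD")
    if (!all(need %in% names(im)))
        return(paste("intensityModel must contain", paste(need, collapse = ", ")))
    if (im$scarMean <= im$bloodMean + 2 * im$bloodSD)
        return("scarMean must exceed bloodMean + 2*bloodSD (2-SD baseline well-posedness)")
    if (im$myoMean >= im$bloodMean)
        return("myoMean must be below bloodMean (nulled myocardium)")
    if (object@wallThicknessMM < object@spacingMM)
        return("wallThicknessMM must be >= spacingMM")
    if (object@gridEdge < 8L) return("gridEdge must be >= 8")
    if (object@nPVTubes < 0L || object@nScarPatches < 0L)
        return("tube and patch counts must be nonnegative")
    if (object@noiseSD < 0) return("noiseSD must be nonnegative")
    if (object@noiseEnhancementRate < 0 || object@noiseEnhancementRate >= 1)
        return("noiseEnhancementRate must be in [0, 1)")
    TRUE
})

#' PhantomSample: synthetic volume with ground-truth anatomy and scar
#'
#' @slot image the intensity \code{Volume}.
#' @slot anatomy \code{LabelVolume} of the LA cavity plus PV lumens.
#' @slot scar \code{LabelVolume} of scar voxels (a subset of the wall shell).
#' @slot trueScarFraction |scar| / |wall shell| at the spec's wall thickness.
#' @slot spec the generating \code{PhantomSpec}.
#' @export
setClass("PhantomSample",
         representation(image = "Volume", anatomy = "LabelVolume",
                        scar = "LabelVolume", trueScarFraction = "numeric",
                        spec = "PhantomSpec"))

#' MVTTConfig: architecture and ablation switches of the MVTT model
#'
#' Every model variant of the ablation grid is a configuration: \code{SV+CLSTM}
#' = no multiview, \code{MV} = no ConvLSTM, \code{MV+CLSTM} = no attention,
#' \code{S-LA/PV} / \code{S-Scar} = single-task, \code{K5} = 5x5 kernels,
#' \code{AFT} = tanh state activation, \code{NDC} = plain (undilated) convs.
#'
#' @slot useMultiview include sagittal/coronal dilated residual subnetworks.
#' @slot useConvLSTM axial sequence learning via ConvLSTM (else per-slice convs).
#' @slot useAttention attention-gate the scar branch input.
#' @slot kernelSize odd kernel size (3 or 5).
#' @slot convlstmActivation "relu" (default) or "tanh".
#' @slot convMode "hdc" (dilation cycle) or "plain".
#' @slot tasks "both", "anatomy_only" or "scar_only".
#' @slot cubeEdge isotropic processing grid edge.
#' @slot baseChannels feature width of the subnetworks.
#' @slot dilationCycle HDC dilation rates.
#' @export
setClass("MVTTConfig",
         representation(useMultiview = "logical", useConvLSTM = "logical",
                        useAttention = "logical", kernelSize = "integer",
                        convlstmActivation = "character", convMode = "character",
                        tasks = "character", cubeEdge = "integer",
                        baseChannels = "integer", dilationCycle = "integer"))

setValidity("MVTTConfig", function(object) {
    if (object@kernelSize %% 2L == 0L) return("kernelSize must be odd")
    if (!object@convlstmActivation %in% c("relu", "tanh"))
        return("convlstmActivation must be 'relu' or 'tanh'")
    if (!object@convMode %in% c("hdc", "plain"))
        return("convMode must be 'hdc' or 'plain'")
    if (!object@tasks %in% c("both", "anatomy_only", "scar_only"))
        return("tasks must be 'both', 'anatomy_only' or 'scar_only'")
    if (object@cubeEdge < 8L) return("cubeEdge must be >= 8")
    if (!length(object@dilationCycle)) return("dilationCycle must be non-empty")
    TRUE
})

#' SegmentationOutput: paired probability volumes for anatomy and scar
#'
#' @slot anatomyProb probability \code{Volume} of the LA anatomy (m_l), or NULL
#'   array for scar-only models.
#' @slot scarProb probability \code{Volume} of the scar (m_as).
#' @export
setClass("SegmentationOutput",
         representation(anatomyProb = "ANY", scarProb = "ANY"))

#' TrainConfig: optimizer and protocol settings
#'
#' @slot lrInit initial learning rate (0.001).
#' @slot lrDecay multiplicative decay per epoch (0.98).
#' @slot maxEpochs maximum epochs.
#' @slot earlyStopPatience epochs without validation improvement before stopping.
#' @slot batchSize volumes per gradient step (slice stacks of one volume each).
#' @slot seed integer seed for initialization and shuffling.
#' @slot kFolds folds for cross-validation splitting.
#' @export
setClass("TrainConfig",
         representation(lrInit = "numeric", lrDecay = "numeric",
                        maxEpochs = "integer", earlyStopPatience = "integer",
                        batchSize = "integer", seed = "integer",
                        kFolds = "integer"))

setValidity("TrainConfig", function(object) {
    if (object@lrDecay <= 0 || object@lrDecay > 1)
        return("lrDecay must be in (0, 1]")
    if (object@earlyStopPatience < 1L) return("earlyStopPatience must be >= 1")
    TRUE
})

setMethod("show", "Volume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("Volume %dx%dx%d (z,y,x), spacing %s mm, range [%.3g, %.3g]\n",
                d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = "x"),
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@labels)
    cat(sprintf("LabelVolume %dx%dx%d, %d foreground voxels\n",
                d[1], d[2], d[3], sum(object@labels)))
})

setMethod("show", "PhantomSample", function(object) {
    cat(sprintf("PhantomSample: edge %d, scar fraction %.4f (%d scar voxels)\n",
                object@spec@gridEdge, object@trueScarFraction, sum(object@scar@labels)))
})

#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname Volume-class
#' @export
setMethod("voxels", "Volume", function(x) x@voxels)

#' @export
setGeneric("labels")
#' @rdname LabelVolume-class
#' @export
setMethod("labels", "LabelVolume", function(object, ...) object@labels)

#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname Volume-class
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)
#' @rdname LabelVolume-class
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)

#' @export
setGeneric("trueScarFraction", function(x) standardGeneric("trueScarFraction"))
#' @rdname PhantomSample-class
#' @export
setMethod("trueScarFraction", "PhantomSample", function(x) x@trueScarFraction)
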