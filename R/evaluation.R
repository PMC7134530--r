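#' Voxelwise confusion counts between two binary masks
#'
#' @param pred predicted \code{LabelVolume} (or 0/1 array).
#' @param truth ground-truth \code{LabelVolume} (or 0/1 array).
#' @return list(tp, fp, tn, fn); the four counts sum to the voxel total.
#' @export
confusionCounts <- function(pred, truth) {
    p <- if (is(pred, "LabelVolume")) pred@labels else pred
    g <- if (is(truth, "LabelVolume")) truth@labels else truth
    if (!identical(dim(p), dim(g)))
        stop("shape mismatch: ", paste(dim(p), collapse = "x"), " vs ",
             paste(dim(g), collapse = "x"))
    if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
        stop("masks must be binary")
    p <- p > 0; g <- g > 0
    list(tp = sum(p & g), fp = sum(p & !g), tn = sum(!p & !g), fn = sum(!p & g))
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy (tp+tn)/total, sensitivity tp/(tp+fn), specificity tn/(tn+fp) and
#' Dice 2tp/(2tp+fp+fn). A metric with a zero denominator is reported as NaN
#' with a warning.
#'
#' @param counts list(tp, fp, tn, fn).
#' @return list(accuracy, sensitivity, specificity, dice).
#' @export
segmentationMetrics <- function(counts) {
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
    total <- tp + fp + tn + fn
    if (total == 0) stop("no voxels compared")
    ratio <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined (zero denominator); reporting NaN")
            return(NaN)
        }
        num / den
    }
    list(accuracy = (tp + tn) / total,
         sensitivity = ratio(tp, tp + fn, "sensitivity"),
         specificity = ratio(tn, tn + fp, "specificity"),
         dice = ratio(2 * tp, 2 * tp + fp + fn, "dice"))
}

#' Scar extent as a percentage of the atrial wall compartment
#'
#' 100 * |scar| / |wall shell|, with the shell derived from the anatomy at a
#' fixed wall thickness (2.25 mm by default). Volumetric definition: voxel
#' counts at equal spacing are proportional to tissue volumes.
#'
#' @param scar scar \code{LabelVolume}.
#' @param anatomy anatomy \code{LabelVolume} (non-empty).
#' @param spacing voxel spacing in mm; defaults to the anatomy's.
#' @param wallMM wall thickness in mm.
#' @return scar percentage in [0, 100] (can exceed 100 if the predicted scar is
#'   larger than the shell).
#' @export
scarPercentage <- function(scar, anatomy, spacing = NULL, wallMM = 2.25) {
    stopifnot(is(scar, "LabelVolume"), is(anatomy, "LabelVolume"))
    if (!any(anatomy@labels > 0)) stop("anatomy mask is empty")
    if (is.null(spacing)) spacing <- anatomy@spacing
    shell <- wallShell(anatomy, spacing, wallMM)
    100 * sum(scar@labels) / sum(shell@labels)
}

#' Pearson correlation between estimates and a reference
#'
#' @param estimate,reference numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return the sample Pearson correlation coefficient.
#' @export
pearsonCorrelation <- function(estimate, reference) {
    if (length(estimate) != length(reference)) stop("length mismatch")
    if (length(estimate) < 3L) stop("need at least 3 pairs")
    if (stats::var(estimate) == 0 || stats::var(reference) == 0)
        stop("zero variance")
    stats::cor(estimate, reference, method = "pearson")
}

#' Bland-Altman agreement statistics
#'
#' Bias = mean(estimate - reference); limits of agreement = bias +/- 1.96 times
#' the sample (n-1 denominator) standard deviation of the differences.
#'
#' @param estimate,reference numeric vectors of equal length >= 2.
#' @return list(bias, loaLow, loaHigh, sd).
#' @export
blandAltman <- function(estimate, reference) {
    if (length(estimate) != length(reference)) stop("length mismatch")
    if (length(estimate) < 2L) stop("need at least 2 pairs")
    d <- estimate - reference
    bias <- mean(d)
    s <- stats::sd(d)
    list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s, sd = s)
}
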