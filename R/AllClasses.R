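#' @import methods
NULL

GEOM_TOL_MM <- 1e-4

#' ImageGrid: a 3D scalar lattice with physical geometry
#'
#' The universal carrier for CT volumes (HU), dose grids (Gy) and Jacobian
#' maps (unitless). Voxel indexing is 1-based in R; the world position of
#' voxel \code{(i,j,k)} is \code{origin + (c(i,j,k) - 1) * spacing}. Grids
#' are axis-aligned: no direction cosines are carried, because the analysis
#' never needs oblique geometry and the phantom emits axis-aligned data.
#'
#' @slot values 3D numeric array of scalars (HU, Gy or unitless).
#' @slot spacing numeric(3), voxel edge lengths in mm; all > 0.
#' @slot origin numeric(3), world coordinates (mm) of the first voxel centre.
#' @export
setClass("ImageGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, c(2, 2, 2)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("ImageGrid", function(object) {
  msgs <- character()
  if (length(dim(object@values)) != 3L)
    msgs <- c(msgs, sprintf("values must be a 3D array, got %dD",
                            length(dim(object@values))))
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values (mm)")
  if (any(is.nan(object@values)) || any(is.infinite(object@values)))
    msgs <- c(msgs, "values must not contain NaN or Inf")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImageGrid
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world position of the first voxel, mm.
#' @return An \linkS4class{ImageGrid}.
#' @examples
#' g <- ImageGrid(array(-850, c(8, 8, 8)), spacing = c(2, 2, 2))
#' gridSpacing(g)
#' @export
ImageGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' BinaryMask: a boolean volume tied to a reference geometry
#'
#' Lung masks, vessel contours and dose-bin contours. Geometry must equal
#' its reference grid exactly; the pipeline never resamples implicitly.
#'
#' @slot values 3D logical array.
#' @slot spacing,origin as in \linkS4class{ImageGrid}.
#' @export
setClass("BinaryMask", contains = "ImageGrid")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@values))
    return("mask values must be a logical array")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param values 3D logical (or 0/1 numeric, coerced) array.
#' @param spacing,origin geometry, or supply \code{reference} to copy it.
#' @param reference optional \linkS4class{ImageGrid} whose geometry to adopt.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       reference = NULL) {
  if (!is.logical(values)) {
    storage.mode(values) <- "logical"
  }
  values[is.na(values)] <- FALSE
  if (!is.null(reference)) {
    spacing <- gridSpacing(reference)
    origin <- gridOrigin(reference)
  }
  new("BinaryMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' VectorField: per-voxel displacement between breathing phases/timepoints
#'
#' @slot u 4D numeric array (nx, ny, nz, 3); displacement components in mm.
#' @slot spacing,origin geometry as for \linkS4class{ImageGrid}.
#' @export
setClass("VectorField",
  representation(u = "array", spacing = "numeric", origin = "numeric"))

setValidity("VectorField", function(object) {
  d <- dim(object@u)
  if (length(d) != 4L || d[4] != 3L)
    return("u must be a 4D array with 3 components in the last dimension")
  if (any(!is.finite(object@u))) return("displacements must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  TRUE
})

#' Construct a VectorField
#' @param u 4D array (nx, ny, nz, 3), mm.
#' @param spacing,origin geometry; or copy from \code{reference}.
#' @param reference optional \linkS4class{ImageGrid}.
#' @return A \linkS4class{VectorField}.
#' @export
VectorField <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        reference = NULL) {
  if (!is.null(reference)) {
    spacing <- gridSpacing(reference)
    origin <- gridOrigin(reference)
  }
  new("VectorField", u = u, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' DynamicSeries: time-ordered, co-registered contrast-enhanced frames
#'
#' Carrier of contrast kinetics: an ordered stack of \linkS4class{ImageGrid}
#' frames on one geometry with strictly increasing acquisition times, plus
#' the number of pre-contrast frames acquired before injection began.
#'
#' @slot frames list of \linkS4class{ImageGrid}, one per acquisition.
#' @slot times numeric acquisition times, seconds, strictly increasing.
#' @slot nPrecontrast integer count of frames acquired before injection.
#' @export
setClass("DynamicSeries",
  representation(frames = "list", times = "numeric",
                 nPrecontrast = "integer"))

setValidity("DynamicSeries", function(object) {
  n <- length(object@frames)
  if (n < 2L) return("a dynamic series needs at least 2 frames")
  if (length(object@times) != n)
    return("times must have one entry per frame")
  if (any(diff(object@times) <= 0))
    return("acquisition times must be strictly increasing")
  np <- object@nPrecontrast
  if (np < 1L || np >= n)
    return("nPrecontrast must satisfy 0 < nPrecontrast < n_frames")
  ref <- object@frames[[1]]
  for (f in object@frames) {
    if (!identical(dim(f@values), dim(ref@values)) ||
        max(abs(f@spacing - ref@spacing)) > GEOM_TOL_MM ||
        max(abs(f@origin - ref@origin)) > GEOM_TOL_MM)
      return("all frames must share one geometry")
  }
  TRUE
})

#' Construct a DynamicSeries
#' @param frames list of \linkS4class{ImageGrid} sharing one geometry.
#' @param times acquisition times in seconds, strictly increasing.
#' @param nPrecontrast frames acquired before contrast injection.
#' @return A \linkS4class{DynamicSeries}.
#' @export
DynamicSeries <- function(frames, times, nPrecontrast) {
  new("DynamicSeries", frames = frames, times = as.numeric(times),
      nPrecontrast = as.integer(nPrecontrast))
}

#' DoseBin: one 10 Gy-wide isodose shell
#'
#' @slot lo,hi dose interval in Gy, half-open \code{[lo, hi)} (the top bin
#'   of an edge set is closed).
#' @slot mask \linkS4class{BinaryMask} of the in-lung bin voxels.
#' @slot volumeCc mask volume in cc.
#' @slot eqd2 equivalent dose in 2 Gy fractions for the bin, Gy.
#' @slot laterality \code{"irradiated"} or \code{"control"} (mirrored).
#' @slot label bin label by representative dose, e.g. \code{"20Gy"}.
#' @export
setClass("DoseBin",
  representation(lo = "numeric", hi = "numeric", mask = "BinaryMask",
                 volumeCc = "numeric", eqd2 = "numeric",
                 laterality = "character", label = "character"))

setValidity("DoseBin", function(object) {
  if (object@lo >= object@hi) return("lo must be < hi")
  if (!object@laterality %in% c("irradiated", "control"))
    return("laterality must be 'irradiated' or 'control'")
  if (object@volumeCc < 0) return("volumeCc must be >= 0")
  TRUE
})

#' ModeFit: bimodal histogram fit of in-lung HU values
#'
#' Mode 1 is aerated parenchyma (around -850 HU); mode 2 is the
#' soft-tissue/blood mode near +40 HU whose spread sets the vessel
#' threshold. The Gaussian convention FWHM = 2.35 sigma links the measured
#' full width at half maximum to the standard deviation.
#'
#' @slot mode1Mean,mode2Mean mode locations, HU.
#' @slot mode2Fwhm full width at half maximum of mode 2, HU.
#' @slot mode2Sigma \code{mode2Fwhm / 2.35}, HU.
#' @slot histogram data.frame with columns \code{mid} (bin centre, HU),
#'   \code{count} (raw) and \code{smoothed}.
#' @export
setClass("ModeFit",
  representation(mode1Mean = "numeric", mode2Mean = "numeric",
                 mode2Fwhm = "numeric", mode2Sigma = "numeric",
                 histogram = "data.frame"))

setValidity("ModeFit", function(object) {
  if (object@mode1Mean >= object@mode2Mean)
    return("mode1Mean must be < mode2Mean")
  if (object@mode2Fwhm <= 0) return("mode2Fwhm must be > 0")
  if (abs(object@mode2Sigma - object@mode2Fwhm / 2.35) > 1e-9)
    return("mode2Sigma must equal mode2Fwhm / 2.35 exactly")
  TRUE
})

#' FractionationScheme: prescription parameters for EQD2 conversion
#'
#' Holds the prescribed total dose D, the number of fractions and the
#' lung alpha/beta ratio of the linear-quadratic model.
#'
#' @slot rxTotal prescribed total dose, Gy.
#' @slot nFractions number of fractions.
#' @slot alphaBeta alpha/beta ratio, Gy (3 for lung tissue).
#' @export
setClass("FractionationScheme",
  representation(rxTotal = "numeric", nFractions = "numeric",
                 alphaBeta = "numeric"))

setValidity("FractionationScheme", function(object) {
  if (object@rxTotal <= 0 || object@nFractions <= 0 || object@alphaBeta <= 0)
    return("rxTotal, nFractions and alphaBeta must all be positive")
  TRUE
})

#' Construct a FractionationScheme
#' @param rxTotal prescribed total dose, Gy.
#' @param nFractions number of fractions.
#' @param alphaBeta alpha/beta ratio in Gy; 3 Gy is the lung default.
#' @return A \linkS4class{FractionationScheme}.
#' @examples
#' FractionationScheme(60, 5)   # swine research course
#' FractionationScheme(50, 5)   # typical SBRT prescription
#' @export
FractionationScheme <- function(rxTotal, nFractions, alphaBeta = 3) {
  new("FractionationScheme", rxTotal = as.numeric(rxTotal),
      nFractions = as.numeric(nFractions), alphaBeta = as.numeric(alphaBeta))
}

#' LinearFit: ordinary least squares fit with correlation statistics
#'
#' @slot slope,intercept OLS coefficients.
#' @slot rSquared coefficient of determination.
#' @slot pearsonR Pearson correlation coefficient of (x, y).
#' @slot pValue two-sided p for the correlation (t-distribution transform);
#'   NA when n < 3.
#' @slot n number of points.
#' @export
setClass("LinearFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", pearsonR = "numeric",
                 pValue = "numeric", n = "integer"))

setValidity("LinearFit", function(object) {
  if (is.finite(object@pearsonR) &&
      (object@pearsonR < -1 - 1e-12 || object@pearsonR > 1 + 1e-12))
    return("pearsonR must lie in [-1, 1]")
  TRUE
})

## ---- accessors -----------------------------------------------------------

#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Accessors for grid-like objects
#'
#' \code{gridValues} returns the voxel array, \code{gridSpacing} the voxel
#' size (mm), \code{gridOrigin} the world position of the first voxel (mm),
#' and \code{gridDim} the array dimensions.
#'
#' @param x an \linkS4class{ImageGrid}, \linkS4class{BinaryMask},
#'   \linkS4class{VectorField} or \linkS4class{DynamicSeries}.
#' @return The requested component.
#' @name gridValues
#' @aliases gridSpacing gridOrigin gridDim
#' @export
setMethod("gridValues", "ImageGrid", function(x) x@values)

#' @rdname gridValues
#' @export
setMethod("gridValues", "VectorField", function(x) x@u)

#' @rdname gridValues
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname gridValues
#' @export
setMethod("gridSpacing", "ImageGrid", function(x) x@spacing)
#' @rdname gridValues
#' @export
setMethod("gridSpacing", "VectorField", function(x) x@spacing)
#' @rdname gridValues
#' @export
setMethod("gridSpacing", "DynamicSeries", function(x) x@frames[[1]]@spacing)

#' @rdname gridValues
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname gridValues
#' @export
setMethod("gridOrigin", "ImageGrid", function(x) x@origin)
#' @rdname gridValues
#' @export
setMethod("gridOrigin", "VectorField", function(x) x@origin)
#' @rdname gridValues
#' @export
setMethod("gridOrigin", "DynamicSeries", function(x) x@frames[[1]]@origin)

#' @rdname gridValues
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname gridValues
#' @export
setMethod("gridDim", "ImageGrid", function(x) dim(x@values))
#' @rdname gridValues
#' @export
setMethod("gridDim", "VectorField", function(x) dim(x@u)[1:3])
#' @rdname gridValues
#' @export
setMethod("gridDim", "DynamicSeries", function(x) dim(x@frames[[1]]@values))

#' Series accessors
#'
#' @param x a \linkS4class{DynamicSeries}.
#' @param i frame index.
#' @return \code{seriesFrames}: list of frames; \code{seriesFrame}: one
#'   frame; \code{seriesTimes}: acquisition times (s); \code{nPrecontrast}:
#'   number of pre-injection frames; \code{nFrames}: frame count.
#' @name seriesFrames
#' @export
seriesFrames <- function(x) x@frames

#' @rdname seriesFrames
#' @export
seriesFrame <- function(x, i) x@frames[[i]]

#' @rdname seriesFrames
#' @export
seriesTimes <- function(x) x@times

#' @rdname seriesFrames
#' @export
nPrecontrast <- function(x) x@nPrecontrast

#' @rdname seriesFrames
#' @export
nFrames <- function(x) length(x@frames)

#' DoseBin accessors
#'
#' @param x a \linkS4class{DoseBin}.
#' @return The requested slot value.
#' @name binLabel
#' @export
binLabel <- function(x) x@label

#' @rdname binLabel
#' @export
binRange <- function(x) c(x@lo, x@hi)

#' @rdname binLabel
#' @export
binMask <- function(x) x@mask

#' @rdname binLabel
#' @export
binVolumeCc <- function(x) x@volumeCc

#' @rdname binLabel
#' @export
binEqd2Gy <- function(x) x@eqd2

#' @rdname binLabel
#' @export
binLaterality <- function(x) x@laterality

#' Coerce a LinearFit to a one-row data.frame
#' @param fit a \linkS4class{LinearFit}.
#' @return data.frame with slope, intercept, r_squared, pearson_r, p_value, n.
#' @export
fitAsDataFrame <- function(fit) {
  data.frame(slope = fit@slope, intercept = fit@intercept,
             r_squared = fit@rSquared, pearson_r = fit@pearsonR,
             p_value = fit@pValue, n = fit@n)
}

## ---- show methods --------------------------------------------------------

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s %dx%dx%d, spacing %s mm, origin %s mm, range [%.4g, %.4g]\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ","),
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask %dx%dx%d, spacing %s mm, %d voxels true (%.2f cc)\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              sum(object@values), maskVolumeCc(object)))
})

setMethod("show", "VectorField", function(object) {
  d <- dim(object@u)
  cat(sprintf(
    "VectorField %dx%dx%d, spacing %s mm, |u| max %.3f mm\n",
    d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = "x"),
    sqrt(max(object@u[, , , 1]^2 + object@u[, , , 2]^2 + object@u[, , , 3]^2))))
})

setMethod("show", "DynamicSeries", function(object) {
  d <- gridDim(object)
  cat(sprintf(
    "DynamicSeries: %d frames (%d pre-contrast), %dx%dx%d, t = %.1f..%.1f s\n",
    length(object@frames), object@nPrecontrast, d[1], d[2], d[3],
    object@times[1], object@times[length(object@times)]))
})

setMethod("show", "DoseBin", function(object) {
  cat(sprintf("DoseBin %s [%g, %g) Gy, %s, %.1f cc, EQD2 %.1f Gy\n",
              object@label, object@lo, object@hi, object@laterality,
              object@volumeCc, object@eqd2))
})

setMethod("show", "ModeFit", function(object) {
  cat(sprintf(
    "ModeFit: mode1 %.1f HU, mode2 %.1f HU, FWHM %.1f HU (sigma %.1f HU)\n",
    object@mode1Mean, object@mode2Mean, object@mode2Fwhm, object@mode2Sigma))
})

setMethod("show", "FractionationScheme", function(object) {
  cat(sprintf("FractionationScheme: %g Gy in %g fx, alpha/beta %g Gy\n",
              object@rxTotal, object@nFractions, object@alphaBeta))
})

setMethod("show", "LinearFit", function(object) {
  cat(sprintf(
    "LinearFit: slope %.4g, intercept %.4g, R^2 %.4f, r %.4f (p %.3g, n %d)\n",
    object@slope, object@intercept, object@rSquared, object@pearsonR,
    object@pValue, object@n))
})
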