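#' @import methods
NULL

#' Accessor generics
#'
#' Small family of accessor generics used across the package's S4 classes.
#' Each class documents which accessors apply to it.
#'
#' @param x an object of one of the package's S4 classes
#' @return The slot value; see the class documentation for units.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("huZero", function(x) standardGeneric("huZero"))

#' @rdname accessors
#' @export
setGeneric("huHundred", function(x) standardGeneric("huHundred"))

#' @rdname accessors
#' @export
setGeneric("huRange", function(x) standardGeneric("huRange"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("gridArray", function(x) standardGeneric("gridArray"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("volumeUl", function(x) standardGeneric("volumeUl"))

#' @rdname accessors
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))

#' @rdname accessors
#' @export
setGeneric("radiusOfGyration", function(x) standardGeneric("radiusOfGyration"))

#' @rdname accessors
#' @export
setGeneric("effectiveRadius", function(x) standardGeneric("effectiveRadius"))

#' @rdname accessors
#' @export
setGeneric("aspectRatio", function(x) standardGeneric("aspectRatio"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname accessors
#' @export
setGeneric("huValues", function(x) standardGeneric("huValues"))

#' @rdname accessors
#' @export
setGeneric("trueConcentration", function(x) standardGeneric("trueConcentration"))

#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname accessors
#' @export
setGeneric("sectionImage", function(x) standardGeneric("sectionImage"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("sectionIndex", function(x) standardGeneric("sectionIndex"))

#' @rdname accessors
#' @export
setGeneric("stepSize", function(x) standardGeneric("stepSize"))

#' @rdname accessors
#' @export
setGeneric("tissueArea", function(x) standardGeneric("tissueArea"))

#' @rdname accessors
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname accessors
#' @export
setGeneric("maskedImage", function(x) standardGeneric("maskedImage"))

#' @rdname accessors
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))

#' @rdname accessors
#' @export
setGeneric("necroticArea", function(x) standardGeneric("necroticArea"))

#' @rdname accessors
#' @export
setGeneric("perSectionAreas", function(x) standardGeneric("perSectionAreas"))

#' @rdname accessors
#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))
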