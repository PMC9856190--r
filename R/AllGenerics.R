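#' @rdname RamanSpectra-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("tissueClass", function(x) standardGeneric("tissueClass"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("tissueComponent", function(x) standardGeneric("tissueComponent"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("polarizationAngle", function(x) standardGeneric("polarizationAngle"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("pointId", function(x) standardGeneric("pointId"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("imagePixels", function(x, i) standardGeneric("imagePixels"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("imageMeta", function(x) standardGeneric("imageMeta"))

#' @rdname RamanSpectra-accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
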