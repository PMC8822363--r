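#' @rdname activations
#' @export
setGeneric("activations", function(x, ...) standardGeneric("activations"))

#' @rdname stimulusMeta
#' @export
setGeneric("stimulusMeta", function(x, ...) standardGeneric("stimulusMeta"))

#' @rdname rdmValues
#' @export
setGeneric("rdmValues", function(x) standardGeneric("rdmValues"))

#' @rdname rdmLabels
#' @export
setGeneric("rdmLabels", function(x) standardGeneric("rdmLabels"))

#' @rdname lowerTriangle
#' @export
setGeneric("lowerTriangle", function(x, ...) standardGeneric("lowerTriangle"))

#' @rdname layerNames
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname getLayer
#' @export
setGeneric("getLayer", function(x, layer) standardGeneric("getLayer"))

#' @rdname nullSample
#' @export
setGeneric("nullSample", function(x) standardGeneric("nullSample"))

#' @rdname pValue
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname observedStatistic
#' @export
setGeneric("observedStatistic",
           function(x) standardGeneric("observedStatistic"))

#' @rdname meanAccuracy
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname standardError
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))

#' @rdname choiceCounts
#' @export
setGeneric("choiceCounts", function(x) standardGeneric("choiceCounts"))

#' @rdname choiceSimilarity
#' @export
setGeneric("choiceSimilarity", function(x) standardGeneric("choiceSimilarity"))
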