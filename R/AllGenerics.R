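#' @rdname dosageMatrix
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname snpIds
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname snpMap
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname callRate
#' @export
setGeneric("callRate", function(x, axis = c("snp", "sample"))
    standardGeneric("callRate"))

#' @rdname minorAlleleFreq
#' @export
setGeneric("minorAlleleFreq", function(x, samples = NULL)
    standardGeneric("minorAlleleFreq"))

#' @rdname restrictToPanel
#' @export
setGeneric("restrictToPanel", function(x, panel)
    standardGeneric("restrictToPanel"))

#' @rdname panelName
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname isPhased
#' @export
setGeneric("isPhased", function(x) standardGeneric("isPhased"))

#' @rdname haplotypeMatrices
#' @export
setGeneric("haplotypeMatrices", function(x) standardGeneric("haplotypeMatrices"))

#' @rdname pedRecords
#' @export
setGeneric("pedRecords", function(x) standardGeneric("pedRecords"))
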