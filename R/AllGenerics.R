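#' @rdname MRInstruments-class
#' @param x an object.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname MRInstruments-class
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname MRInstruments-class
#' @export
setGeneric("droppedVariants", function(x) standardGeneric("droppedVariants"))

#' @rdname MRInstruments-class
#' @export
setGeneric("exposureBeta", function(x) standardGeneric("exposureBeta"))

#' @rdname MRInstruments-class
#' @export
setGeneric("exposureSE", function(x) standardGeneric("exposureSE"))

#' @rdname MRInstruments-class
#' @export
setGeneric("outcomeBeta", function(x) standardGeneric("outcomeBeta"))

#' @rdname MRInstruments-class
#' @export
setGeneric("outcomeSE", function(x) standardGeneric("outcomeSE"))

#' @rdname MREstimate-class
#' @param x an object.
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname MREstimate-class
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname MREstimate-class
#' @export
setGeneric("ciLower", function(x) standardGeneric("ciLower"))

#' @rdname MREstimate-class
#' @export
setGeneric("ciUpper", function(x) standardGeneric("ciUpper"))

#' @rdname MREstimate-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
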