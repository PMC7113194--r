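#' @rdname GenotypeData-class
#' @param x a `GenotypeData`, `GRM` or `PCScores` object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GRM-class
#' @param x object.
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname GRM-class
#' @export
setGeneric("grmPairCounts", function(x) standardGeneric("grmPairCounts"))

#' @rdname GRM-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname GRM-class
#' @export
setGeneric("grmComponent", function(x) standardGeneric("grmComponent"))

#' @rdname PCScores-class
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname PCScores-class
#' @export
setGeneric("pcValues", function(x) standardGeneric("pcValues"))

#' @rdname GREMLFit-class
#' @param object,x a `GREMLFit`.
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname GREMLFit-class
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))
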