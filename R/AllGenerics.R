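#' @rdname fitControlRegression
#' @export
setGeneric("fitControlRegression",
           function(object, protein, level = 0.95, ...)
             standardGeneric("fitControlRegression"),
           signature = "object")

#' @rdname classifyFrequentist
#' @export
setGeneric("classifyFrequentist",
           function(object, controls, proteins = NULL, ...)
             standardGeneric("classifyFrequentist"),
           signature = "object")

#' @rdname classifyByPolygons
#' @export
setGeneric("classifyByPolygons",
           function(object, annotations, investigator = NULL, ...)
             standardGeneric("classifyByPolygons"),
           signature = "object")

#' @rdname FibreExperiment
#' @export
setGeneric("fibreTable", function(object, ...) standardGeneric("fibreTable"))

#' @rdname MitoCohort-accessors
#' @export
setGeneric("patientFibres", function(object) standardGeneric("patientFibres"))

#' @rdname MitoCohort-accessors
#' @export
setGeneric("controlFibres", function(object) standardGeneric("controlFibres"))

#' @rdname MitoCohort-accessors
#' @export
setGeneric("sectionInfo", function(object) standardGeneric("sectionInfo"))

#' @rdname MitoCohort-accessors
#' @export
setGeneric("cohortDesign", function(object) standardGeneric("cohortDesign"))

#' @rdname FibreExperiment
#' @export
setGeneric("oxphosProteins", function(object) standardGeneric("oxphosProteins"))
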