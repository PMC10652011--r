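#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers, so downstream code
#' never touches slots directly.
#'
#' @param x an iscCD8 S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname accessors
#' @export
setGeneric("moduleNames", function(x) standardGeneric("moduleNames"))

#' @rdname accessors
#' @export
setGeneric("subtypeOf", function(x) standardGeneric("subtypeOf"))

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("averagedDistance", function(x) standardGeneric("averagedDistance"))

#' @rdname accessors
#' @export
setGeneric("signatureDistances", function(x)
  standardGeneric("signatureDistances"))

#' @rdname accessors
#' @export
setGeneric("iscLabels", function(x) standardGeneric("iscLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname accessors
setMethod("moduleGenes", "SignalingModuleSet", function(x) x@modules)

#' @rdname accessors
setMethod("moduleNames", "SignalingModuleSet", function(x) names(x@modules))

#' @rdname accessors
setMethod("subtypeOf", "SignalingModuleSet", function(x) x@subtype)

#' @rdname accessors
setMethod("subtypeOf", "IscLabeling", function(x) x@subtype)

#' @rdname accessors
setMethod("patientIds", "PatientDistanceMatrix", function(x) x@patients)

#' @rdname accessors
setMethod("patientIds", "IscLabeling", function(x) names(x@labels))

#' @rdname accessors
setMethod("averagedDistance", "PatientDistanceMatrix", function(x) x@averaged)

#' @rdname accessors
setMethod("signatureDistances", "PatientDistanceMatrix",
          function(x) x@perSignature)

#' @rdname accessors
setMethod("iscLabels", "IscLabeling", function(x) x@labels)

#' @rdname accessors
setMethod("clusterIds", "IscLabeling", function(x) x@clusters)

#' @rdname accessors
setMethod("selectedGenes", "IscClassifier", function(x) x@selectedGenes)
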