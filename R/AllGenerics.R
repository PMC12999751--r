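#' @rdname MoleculeGraph-class
#' @param object,x a \linkS4class{MoleculeGraph} (or other class as
#'   documented).
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname MoleculeGraph-class
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname MoleculeGraph-class
#' @export
setGeneric("edgeFeatures", function(x) standardGeneric("edgeFeatures"))

#' @rdname MoleculeGraph-class
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname TautomerGroup-class
#' @param x a \linkS4class{TautomerGroup}.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname TautomerGroup-class
#' @export
setGeneric("parentId", function(x) standardGeneric("parentId"))

#' @rdname SplitPlan-class
#' @param x the object to extract assignments from.
#' @param repeatIndex which repeat (1-based).
#' @export
setGeneric("assignments", function(x, repeatIndex = 1L) standardGeneric("assignments"))

#' @rdname GraphDataset-class
#' @param x a \linkS4class{GraphDataset} (or other class as documented).
#' @export
setGeneric("datasetLabels", function(x) standardGeneric("datasetLabels"))

#' @rdname GraphDataset-class
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname GraphDataset-class
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname EvalReport-class
#' @param x an \linkS4class{EvalReport}.
#' @export
setGeneric("perRepeat", function(x) standardGeneric("perRepeat"))

#' @rdname EvalReport-class
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
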