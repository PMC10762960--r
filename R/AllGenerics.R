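#' @rdname LocusPanel-class
#' @param x a `LocusPanel`
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))

#' @rdname LocusPanel-class
#' @export
setGeneric("locusInfo", function(x) standardGeneric("locusInfo"))

#' @rdname LocusPanel-class
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' @rdname LocusPanel-class
#' @export
setGeneric("hhaISites", function(x) standardGeneric("hhaISites"))

#' @rdname LocusPanel-class
#' @export
setGeneric("labeledEnd", function(x) standardGeneric("labeledEnd"))

#' @rdname LocusPanel-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname LocusPanel-class
#' @export
setGeneric("locusNames", function(x) standardGeneric("locusNames"))

#' @rdname MoleculePool-class
#' @param x a `MoleculePool`
#' @export
setGeneric("moleculeStates", function(x) standardGeneric("moleculeStates"))

#' @rdname MoleculePool-class
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname Electropherogram-class
#' @param x an `Electropherogram`
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname Trajectory-class
#' @param x a `Trajectory`
#' @export
setGeneric("draws", function(x) standardGeneric("draws"))

#' @rdname Trajectory-class
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname RocResult-class
#' @param x an `RocResult`
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname RocResult-class
#' @export
setGeneric("aucCI", function(x) standardGeneric("aucCI"))

#' @rdname RocResult-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
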