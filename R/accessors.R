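#' @rdname LocusPanel-class
#' @export
setMethod("amplicons", "LocusPanel", function(x) x@amplicons)

#' @rdname LocusPanel-class
#' @export
setMethod("locusInfo", "LocusPanel", function(x) x@info)

#' @rdname LocusPanel-class
#' @export
setMethod("cpgPositions", "LocusPanel",
          function(x) setNames(x@info$cpg_positions, x@info$locus))

#' @rdname LocusPanel-class
#' @export
setMethod("hhaISites", "LocusPanel",
          function(x) setNames(x@info$hhal_sites, x@info$locus))

#' @rdname LocusPanel-class
#' @export
setMethod("labeledEnd", "LocusPanel",
          function(x) setNames(x@info$labeled_end, x@info$locus))

#' @rdname LocusPanel-class
#' @export
setMethod("nLoci", "LocusPanel", function(x) nrow(x@info))

#' @rdname LocusPanel-class
#' @export
setMethod("locusNames", "LocusPanel", function(x) x@info$locus)

#' Extract single loci from a panel
#'
#' @param x a `LocusPanel`
#' @param i locus index or name
#' @param j,drop,... ignored
#' @rdname LocusPanel-class
#' @export
setMethod("[", "LocusPanel", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$locus)
  new("LocusPanel", amplicons = x@amplicons[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "LocusPanel", function(object) {
  cat("LocusPanel with", nrow(object@info), "amplicons\n")
  inf <- object@info
  for (i in seq_len(nrow(inf))) {
    cat(sprintf("  %-10s %4d bp, %2d CpGs, %d HhaI site(s), labeled %s\n",
                inf$locus[i], inf$length_bp[i],
                length(inf$cpg_positions[[i]]),
                length(inf$hhal_sites[[i]]), inf$labeled_end[i]))
  }
})

#' @rdname MoleculePool-class
#' @export
setMethod("moleculeStates", "MoleculePool", function(x) x@states)

#' @rdname MoleculePool-class
#' @export
setMethod("nMolecules", "MoleculePool", function(x) nrow(x@states))

setMethod("show", "MoleculePool", function(object) {
  cat(sprintf("MoleculePool: %d molecules of %s (%d CpGs), %.1f%% methylated calls\n",
              nrow(object@states), object@locus@info$locus[1],
              ncol(object@states), 100 * mean(object@states)))
})

#' @rdname Electropherogram-class
#' @export
setMethod("peaks", "Electropherogram", function(x) x@peaks)

setMethod("show", "Electropherogram", function(object) {
  cat(sprintf("Electropherogram: %s replicate %d (%s channel), %d peak(s)\n",
              object@locus, object@replicate, object@channel,
              nrow(object@peaks)))
  if (nrow(object@peaks))
    print(object@peaks, row.names = FALSE)
})

#' @rdname Trajectory-class
#' @export
setMethod("draws", "Trajectory", function(x) x@draws)

#' @rdname Trajectory-class
#' @export
setMethod("events", "Trajectory", function(x) x@events)

setMethod("show", "Trajectory", function(object) {
  d <- object@draws
  cat(sprintf("Trajectory %s: %d draws over days %d-%d, %d event(s)\n",
              object@patientId, nrow(d), min(d$day), max(d$day),
              nrow(object@events)))
  if (nrow(object@events))
    print(object@events, row.names = FALSE)
})

#' @rdname RocResult-class
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

#' @rdname RocResult-class
#' @export
setMethod("aucCI", "RocResult", function(x) x@ci)

#' @rdname RocResult-class
#' @export
setMethod("rocPoints", "RocResult", function(x) x@points)

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC %.3f (95%% CI %.3f-%.3f), %d cases vs %d controls\n",
              object@auc, object@ci[1], object@ci[2],
              object@nCases, object@nControls))
})
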