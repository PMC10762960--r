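#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IntegerList
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom stats coef cor dnorm glm lm na.omit optim pnorm predict qbeta
#'   qlogis plogis qnorm quantile rbeta rbinom rlnorm rnorm runif sd setNames
#'   var wilcox.test binomial logLik p.adjust
#' @importFrom utils head read.csv read.delim tail write.csv write.table
NULL

#' Amplicon panel for the six promoter regions
#'
#' A `LocusPanel` bundles the bisulfite-PCR amplicon templates (top strand,
#' pre-conversion) with per-locus annotation: gene, region (1 or 2), which
#' primer end carries the fluorophore, the 0-based offsets of CpG cytosines,
#' and the 0-based start offsets of HhaI (GCGC) recognition sites as they
#' appear on the fully methylated, bisulfite-converted sequence.
#'
#' Offsets are 0-based throughout (matching the on-disk locus-table format);
#' a GCGC site starting at offset `h` spans bases `h..h+3` and is cleaved
#' after `h+2` (GCG^C).
#'
#' @slot amplicons `DNAStringSet` of amplicon templates, named `GENE_R1` etc.
#' @slot info `DataFrame` with columns `gene`, `region`, `locus`,
#'   `labeled_end` (`"5p"` or `"3p"`), `length_bp`, `cpg_positions`
#'   (`IntegerList`), `hhal_sites` (`IntegerList`).
#' @export
setClass("LocusPanel",
  slots = c(amplicons = "DNAStringSet", info = "DataFrame"))

setValidity("LocusPanel", function(object) {
  amp <- object@amplicons
  info <- object@info
  need <- c("gene", "region", "locus", "labeled_end", "length_bp",
            "cpg_positions", "hhal_sites")
  if (!all(need %in% colnames(info)))
    return(paste("info is missing columns:",
                 paste(setdiff(need, colnames(info)), collapse = ", ")))
  if (length(amp) != nrow(info))
    return("amplicons and info must have the same length")
  if (!all(info$labeled_end %in% c("5p", "3p")))
    return("labeled_end must be '5p' or '3p'")
  for (i in seq_len(nrow(info))) {
    s <- as.character(amp[[i]])
    L <- nchar(s)
    if (L != info$length_bp[i])
      return(sprintf("locus %s: amplicon length != length_bp", info$locus[i]))
    cp <- info$cpg_positions[[i]]
    if (length(cp) && (is.unsorted(cp, strictly = TRUE) || any(cp < 0) ||
                       any(cp >= L)))
      return(sprintf("locus %s: cpg_positions must be strictly increasing in [0, length)",
                     info$locus[i]))
    if (length(cp) && !all(substring(s, cp + 1, cp + 2) == "CG"))
      return(sprintf("locus %s: cpg_positions must point at CpG cytosines",
                     info$locus[i]))
    hh <- info$hhal_sites[[i]]
    if (length(hh)) {
      if (any(hh < 0) || any(hh + 3 >= L))
        return(sprintf("locus %s: hhal_sites out of range", info$locus[i]))
      if (!all(substring(s, hh + 1, hh + 4) == "GCGC"))
        return(sprintf("locus %s: hhal_sites must point at GCGC", info$locus[i]))
      if (!all((hh + 1) %in% cp))
        return(sprintf("locus %s: each HhaI site must contain a CpG cytosine",
                       info$locus[i]))
    }
  }
  TRUE
})

#' Pool of template molecules with per-molecule CpG methylation states
#'
#' Molecule-level substrate of the in-silico COBRA assay: each row of
#' `states` is one template molecule of the locus amplicon, each column one
#' CpG (in `cpgPositions()` order), `TRUE` meaning 5-methylcytosine.
#'
#' @slot locus single-locus [LocusPanel] (one amplicon).
#' @slot states logical matrix, molecules x CpGs.
#' @slot seed integer seed used to draw the states (NA if deterministic).
#' @export
setClass("MoleculePool",
  slots = c(locus = "LocusPanel", states = "matrix", seed = "integer"))

setValidity("MoleculePool", function(object) {
  if (length(object@locus@amplicons) != 1L)
    return("locus must contain exactly one amplicon")
  ncpg <- length(object@locus@info$cpg_positions[[1]])
  if (!is.logical(object@states))
    return("states must be a logical matrix")
  if (ncol(object@states) != ncpg)
    return("states must have one column per CpG")
  TRUE
})

#' Simulated fluorescent electropherogram for one locus and replicate
#'
#' Peaks are (fragment length, signal area) pairs from the labeled-primer
#' fragments of a digested molecule pool; at most one peak per distinct
#' length, areas in arbitrary fluorescence units.
#'
#' @slot peaks data.frame with columns `length_bp`, `area`.
#' @slot channel dye identifier.
#' @slot locus locus identifier (e.g. `"EFEMP1_R1"`).
#' @slot ampliconLength full amplicon length in bp.
#' @slot replicate replicate index (1 or 2).
#' @export
setClass("Electropherogram",
  slots = c(peaks = "data.frame", channel = "character", locus = "character",
            ampliconLength = "integer", replicate = "integer"))

setValidity("Electropherogram", function(object) {
  p <- object@peaks
  if (!all(c("length_bp", "area") %in% colnames(p)))
    return("peaks needs columns length_bp, area")
  if (nrow(p) && any(p$area < 0)) return("peak areas must be >= 0")
  if (nrow(p) && any(p$length_bp > object@ampliconLength))
    return("fragment lengths must not exceed the amplicon length")
  if (anyDuplicated(p$length_bp)) return("at most one peak per distinct length")
  TRUE
})

#' Hi-SA cohort container
#'
#' A [SummarizedExperiment] with rows = the six panel loci and columns =
#' subjects. Mandatory assays: `meth1`, `meth2` (methylation ratios in
#' \[0,1\], NA = no recovery) and `rec1`, `rec2` (non-negative recovery
#' signals) for the duplicate ("two-time") Hi-SA runs. `colData` carries at
#' least `group` (NN/AP/CRC), `stage` (I-IV or NA) and `conc_ng_ml`.
#'
#' @export
setClass("HiSAExperiment", contains = "SummarizedExperiment")

setValidity("HiSAExperiment", function(object) {
  need <- c("meth1", "meth2", "rec1", "rec2")
  if (!all(need %in% assayNames(object)))
    return(paste("missing assays:",
                 paste(setdiff(need, assayNames(object)), collapse = ", ")))
  for (a in c("meth1", "meth2")) {
    m <- assay(object, a)
    if (any(m < 0 | m > 1, na.rm = TRUE))
      return(sprintf("assay %s: methylation ratios must lie in [0,1]", a))
  }
  for (a in c("rec1", "rec2")) {
    r <- assay(object, a)
    if (any(r < 0, na.rm = TRUE))
      return(sprintf("assay %s: recovery signals must be >= 0", a))
  }
  cd <- colData(object)
  miss <- setdiff(c("group", "stage", "conc_ng_ml"), colnames(cd))
  if (length(miss))
    return(paste("colData is missing:", paste(miss, collapse = ", ")))
  TRUE
})

#' Longitudinal monitoring record for one patient
#'
#' Ordered blood-draw series (day, combination score Fc, serum CEA in
#' ng/ml, imaging tumor burden as the sum of maximum equators of metastatic
#' lesions in mm, treatment line) plus dated clinical events.
#'
#' @slot patientId patient identifier.
#' @slot draws data.frame with columns `day`, `fc`, `cea`, `burden`, `line`;
#'   days strictly increasing, at least two draws.
#' @slot events data.frame with columns `day`, `type` where type is one of
#'   `radiological_PD`, `clinical_PD`, `surgery`, `regimen_change`.
#' @export
setClass("Trajectory",
  slots = c(patientId = "character", draws = "data.frame",
            events = "data.frame"))

setValidity("Trajectory", function(object) {
  d <- object@draws
  if (!all(c("day", "fc", "cea", "burden", "line") %in% colnames(d)))
    return("draws needs columns day, fc, cea, burden, line")
  if (nrow(d) < 2L) return("a trajectory needs at least two draws")
  if (is.unsorted(d$day, strictly = TRUE))
    return("draw days must be strictly increasing")
  if (any(d$burden < 0, na.rm = TRUE)) return("burden must be >= 0")
  e <- object@events
  if (!all(c("day", "type") %in% colnames(e)))
    return("events needs columns day, type")
  ok <- c("radiological_PD", "clinical_PD", "surgery", "regimen_change")
  if (nrow(e) && !all(e$type %in% ok))
    return(paste("event types must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' ROC curve with AUC and DeLong confidence interval
#'
#' @slot points data.frame with columns `threshold`, `sensitivity`, `fpr`
#'   (1 - specificity), ordered so both coordinates are non-decreasing,
#'   starting at (0,0) and ending at (1,1).
#' @slot auc area under the curve.
#' @slot ci length-2 numeric, 95\% confidence interval for the AUC.
#' @slot nCases,nControls class sizes.
#' @export
setClass("RocResult",
  slots = c(points = "data.frame", auc = "numeric", ci = "numeric",
            nCases = "integer", nControls = "integer"))

setValidity("RocResult", function(object) {
  p <- object@points
  if (!all(c("threshold", "sensitivity", "fpr") %in% colnames(p)))
    return("points needs columns threshold, sensitivity, fpr")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
  if (is.unsorted(p$sensitivity) || is.unsorted(p$fpr))
    return("sensitivity and fpr must be non-decreasing along the curve")
  TRUE
})
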