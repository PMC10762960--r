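#' In-silico bisulfite conversion
#'
#' Applies the conversion chemistry to one template molecule: every cytosine
#' that is not a methylated CpG cytosine deaminates to thymine; methylated
#' CpG cytosines are protected; all other bases are untouched, so the output
#' has the same length as the input.
#'
#' @param sequence character scalar or `DNAString` (top strand).
#' @param methylated logical vector, one element per CpG cytosine of the
#'   sequence in left-to-right order (`TRUE` = 5mC, protected).
#' @param cpg_positions optional 0-based CpG offsets; detected with
#'   [detectCpGs()] when `NULL`.
#' @return converted sequence as a character scalar.
#' @export
bisulfiteConvert <- function(sequence, methylated, cpg_positions = NULL) {
  s <- as.character(sequence)
  if (is.null(cpg_positions)) cpg_positions <- detectCpGs(s)
  if (length(methylated) != length(cpg_positions))
    stop("`methylated` must have one element per CpG (",
         length(cpg_positions), " expected, got ", length(methylated), ")")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  isC <- chars == "C"
  protected <- rep(FALSE, length(chars))
  protected[cpg_positions[methylated] + 1L] <- TRUE
  chars[isC & !protected] <- "T"
  paste(chars, collapse = "")
}

#' HhaI sites retained after bisulfite conversion
#'
#' Scans a post-conversion sequence for GCGC recognition sites. A site
#' survives conversion only if its internal CpG cytosines were methylated;
#' on an unmethylated template the cytosines read as thymine and the site is
#' destroyed.
#'
#' @param converted post-conversion sequence (character or `DNAString`).
#' @return integer vector of 0-based site start offsets (overlap-aware).
#' @export
retainedHhaISites <- function(converted) {
  s <- as.character(converted)
  m <- gregexpr("(?=GCGC)", s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Restriction digestion into fragment lengths
#'
#' Cuts a sequence at every retained HhaI site using the GCG^C convention
#' (cleavage after the third base of the 4-mer). `k` sites yield `k + 1`
#' fragments whose lengths always sum to the sequence length.
#'
#' @param sequence sequence (character/`DNAString`) or its length in bp.
#' @param sites 0-based site start offsets, sorted ascending.
#' @return integer vector of fragment lengths, 5' to 3'.
#' @export
digestFragments <- function(sequence, sites) {
  L <- if (is.numeric(sequence)) as.integer(sequence)
       else nchar(as.character(sequence))
  sites <- as.integer(sites)
  if (anyNA(sites)) stop("`sites` must not contain NA")
  if (length(sites)) {
    if (is.unsorted(sites, strictly = TRUE))
      stop("`sites` must be sorted, strictly increasing")
    if (any(sites < 0L) || any(sites + 3L >= L))
      stop("site offset out of range for a ", L, " bp sequence")
  }
  cuts <- sites + 3L  # length of sequence 5' of the cut
  diff(c(0L, cuts, L))
}

# Per-molecule labeled fragment lengths, computed directly from the CpG
# states (a retained GCGC needs all of its member CpGs methylated, which is
# exactly what survives string-level conversion; equivalence is tested).
.labeledFragmentLengths <- function(locus, states) {
  info <- locusInfo(locus)
  L <- info$length_bp[1]
  cpg <- info$cpg_positions[[1]]
  sites <- info$hhal_sites[[1]]
  end <- info$labeled_end[1]
  n <- nrow(states)
  if (!length(sites)) return(rep(L, n))
  # molecules x sites matrix of retention
  ret <- vapply(sites, function(h) {
    member <- which(cpg %in% c(h + 1L, h + 3L))
    if (!length(member)) return(rep(FALSE, n))
    rowSums(!states[, member, drop = FALSE]) == 0L
  }, logical(n))
  ret <- matrix(ret, nrow = n)
  if (end == "5p") {
    first <- apply(ret, 1L, function(r) if (any(r)) sites[which(r)[1]] else NA_integer_)
    ifelse(is.na(first), L, first + 3L)
  } else {
    last <- apply(ret, 1L, function(r) if (any(r)) sites[tail(which(r), 1L)] else NA_integer_)
    ifelse(is.na(last), L, L - (last + 3L))
  }
}

#' Simulate the Hi-SA readout of a molecule pool
#'
#' Runs every molecule of the pool through conversion and digestion and
#' synthesizes the fluorescent electropherogram: only fragments carrying the
#' labeled primer end contribute, so each molecule yields exactly one peak
#' contribution and peak area is proportional to molecule count. Optional
#' multiplicative log-normal noise per peak and a detection floor mimic
#' capillary readout variability.
#'
#' @param pool a [MoleculePool-class].
#' @param noise_sd standard deviation (log scale) of multiplicative peak
#'   noise; 0 (default) gives exact counts.
#' @param detection_floor peaks with area below this are dropped (default 0,
#'   i.e. off).
#' @param replicate replicate index stamped on the readout.
#' @param channel dye identifier.
#' @param seed optional RNG seed for the noise draw.
#' @return an [Electropherogram-class].
#' @export
quantifyPool <- function(pool, noise_sd = 0, detection_floor = 0,
                         replicate = 1L, channel = "FAM", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- .labeledFragmentLengths(pool@locus, moleculeStates(pool))
  tab <- table(lens)
  area <- as.numeric(tab)
  if (noise_sd > 0)
    area <- area * exp(rnorm(length(area), 0, noise_sd))
  pk <- data.frame(length_bp = as.integer(names(tab)), area = area)
  pk <- pk[pk$area >= detection_floor, , drop = FALSE]
  pk <- pk[order(pk$length_bp), , drop = FALSE]
  rownames(pk) <- NULL
  new("Electropherogram", peaks = pk,
      channel = channel, locus = locusInfo(pool@locus)$locus[1],
      ampliconLength = as.integer(locusInfo(pool@locus)$length_bp[1]),
      replicate = as.integer(replicate))
}

#' Methylation ratio and recovery signal from an electropherogram
#'
#' The COBRA quantity: cut (methylated) labeled-fragment area over total
#' labeled area, i.e. `cut / (cut + uncut)`, where the uncut peak is the
#' full-length amplicon. The total labeled area doubles as the recovery
#' signal, a proxy for the amount of amplifiable (non-apoptotically
#' fragmented) template. Zero total signal is a distinguished "no recovery"
#' result: the ratio is `NA` and the recovery signal 0.
#'
#' @param e an [Electropherogram-class].
#' @return data.frame with one row: `locus`, `replicate`, `meth_ratio`,
#'   `recovery_signal`, `evaluable`.
#' @export
methylationRatio <- function(e) {
  pk <- peaks(e)
  total <- sum(pk$area)
  if (total <= 0) {
    return(data.frame(locus = e@locus, replicate = e@replicate,
                      meth_ratio = NA_real_, recovery_signal = 0,
                      evaluable = FALSE))
  }
  uncut <- sum(pk$area[pk$length_bp == e@ampliconLength])
  data.frame(locus = e@locus, replicate = e@replicate,
             meth_ratio = (total - uncut) / total,
             recovery_signal = total, evaluable = TRUE)
}
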