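#' Find CpG cytosines and HhaI sites in an amplicon template
#'
#' `detectCpGs()` returns the 0-based offsets of every cytosine that is part
#' of a CG dinucleotide. `detectHhaISites()` returns the 0-based start
#' offsets of every GCGC recognition site that survives bisulfite conversion
#' when fully methylated: since only CpG cytosines can be protected, both
#' cytosines of the 4-mer must sit in CpG context (in practice the motif is
#' GCGCG), otherwise conversion destroys the site unconditionally.
#'
#' @param sequence character scalar or `DNAString` (unconverted top strand).
#' @return integer vector of 0-based offsets.
#' @export
detectCpGs <- function(sequence) {
  s <- as.character(sequence)
  m <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' @rdname detectCpGs
#' @export
detectHhaISites <- function(sequence) {
  s <- as.character(sequence)
  m <- gregexpr("(?=GCGC)", s, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  off <- as.integer(m) - 1L
  cpg <- detectCpGs(s)
  # both cytosines (offsets +1 and +3) must be CpG cytosines
  off[(off + 1L) %in% cpg & (off + 3L) %in% cpg]
}

#' Construct a LocusPanel
#'
#' @param amplicons `DNAStringSet` (or named character vector) of amplicon
#'   templates (top strand, pre-conversion).
#' @param gene,region,labeled_end per-amplicon annotation vectors; `region`
#'   is 1 or 2, `labeled_end` `"5p"` or `"3p"`.
#' @param cpg_positions,hhal_sites optional lists of 0-based offsets; when
#'   `NULL` they are detected from the sequences with [detectCpGs()] and
#'   [detectHhaISites()].
#' @return a [LocusPanel-class] object.
#' @export
LocusPanel <- function(amplicons, gene, region, labeled_end,
                       cpg_positions = NULL, hhal_sites = NULL) {
  if (!methods::is(amplicons, "DNAStringSet"))
    amplicons <- DNAStringSet(unlist(amplicons))
  seqs <- as.character(amplicons)
  if (is.null(cpg_positions)) cpg_positions <- lapply(seqs, detectCpGs)
  if (is.null(hhal_sites)) hhal_sites <- lapply(seqs, detectHhaISites)
  locus <- paste0(gene, "_R", region)
  names(amplicons) <- locus
  info <- DataFrame(
    gene = gene, region = as.integer(region), locus = locus,
    labeled_end = labeled_end, length_bp = nchar(seqs),
    cpg_positions = IntegerList(cpg_positions),
    hhal_sites = IntegerList(hhal_sites))
  rownames(info) <- locus
  new("LocusPanel", amplicons = amplicons, info = info)
}

# -- synthetic amplicon assembly ---------------------------------------------
# Building blocks keep every cytosine in CpG context so the declared CpG set
# is exhaustive. Filler uses A/T/G only (cannot create CG or GCGC).

.filler <- function(n) {
  if (n <= 0) return("")
  substr(strrep("ATTGGTA", ceiling(n / 7)), 1L, n)
}
.CPG_UNIT <- "TTACGT"    # CpG cytosine at local offset 3
.SITE_UNIT <- "AGCGCGT"  # GCGC at local offset 1; CpGs at local 2 and 4

.assembleAmplicon <- function(blocks) {
  seq <- ""
  cpg <- integer(0)
  off <- 0L
  for (b in blocks) {
    if (b == "cpg") {
      cpg <- c(cpg, off + 3L)
      piece <- .CPG_UNIT
    } else if (b == "site") {
      cpg <- c(cpg, off + 2L, off + 4L)
      piece <- .SITE_UNIT
    } else {
      piece <- .filler(as.integer(b))
    }
    seq <- paste0(seq, piece)
    off <- off + nchar(piece)
  }
  list(seq = seq, cpg = cpg)
}

#' Default synthetic amplicon panel
#'
#' A fully synthetic stand-in for the six promoter amplicons (two regions
#' each of EFEMP1, SFRP2 and UNC5C): the sequences are constructed, not
#' genomic, but reproduce the structural features the assay model needs --
#' a CpG-dense interior, one (region 1) or two (region 2) HhaI GCGCG sites,
#' realistic COBRA product sizes and a single labeled primer end per locus.
#'
#' @return a [LocusPanel-class] with six loci.
#' @export
defaultLocusPanel <- function() {
  spec <- list(
    EFEMP1_R1 = list(lead = 24, c5 = 4, sites = 1, c3 = 5, tail = 22, end = "5p"),
    EFEMP1_R2 = list(lead = 30, c5 = 5, sites = 2, c3 = 4, tail = 26, end = "3p"),
    SFRP2_R1  = list(lead = 20, c5 = 6, sites = 1, c3 = 4, tail = 30, end = "5p"),
    SFRP2_R2  = list(lead = 26, c5 = 3, sites = 2, c3 = 6, tail = 24, end = "3p"),
    UNC5C_R1  = list(lead = 28, c5 = 5, sites = 1, c3 = 6, tail = 20, end = "5p"),
    UNC5C_R2  = list(lead = 22, c5 = 6, sites = 2, c3 = 5, tail = 28, end = "3p"))
  seqs <- character(0); cpgs <- list(); genes <- character(0)
  regions <- integer(0); ends <- character(0)
  for (nm in names(spec)) {
    p <- spec[[nm]]
    blocks <- c(as.character(p$lead), rep("cpg", p$c5),
                rep(c("site", "8"), p$sites)[-(2 * p$sites)],
                rep("cpg", p$c3), as.character(p$tail))
    if (p$sites == 2)  # re-insert spacer between the two sites
      blocks <- c(as.character(p$lead), rep("cpg", p$c5),
                  "site", "10", "site", rep("cpg", p$c3), as.character(p$tail))
    a <- .assembleAmplicon(blocks)
    seqs <- c(seqs, a$seq)
    cpgs <- c(cpgs, list(a$cpg))
    genes <- c(genes, sub("_R[12]$", "", nm))
    regions <- c(regions, as.integer(sub("^.*_R", "", nm)))
    ends <- c(ends, p$end)
  }
  LocusPanel(DNAStringSet(seqs), gene = genes, region = regions,
             labeled_end = ends)
}

#' Read and write locus panels
#'
#' The on-disk representation is a FASTA file of amplicon templates plus a
#' tab-separated locus table with columns `gene`, `region`, `locus`,
#' `length_bp`, `cpg_positions`, `hhal_sites` (both `;`-separated 0-based
#' offsets) and `labeled_end`.
#'
#' @param panel a [LocusPanel-class].
#' @param fasta,table paths to the FASTA and TSV files.
#' @return `readLocusPanel()` returns a [LocusPanel-class];
#'   `writeLocusPanel()` returns the paths invisibly.
#' @export
writeLocusPanel <- function(panel, fasta, table) {
  writeXStringSet(amplicons(panel), fasta)
  info <- locusInfo(panel)
  tab <- data.frame(
    gene = info$gene, region = info$region, locus = info$locus,
    length_bp = info$length_bp,
    cpg_positions = vapply(info$cpg_positions, paste, "", collapse = ";"),
    hhal_sites = vapply(info$hhal_sites, paste, "", collapse = ";"),
    labeled_end = info$labeled_end)
  write.table(tab, table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, table = table))
}

#' @rdname writeLocusPanel
#' @export
readLocusPanel <- function(fasta, table) {
  amp <- readDNAStringSet(fasta)
  tab <- read.delim(table, stringsAsFactors = FALSE)
  amp <- amp[tab$locus]
  splitOffsets <- function(x)
    lapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(v) as.integer(v[nzchar(v)]))
  LocusPanel(amp, gene = tab$gene, region = tab$region,
             labeled_end = tab$labeled_end,
             cpg_positions = splitOffsets(tab$cpg_positions),
             hhal_sites = splitOffsets(tab$hhal_sites))
}
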