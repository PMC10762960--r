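#' Generate a molecule pool with independent per-CpG methylation
#'
#' Draws `n_molecules` template molecules whose CpG states are independent
#' Bernoulli draws with the given per-CpG probabilities, so expected column
#' means equal the probabilities.
#'
#' @param locus single-locus [LocusPanel-class] (e.g. `defaultLocusPanel()[1]`).
#' @param per_cpg_meth_prob numeric vector of methylation probabilities, one
#'   per CpG of the locus (a scalar is recycled).
#' @param n_molecules number of molecules.
#' @param seed optional RNG seed (stored in the pool).
#' @return a [MoleculePool-class].
#' @export
generateMoleculePool <- function(locus, per_cpg_meth_prob, n_molecules,
                                 seed = NULL) {
  if (length(amplicons(locus)) != 1L)
    stop("`locus` must contain exactly one amplicon; subset the panel first")
  ncpg <- length(locusInfo(locus)$cpg_positions[[1]])
  if (length(per_cpg_meth_prob) == 1L)
    per_cpg_meth_prob <- rep(per_cpg_meth_prob, ncpg)
  if (length(per_cpg_meth_prob) != ncpg)
    stop("`per_cpg_meth_prob` must have one probability per CpG (",
         ncpg, " expected, got ", length(per_cpg_meth_prob), ")")
  if (any(per_cpg_meth_prob < 0 | per_cpg_meth_prob > 1))
    stop("methylation probabilities must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  states <- matrix(
    runif(n_molecules * ncpg) < rep(per_cpg_meth_prob, each = n_molecules),
    nrow = n_molecules, ncol = ncpg)
  new("MoleculePool", locus = locus, states = states,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Molecule pool with an exact fraction of fully methylated molecules
#'
#' Deterministic pool in which `round(fraction * n_molecules)` molecules are
#' methylated at every CpG and the rest at none -- the regime in which the
#' COBRA cut-fragment share equals the molecule fraction exactly, used for
#' assay-oracle checks.
#'
#' @param locus single-locus [LocusPanel-class].
#' @param fraction fraction of fully methylated molecules in \[0,1\].
#' @param n_molecules number of molecules.
#' @return a [MoleculePool-class].
#' @export
fractionPool <- function(locus, fraction, n_molecules) {
  stopifnot(fraction >= 0, fraction <= 1, n_molecules >= 1)
  ncpg <- length(locusInfo(locus)$cpg_positions[[1]])
  k <- round(fraction * n_molecules)
  states <- matrix(FALSE, n_molecules, ncpg)
  if (k > 0) states[seq_len(k), ] <- TRUE
  new("MoleculePool", locus = locus, states = states, seed = NA_integer_)
}
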