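# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# AUC by exhaustive case-control pair counting (ties count one half)
oracleAucPairs <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exact two-sided Wilcoxon p by full enumeration of label assignments
oracleWilcoxonExact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  U <- apply(idx, 2, function(i) {
    xx <- pooled[i]; yy <- pooled[-i]
    sum(outer(xx, yy, function(a, b) (a > b) + 0.5 * (a == b)))
  })
  uobs <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  pl <- mean(U <= uobs); pg <- mean(U >= uobs)
  min(1, 2 * min(pl, pg))
}

# permutation p-value for the control-vs-group mean-rank difference
oraclePermRankP <- function(values, groups, control, other, n_perm = 10000) {
  keepAll <- groups %in% c(control, other)
  # ranks over the FULL merged sample, as Dunn's procedure uses
  rk <- rank(values)
  obs <- abs(mean(rk[groups == other]) - mean(rk[groups == control]))
  n_o <- sum(groups == other)
  pool <- which(keepAll)
  stat <- replicate(n_perm, {
    pick <- sample(pool, n_o)
    abs(mean(rk[pick]) - mean(rk[setdiff(pool, pick)]))
  })
  mean(stat >= obs - 1e-12)
}

# stratified bootstrap SE of the AUC
oracleBootAucSE <- function(scores, labels, n_boot = 10000) {
  ci <- which(labels == 1); co <- which(labels == 0)
  a <- replicate(n_boot, {
    i <- sample(ci, replace = TRUE); j <- sample(co, replace = TRUE)
    oracleAucPairs(c(scores[i], scores[j]),
                   rep(c(1, 0), c(length(i), length(j))))
  })
  stats::sd(a)
}

# string-route assay pipeline for one molecule (conversion -> retained
# sites -> digestion -> labeled fragment length)
oracleLabeledLength <- function(panel1, states_row) {
  info <- locusInfo(panel1)
  s <- as.character(amplicons(panel1)[[1]])
  conv <- bisulfiteConvert(s, states_row, info$cpg_positions[[1]])
  sites <- retainedHhaISites(conv)
  frags <- digestFragments(conv, sites)
  if (info$labeled_end[1] == "5p") frags[1] else frags[length(frags)]
}
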