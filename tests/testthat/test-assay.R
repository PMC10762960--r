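test_that("bisulfite conversion protects methylated CpGs only", {
  expect_equal(bisulfiteConvert("ACGT", TRUE), "ACGT")
  expect_equal(bisulfiteConvert("ACGT", FALSE), "ATGT")
  # non-CpG cytosine converts even when the CpG is methylated
  expect_equal(bisulfiteConvert("CCGG", TRUE), "TCGG")
  expect_equal(bisulfiteConvert("CCGG", FALSE), "TTGG")
  # length preserved, non-C bases untouched
  p <- defaultLocusPanel()
  s <- as.character(amplicons(p)[[1]])
  ncpg <- length(cpgPositions(p)[[1]])
  conv <- bisulfiteConvert(s, rep(FALSE, ncpg))
  expect_equal(nchar(conv), nchar(s))
  expect_false(grepl("C", conv, fixed = TRUE))
  expect_error(bisulfiteConvert("ACGT", c(TRUE, FALSE)), "one element per CpG")
})

test_that("HhaI site retention requires methylation of its CpGs", {
  p <- defaultLocusPanel()
  for (i in seq_len(nLoci(p))) {
    l <- p[i]
    ncpg <- length(cpgPositions(l)[[1]])
    full <- bisulfiteConvert(as.character(amplicons(l)[[1]]),
                             rep(TRUE, ncpg))
    none <- bisulfiteConvert(as.character(amplicons(l)[[1]]),
                             rep(FALSE, ncpg))
    expect_equal(retainedHhaISites(full), locusInfo(l)$hhal_sites[[1]])
    expect_length(retainedHhaISites(none), 0L)
  }
})

test_that("mixed-pool site retention matches per-molecule enumeration", {
  set.seed(101)
  p <- defaultLocusPanel()
  l <- p[1]
  pool <- generateMoleculePool(l, 0.6, 400, seed = 7)
  st <- moleculeStates(pool)
  info <- locusInfo(l)
  h <- info$hhal_sites[[1]][1]
  # enumeration oracle: run each molecule through the string pipeline
  retained <- vapply(seq_len(nrow(st)), function(i) {
    conv <- bisulfiteConvert(as.character(amplicons(l)[[1]]), st[i, ],
                             info$cpg_positions[[1]])
    h %in% retainedHhaISites(conv)
  }, logical(1))
  # retention happens exactly when all CpGs inside the 4-mer are methylated
  member <- which(info$cpg_positions[[1]] %in% c(h + 1L, h + 3L))
  expect_equal(retained, rowSums(!st[, member, drop = FALSE]) == 0)
  # frequency close to the product of the member CpG probabilities
  expect_lt(abs(mean(retained) - 0.6^length(member)),
            4 * sqrt(0.36 * 0.64 / nrow(st)))
})

test_that("digestion conserves bases and yields k+1 fragments", {
  expect_equal(digestFragments(200, integer(0)), 200L)
  expect_equal(digestFragments(200, 100L), c(103L, 97L))
  set.seed(42)
  for (rep in 1:25) {
    L <- sample(60:300, 1)
    k <- sample(0:5, 1)
    sites <- sort(sample(0:(L - 5), k))
    fr <- digestFragments(L, sites)
    expect_length(fr, length(sites) + 1L)
    expect_equal(sum(fr), L)
    expect_true(all(fr >= 0))
  }
  expect_error(digestFragments(100, 99L), "out of range")
  expect_error(digestFragments(100, c(10L, 5L)), "sorted")
})

test_that("quantification matches molecule counting for degenerate pools", {
  p <- defaultLocusPanel()
  for (i in c(1, 2)) {  # one 5'-labeled, one 3'-labeled locus
    l <- p[i]
    L <- locusInfo(l)$length_bp[1]
    all_m <- quantifyPool(fractionPool(l, 1, 50))
    expect_equal(nrow(peaks(all_m)), 1L)
    expect_lt(peaks(all_m)$length_bp, L)
    all_u <- quantifyPool(fractionPool(l, 0, 50))
    expect_equal(peaks(all_u)$length_bp, L)
    expect_equal(peaks(all_u)$area, 50)
  }
})

test_that("fast quantification equals the string-route pipeline", {
  p <- defaultLocusPanel()
  for (i in seq_len(nLoci(p))) {
    l <- p[i]
    pool <- generateMoleculePool(l, 0.5, 40, seed = 30 + i)
    e <- quantifyPool(pool)
    oracle <- vapply(seq_len(40), function(j)
      oracleLabeledLength(l, moleculeStates(pool)[j, ]), numeric(1))
    tab <- table(oracle)
    expect_equal(peaks(e)$length_bp, as.integer(names(tab)))
    expect_equal(peaks(e)$area, as.numeric(tab))
  }
})

test_that("noise-free pipeline ratio equals the exact molecule fraction", {
  p <- defaultLocusPanel()
  for (i in seq_len(nLoci(p))) {
    l <- p[i]
    for (f in seq(0, 1, by = 0.1)) {
      m <- methylationRatio(quantifyPool(fractionPool(l, f, 50)))
      expect_equal(m$meth_ratio, f)
      expect_equal(m$recovery_signal, 50)
    }
  }
})

test_that("expected ratio is monotone in the methylation fraction", {
  set.seed(9)
  l <- defaultLocusPanel()[3]
  ratios <- vapply(seq(0, 1, 0.25), function(f) {
    mean(replicate(20, methylationRatio(
      quantifyPool(generateMoleculePool(l, f, 200)))$meth_ratio))
  }, numeric(1))
  expect_false(is.unsorted(ratios))
})

test_that("ratio arithmetic and the no-recovery case behave as defined", {
  e <- new("Electropherogram",
           peaks = data.frame(length_bp = c(60L, 107L), area = c(50, 50)),
           channel = "FAM", locus = "EFEMP1_R1", ampliconLength = 107L,
           replicate = 1L)
  m <- methylationRatio(e)
  expect_equal(m$meth_ratio, 0.5)
  expect_equal(m$recovery_signal, 100)
  e0 <- new("Electropherogram",
            peaks = data.frame(length_bp = 107L, area = 80),
            channel = "FAM", locus = "EFEMP1_R1", ampliconLength = 107L,
            replicate = 1L)
  expect_equal(methylationRatio(e0)$meth_ratio, 0)
  empty <- new("Electropherogram",
               peaks = data.frame(length_bp = integer(0), area = numeric(0)),
               channel = "FAM", locus = "EFEMP1_R1", ampliconLength = 107L,
               replicate = 1L)
  r <- methylationRatio(empty)
  expect_false(r$evaluable)
  expect_true(is.na(r$meth_ratio))
  expect_equal(r$recovery_signal, 0)
})

test_that("peak areas are never negative under noise", {
  pool <- fractionPool(defaultLocusPanel()[1], 0.4, 100)
  e <- quantifyPool(pool, noise_sd = 0.5, seed = 3)
  expect_true(all(peaks(e)$area >= 0))
})
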