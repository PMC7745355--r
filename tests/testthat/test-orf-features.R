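# Brute-force ORF oracle: scan every ATG, walk codons to the first
# in-frame stop; independent of the package's vectorized index logic.
oracleOrfs <- function(s) {
  L <- nchar(s)
  out <- list()
  for (a in seq_len(max(L - 2L, 0L))) {
    if (substr(s, a, a + 2L) != "ATG") next
    pos <- a; stopAt <- NA_integer_
    while (pos + 2L <= L) {
      cod <- substr(s, pos, pos + 2L)
      if (pos > a && cod %in% c("TAA", "TAG", "TGA")) { stopAt <- pos; break }
      pos <- pos + 3L
    }
    if (!is.na(stopAt))
      out[[length(out) + 1L]] <- c(start = a, end = stopAt + 2L, stop = 1L)
    else {
      len <- ((L - a + 1L) %/% 3L) * 3L
      out[[length(out) + 1L]] <- c(start = a, end = a + len - 1L, stop = 0L)
    }
  }
  do.call(rbind, out)
}

test_that("findOrfs handles the canonical cases", {
  o <- findOrfs("ATGAAATAG")
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 1L); expect_equal(o$end, 9L)
  expect_equal(o$frame, 0L); expect_true(o$hasStart && o$hasStop)
  expect_equal(o$ntLength, 9L)

  expect_equal(nrow(findOrfs("CCCCCC")), 0L)

  o2 <- findOrfs("ATGATGTAA")
  expect_equal(o2$start, c(1L, 4L))
  expect_equal(o2$ntLength, c(9L, 6L))
})

test_that("findOrfs agrees with a brute-force codon-walk oracle", {
  set.seed(21)
  for (i in 1:60) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(3:60, 1),
                       replace = TRUE), collapse = "")
    got <- findOrfs(s)
    want <- oracleOrfs(s)
    if (is.null(want)) { expect_equal(nrow(got), 0L); next }
    expect_equal(got$start, unname(want[, "start"]))
    expect_equal(got$end, unname(want[, "end"]))
    expect_equal(got$hasStop, unname(want[, "stop"]) == 1L)
  }
})

test_that("orfFeatures implements the first/longest ORF conventions", {
  expect_equal(orfFeatures("ATGAAATAG"),
               c(orfLength = 9, orfCoverage = 1, orfIntegrity = 1))
  expect_equal(orfFeatures("CCCCCC"),
               c(orfLength = 0, orfCoverage = 0, orfIntegrity = 0))
  expect_equal(orfFeatures("TTATGAAATAGTT"),
               c(orfLength = 9, orfCoverage = 9 / 13, orfIntegrity = 1))
  # incomplete ORF: counts for coverage, zero integrity, no complete ORF
  expect_equal(orfFeatures("ATGAAAAA"),
               c(orfLength = 0, orfCoverage = 6 / 8, orfIntegrity = 0))
  # coverage and length bounds on random sequences
  set.seed(5)
  for (i in 1:40) {
    s <- paste0(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                collapse = "")
    f <- orfFeatures(s)
    expect_lte(f[["orfCoverage"]], 1)
    expect_lte(f[["orfLength"]], 50)
  }
})

test_that("fickettScore matches a literal table-lookup computation", {
  # homopolymer A, L = 60: per-phase counts of A are (20, 20, 20), so the
  # A position parameter is 20/(20+1) = 0.952 which falls in the final
  # lookup bucket; content of A is 1.0 (first bucket); the other bases
  # have position parameter 0 and content 0 (final buckets). Reading the
  # published probabilities and weights by hand:
  #   A: 0.22*0.26 + 0.28*0.11 ; C: 0.23*0.18 + 0.31*0.12
  #   G: 0.08*0.31 + 0.29*0.15 ; T: 0.09*0.33 + 0.58*0.14
  byHand <- (0.22 * 0.26 + 0.28 * 0.11) + (0.23 * 0.18 + 0.31 * 0.12) +
    (0.08 * 0.31 + 0.29 * 0.15) + (0.09 * 0.33 + 0.58 * 0.14)
  expect_equal(fickettScore(strrep("A", 60)), byHand, tolerance = 1e-12)
  expect_equal(fickettScore("AC"), 0)  # below-length convention
})

test_that("fickettScore is a pure function of the normalized sequence", {
  u <- TranscriptSet(c(a = "augcaugcaugcaugc"))
  t <- TranscriptSet(c(b = "ATGCATGCATGCATGC"))
  expect_equal(fickettScore(transcriptSeqs(u)[[1]]),
               fickettScore(transcriptSeqs(t)[[1]]))
})

test_that("hexamer table counts in-frame windows and normalizes", {
  ht <- buildHexamerTable("ATGAAATAG", "CCCCCCCC", pseudocount = 1)
  expect_s4_class(ht, "HexamerTable")
  expect_equal(sum(ht@coding), 1, tolerance = 1e-9)
  expect_equal(sum(ht@noncoding), 1, tolerance = 1e-9)
  # the ORF of ATGAAATAG contributes exactly {ATGAAA, AAATAG}, count 1 each
  expect_equal(unname(ht@coding[["ATGAAA"]]), 2 / 4098)
  expect_equal(unname(ht@coding[["AAATAG"]]), 2 / 4098)
  expect_equal(unname(ht@coding[["CCCCCC"]]), 1 / 4098)
  # no countable hexamers at all -> uniform 1/4096
  ht0 <- buildHexamerTable("ACGTA", "TACGT", pseudocount = 1)
  expect_true(all(abs(ht0@coding - 1 / 4096) < 1e-12))
  expect_error(buildHexamerTable(character(), "ACGTACGTA"), "non-empty")
})

test_that("hexamerScore is the mean in-frame log ratio and antisymmetric", {
  htEq <- buildHexamerTable("ACGTA", "TACGT")  # coding == noncoding
  expect_equal(hexamerScore("ATGAAAAAATAG", htEq), 0)
  expect_equal(hexamerScore("ACGTA", htEq), 0)  # no hexamer -> 0

  ht <- buildHexamerTable(c("ATGAAATAGGG", "ATGCCCTAA"), "AAAAAAAAAAAA")
  s <- "ATGAAAAAATAG"   # ORF = whole sequence; windows at 1, 4, 7
  oracle <- mean(log(ht@coding[c("ATGAAA", "AAAAAA", "AAATAG")] /
                     ht@noncoding[c("ATGAAA", "AAAAAA", "AAATAG")]))
  expect_equal(hexamerScore(s, ht), oracle, tolerance = 1e-12)

  swapped <- methods::new("HexamerTable", coding = ht@noncoding,
                          noncoding = ht@coding, pseudocount = ht@pseudocount)
  expect_equal(hexamerScore(s, swapped), -hexamerScore(s, ht),
               tolerance = 1e-12)
})

test_that("peptide features follow the stated conventions", {
  # ATG GGT TAA -> peptide "MG" (initial Met kept, stop excluded)
  pf <- peptideFeatures("ATGGGTTAA")
  expect_equal(pf[["gravy"]], (1.9 - 0.4) / 2)
  # single-residue peptide: no dipeptides -> instability 0
  pf1 <- peptideFeatures("ATGTAA")
  expect_equal(pf1[["instability"]], 0)
  expect_equal(pf1[["gravy"]], 1.9)   # Met
  # no ORF -> all zero
  expect_equal(unname(peptideFeatures("CCCCCCCCC")), c(0, 0, 0))
})

test_that("pI ordering matches the charge-curve oracle", {
  acidic <- "ATGGATGATTAA"  # M D D
  basic <- "ATGAAAAAATAA"   # M K K
  piA <- peptideFeatures(acidic)[["pI"]]
  piB <- peptideFeatures(basic)[["pI"]]
  expect_lt(piA, piB)
  # oracle: net charge on a pH grid changes sign exactly around the
  # reported pI for both peptides
  for (case in list(list(pep = "MDD", pi = piA), list(pep = "MKK", pi = piB))) {
    ch <- function(pH) lncEnsemble:::.netCharge(case$pep, pH)
    expect_gt(ch(case$pi - 0.2), 0)
    expect_lt(ch(case$pi + 0.2), 0)
  }
})

test_that("ctdFeatures implements composition, transition, distribution", {
  v <- ctdFeatures("ACGT")
  expect_length(v, 30L)
  expect_equal(unname(v[1:4]), rep(0.25, 4))

  v2 <- ctdFeatures("AAAA")
  expect_equal(unname(v2[1:4]), c(1, 0, 0, 0))
  expect_equal(unname(v2[5:10]), rep(0, 6))
  expect_equal(unname(v2[11:15]), c(1, 1, 2, 3, 4) / 4)
  expect_equal(unname(v2[16:30]), rep(0, 15))

  set.seed(9)
  for (i in 1:25) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(2:100, 1),
                       replace = TRUE), collapse = "")
    vv <- ctdFeatures(s)
    expect_equal(sum(vv[1:4]), 1, tolerance = 1e-12)
    expect_true(all(vv >= 0 & vv <= 1))
  }
})

test_that("transcript feature block is 38-dimensional and pure", {
  ts <- TranscriptSet(c(a = strrep("ATGAAATAGC", 30),
                        b = strrep("CGTA", 75),
                        c = strrep("ATGAAATAGC", 30)),
                      label = c(0L, 1L, 0L))
  ht <- buildHexamerTable("ATGAAATAG", "CCCCCCCC")
  fb <- transcriptFeatures(ts, hexTable = ht)
  m <- featureValues(fb)
  expect_identical(dim(m), c(3L, 38L))
  expect_identical(colnames(m)[1:8],
                   c("orfLength", "orfCoverage", "orfIntegrity", "fickett",
                     "hexamer", "pI", "gravy", "instability"))
  # identical sequences -> identical rows; order permutation -> same values
  expect_equal(unname(m["a", ]), unname(m["c", ]))
  perm <- transcriptFeatures(ts[c(2, 3, 1)], hexTable = ht)
  expect_equal(featureValues(perm)["b", ], m["b", ])
})
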