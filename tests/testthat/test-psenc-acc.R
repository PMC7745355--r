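randSeq2 <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

test_that("pseudo composition dimensions follow the variant formulas", {
  s <- randSeq2(80)
  expect_equal(ncol(pseNc(s, "PseDNC")), 16 + 7)
  expect_equal(ncol(pseNc(s, "PC-PseDNC-General")), 16 + 7)
  expect_equal(ncol(pseNc(s, "PC-PseTNC-General")), 64 + 6)
  expect_equal(ncol(pseNc(s, "SC-PseDNC-General")), 16 + 6 * 7)
  expect_equal(ncol(pseNc(s, "SC-PseTNC-General")), 64 + 12 * 6)
  expect_equal(ncol(pseNcBlock(s)), 23 + 23 + 70 + 58 + 136)
})

test_that("pseudo composition vectors are normalized to sum one", {
  # parallel-correlation theta terms are mean squared differences, so the
  # whole vector is nonnegative; series-correlation tau terms are mean
  # products of standardized property values and may be negative, but the
  # shared denominator still normalizes every vector to total 1
  set.seed(31)
  for (v in c("PseDNC", "PC-PseTNC-General", "SC-PseDNC-General",
              "SC-PseTNC-General")) {
    for (i in 1:8) {
      s <- randSeq2(sample(30:120, 1))
      x <- pseNc(s, v)
      if (startsWith(v, "P")) expect_true(all(x >= 0))
      expect_equal(sum(x), 1, tolerance = 1e-10)
    }
  }
})

test_that("w -> 0 collapses to plain oligomer frequencies with zero tail", {
  set.seed(33)
  s <- randSeq2(60)
  x <- pseNc(s, "PseDNC", lambda = 4, w = 0)
  sp <- spectrumProfile(s, ks = 2L)
  expect_equal(unname(x[1, 1:16]), unname(sp[1, ]), tolerance = 1e-12)
  expect_equal(unname(x[1, 17:20]), rep(0, 4))
})

test_that("sequences too short for lambda raise a named error", {
  expect_error(pseNc(c(tiny = "ACGTACG"), "PseDNC", lambda = 7), "tiny")
})

test_that("theta terms match a direct two-loop evaluation", {
  # independent oracle: literal loops over positions and properties using
  # the same packaged standardized property table
  set.seed(35)
  props <- lncEnsemble:::.DINUC_PROPS_STD
  for (rep in 1:5) {
    s <- randSeq2(40)
    lambda <- 3; w <- 0.5
    og <- substring(s, 1:39, 2:40)
    theta <- numeric(lambda)
    for (j in 1:lambda) {
      acc <- 0
      for (i in 1:(length(og) - j)) {
        d2 <- mean((props[, og[i]] - props[, og[i + j]])^2)
        acc <- acc + d2
      }
      theta[j] <- acc / (length(og) - j)
    }
    f <- table(factor(og, levels = allKmers(2))) / length(og)
    want <- c(as.numeric(f), w * theta) / (1 + w * sum(theta))
    got <- pseNc(s, "PseDNC", lambda = lambda, w = w)
    expect_equal(unname(got[1, ]), want, tolerance = 1e-12)
  }
})

test_that("acc output is zero for property-constant sequences", {
  z <- accProfile(strrep("A", 50), "DACC", lagMax = 3)
  expect_equal(unname(z[1, ]), rep(0, 36 * 3))
  expect_equal(ncol(accProfile(strrep("ACG", 30), "DACC", lagMax = 1)), 36)
  expect_equal(ncol(accProfile(strrep("ACG", 30), "TACC", lagMax = 7)), 28)
})

test_that("acc matches a literal double-loop oracle", {
  set.seed(41)
  props <- lncEnsemble:::.DINUC_PROPS_STD
  for (rep in 1:10) {
    s <- randSeq2(sample(15:40, 1))
    lagMax <- 3
    og <- substring(s, 1:(nchar(s) - 1), 2:nchar(s))
    n <- length(og)
    sv <- props[, og]
    want <- numeric(0)
    for (i in 1:6) {
      for (lg in 1:lagMax) {
        acc <- 0
        for (j in 1:(n - lg))
          acc <- acc + (sv[i, j] - mean(sv[i, ])) *
            (sv[i, j + lg] - mean(sv[i, ]))
        want <- c(want, acc / (n - lg))
      }
    }
    for (i1 in 1:6) for (i2 in 1:6) {
      if (i1 == i2) next
      for (lg in 1:lagMax) {
        acc <- 0
        for (j in 1:(n - lg))
          acc <- acc + (sv[i1, j] - mean(sv[i1, ])) *
            (sv[i2, j + lg] - mean(sv[i2, ]))
        want <- c(want, acc / (n - lg))
      }
    }
    got <- accProfile(s, "DACC", lagMax = lagMax)
    expect_equal(unname(got[1, ]), want, tolerance = 1e-10)
  }
})

test_that("property rows are standardized so offsets cancel", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(10, 10, 10, 10))
  st <- lncEnsemble:::.standardizeRows(m)
  expect_equal(mean(st["a", ]), 0)
  expect_equal(stats::sd(st["a", ]), 1)
  expect_equal(unname(st["b", ]), rep(0, 4))
  shifted <- lncEnsemble:::.standardizeRows(m + 100)
  expect_equal(st, shifted)
})

test_that("too-short sequences for the lag raise an error", {
  expect_error(accProfile("ACGTAC", "DACC", lagMax = 7), "too short")
})
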