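# Packaged constant tables.
#
# Provenance:
#  - Fickett TESTCODE position/content probabilities and weights: Fickett
#    (1982), as transcribed in the CPAT lineage of coding-potential tools.
#  - Kyte-Doolittle hydropathy: Kyte & Doolittle (1982).
#  - DIWV dipeptide instability weights: Guruprasad, Reddy & Pandit (1990).
#  - pKa set: Bjellqvist et al., as used by Expasy.
#  - Dinucleotide step parameters: representative B-DNA base-step values
#    (twist after Gorin, Zhurkin & Olson 1995; remaining steps literature
#    B-DNA averages). Rows are standardized to mean 0 / sd 1 over the 16
#    dinucleotides before any use, so only relative patterns matter.
#  - Trinucleotide property tracks are composed from the step parameters
#    (per-trinucleotide mean of its two steps and step-to-step change),
#    giving the 12 standardized tracks required by the series-correlation
#    trinucleotide composition and the 2 composite flexibility tracks used
#    by the trinucleotide auto-cross covariance.
#  - Biased codon table: human-like codon usage (frequencies per thousand),
#    used only by the synthetic generator.

.BASES <- c("A", "C", "G", "T")

.STOP_CODONS <- c("TAA", "TAG", "TGA")

## ---- Fickett TESTCODE lookup tables ----

.FICKETT <- local({
  posProb <- rbind(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  posWeight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  posPara <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  contProb <- rbind(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  contWeight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  contPara <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0.15, 0.0)
  list(posProb = posProb, posWeight = posWeight, posPara = posPara,
       contProb = contProb, contWeight = contWeight, contPara = contPara)
})

## ---- peptide scales ----

.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# DIWV[x, y] is the instability weight of dipeptide xy.
.DIWV <- local({
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix(c(
    1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
    1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
    1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
    1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
    -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
    1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
    1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
    13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
    1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
    20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
    1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
    1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
    1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
    1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
    1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
    -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
    24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34),
    nrow = 20, byrow = TRUE, dimnames = list(aa, aa))
  m
})

# Bjellqvist/Expasy pKa values; groups signed by charge at low pH.
.PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
.PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)

## ---- physicochemical property tracks ----

# B-DNA base-step parameters, one row per property, columns in
# lexicographic dinucleotide order. Reverse-complement symmetric.
.DINUC_PROPS <- local({
  dinucs <- as.vector(outer(.BASES, .BASES, paste0))
  m <- rbind(
    twist = c(35.62, 34.40, 27.70, 31.50, 34.50, 33.67, 29.80, 27.70,
              36.90, 40.00, 33.67, 34.40, 36.00, 36.90, 34.50, 35.62),
    tilt  = c( 0.90,  0.50,  1.70,  0.00,  0.10,  0.40,  0.00,  1.70,
               1.50,  0.00,  0.40,  0.50,  0.00,  1.50,  0.10,  0.90),
    roll  = c( 0.70,  0.70,  4.50,  1.10,  4.70,  3.60,  5.40,  4.50,
               1.90,  0.30,  3.60,  0.70,  3.30,  1.90,  4.70,  0.70),
    shift = c(-0.03,  0.13,  0.09,  0.00,  0.09,  0.05, -0.28,  0.09,
              -0.20, -0.22,  0.05,  0.13,  0.00, -0.20,  0.09, -0.03),
    slide = c(-0.08, -0.58, -0.25, -0.59,  0.53, -0.22,  0.41, -0.25,
               0.09,  0.05, -0.22, -0.58,  0.05,  0.09,  0.53, -0.08),
    rise  = c( 3.16,  3.41,  3.63,  3.89,  3.23,  4.08,  3.60,  3.63,
               3.47,  3.81,  4.08,  3.41,  3.21,  3.47,  3.23,  3.16))
  colnames(m) <- dinucs
  m
})

# Standardize each property row to mean 0 / sd 1 over its oligomer alphabet.
.standardizeRows <- function(m) {
  t(apply(m, 1L, function(r) {
    s <- stats::sd(r)
    if (s == 0) r - mean(r) else (r - mean(r)) / s
  }))
}

.DINUC_PROPS_STD <- .standardizeRows(.DINUC_PROPS)

# Trinucleotide tracks composed from the step parameters: for trinucleotide
# XYZ with steps XY and YZ, '<p>.mean' = (p(XY) + p(YZ))/2 and '<p>.delta'
# = p(YZ) - p(XY). Twelve tracks in total.
.TRINUC_PROPS <- local({
  trinucs <- as.vector(vapply(.BASES, function(a)
    outer(paste0(a, .BASES), .BASES, paste0), matrix("", 4, 4)))
  trinucs <- sort(trinucs)
  s1 <- substr(trinucs, 1, 2)
  s2 <- substr(trinucs, 2, 3)
  rows <- list()
  for (p in rownames(.DINUC_PROPS)) {
    v1 <- .DINUC_PROPS[p, s1]
    v2 <- .DINUC_PROPS[p, s2]
    rows[[paste0(p, ".mean")]] <- (v1 + v2) / 2
    rows[[paste0(p, ".delta")]] <- v2 - v1
  }
  m <- do.call(rbind, rows)
  colnames(m) <- trinucs
  m
})

.TRINUC_PROPS_STD <- .standardizeRows(.TRINUC_PROPS)

# Composite flexibility tracks for the trinucleotide auto-cross covariance
# (two properties, as the 4 x LAG dimensionality requires).
.TACC_PROPS <- c("roll.mean", "twist.mean")

## ---- codon usage (synthetic generator only) ----

# Human-like codon usage, frequencies per thousand codons; stop codons
# removed and the rest renormalized at use time.
.CODON_USAGE <- c(
  TTT = 17.6, TTC = 20.3, TTA =  7.7, TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA =  7.2, CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA =  7.5, ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA =  7.1, GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG =  4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG =  6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG =  6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG =  7.4,
  TAT = 12.2, TAC = 15.3, TAA =  1.0, TAG =  0.8,
  CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
  AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
  GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
  TGT = 10.6, TGC = 12.6, TGA =  1.6, TGG = 13.2,
  CGT =  4.5, CGC = 10.4, CGA =  6.2, CGG = 11.4,
  AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
  GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5)
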