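# Residue-level lookup tables shared by the parameter scorers.

# 3-letter -> 1-letter codes, canonical 20 residues only.
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

AA_ALPHABET <- unname(AA_THREE_TO_ONE)

# AGGRESCAN intrinsic aggregation-propensity values (a3v), one per residue,
# from the published method (v1 scale, derived from in-vivo amyloid data).
AGGRESCAN_A3V <- c(
  I =  1.822, F =  1.754, V =  1.594, L =  1.380, Y =  1.159,
  W =  1.037, M =  0.910, C =  0.604, A = -0.036, T = -0.159,
  S = -0.294, P = -0.334, G = -0.535, K = -0.931, H = -1.033,
  Q = -1.231, R = -1.240, N = -1.302, E = -1.412, D = -1.836)

# Hot-spot threshold on the windowed profile (published constant).
AGGRESCAN_HST <- -0.02

# Chou-Fasman secondary-structure propensities (helix Pa, strand Pb).
CHOU_FASMAN <- list(
  H = c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57,
        H = 1.00, I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67,
        P = 0.57, Q = 1.11, R = 0.98, S = 0.77, T = 0.83, V = 1.06,
        W = 1.08, Y = 0.69),
  E = c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75,
        H = 0.87, I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89,
        P = 0.55, Q = 1.10, R = 0.93, S = 0.75, T = 1.19, V = 1.70,
        W = 1.37, Y = 1.47))

# Hydrophobicity classes: nonpolar vs polar-or-charged (pH 7).
AA_NONPOLAR <- c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W")

# Formal charge class at pH 7 (His counted positive).
AA_CHARGE <- c(D = -1, E = -1, K = 1, R = 1, H = 1)

# Theoretical maximum accessible surface areas (A^2), Tien et al. 2013,
# used to normalise absolute ASA into relative solvent accessibility.
MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

aa_charge <- function(aa) {
  ch <- AA_CHARGE[aa]
  ch[is.na(ch)] <- 0L
  unname(ch)
}

aa_is_nonpolar <- function(aa) aa %in% AA_NONPOLAR

check_aa <- function(aa, what = "residue") {
  bad <- setdiff(aa, AA_ALPHABET)
  if (length(bad))
    stop(sprintf("unknown %s code: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(aa)
}
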