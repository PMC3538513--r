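# Element parameter tables used by the descriptor registry.
#
# Columns:
#   mass   - standard average atomic mass (IUPAC)
#   sand   - Sanderson electronegativity (Sanderson scale)
#   polar  - atomic static polarizability, 1e-24 cm^3 (CRC handbook values)
#   zv     - number of valence electrons
#   pqn    - principal quantum number of the valence shell
#   z      - atomic number
#   defval - default (lowest common) valence used for implicit-H assignment;
#            NA means the element never receives implicit hydrogens
.element_table <- local({
  tab <- rbind(
    #        mass      sand   polar     zv pqn  z  defval
    H  = c(  1.00794, 2.592, 0.666793,  1, 1,  1,  1),
    B  = c( 10.811,   2.275, 3.03,      3, 2,  5,  3),
    C  = c( 12.0107,  2.746, 1.76,      4, 2,  6,  4),
    N  = c( 14.0067,  3.194, 1.10,      5, 2,  7,  3),
    O  = c( 15.9994,  3.654, 0.802,     6, 2,  8,  2),
    F  = c( 18.9984,  4.000, 0.557,     7, 2,  9,  1),
    Na = c( 22.9898,  0.835, 24.08,     1, 3, 11, NA),
    Mg = c( 24.305,   1.318, 10.6,      2, 3, 12, NA),
    Al = c( 26.9815,  1.714, 6.8,       3, 3, 13,  3),
    Si = c( 28.0855,  2.138, 5.38,      4, 3, 14,  4),
    P  = c( 30.9738,  2.515, 3.63,      5, 3, 15,  3),
    S  = c( 32.065,   2.957, 2.90,      6, 3, 16,  2),
    Cl = c( 35.453,   3.475, 2.18,      7, 3, 17,  1),
    K  = c( 39.0983,  0.445, 43.4,      1, 4, 19, NA),
    Ca = c( 40.078,   0.946, 22.8,      2, 4, 20, NA),
    Fe = c( 55.845,   2.000, 8.4,       8, 4, 26, NA),
    Zn = c( 65.38,    2.223, 5.75,      2, 4, 30, NA),
    Se = c( 78.96,       NA, NA,        6, 4, 34,  2),
    Br = c( 79.904,   3.219, 3.05,      7, 4, 35,  1),
    I  = c(126.9045,  2.778, 5.35,      7, 5, 53,  1)
  )
  colnames(tab) <- c("mass", "sand", "polar", "zv", "pqn", "z", "defval")
  tab
})

# Higher-valence states permitted when the bond-order sum exceeds the default
# (hypervalent S and P); used before falling back to zero implicit hydrogens.
.hyper_valences <- list(S = c(2, 4, 6), P = c(3, 5), N = 3, C = 4, O = 2)

.element_param <- function(symbol, what) {
  idx <- match(symbol, rownames(.element_table))
  out <- rep(NA_real_, length(symbol))
  ok <- !is.na(idx)
  out[ok] <- .element_table[idx[ok], what]
  out
}

# Selenium carries graph-level parameters (mass, valence) but deliberately
# no electronegativity/polarizability values, so the "missing parameter"
# contract of the chemical-properties descriptors stays exercised:
# contributions fall back to 0 with a warning.

# Kier alpha contributions alpha_i = r_i/r(Csp3) - 1 by element+hybridization
# (Kier's covalent-radius ratios). Keys are "<element>.<hyb>" with hyb in
# sp3/sp2/sp; elements missing from this list contribute 0.
.kier_alpha <- c(
  "C.sp3" = 0.00,  "C.sp2" = -0.13, "C.sp" = -0.22,
  "N.sp3" = -0.04, "N.sp2" = -0.20, "N.sp" = -0.29,
  "O.sp3" = -0.04, "O.sp2" = -0.20,
  "F.sp3" = -0.07,
  "Cl.sp3" = 0.29, "Br.sp3" = 0.48, "I.sp3" = 0.73,
  "P.sp3" = 0.43,  "S.sp3" = 0.35,  "S.sp2" = 0.35,
  "Si.sp3" = 0.64, "B.sp3" = 0.30, "B.sp2" = 0.30
)
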