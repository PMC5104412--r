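# Element data tables used across the descriptor engine.

# Standard atomic weights (IUPAC 2021, conventional values).
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  Na = 22.990, K = 39.098, Li = 6.94, Mg = 24.305, Ca = 40.078,
  Zn = 65.38, Fe = 55.845, Se = 78.971
)

# Bondi van der Waals radii (Angstrom); elements without a Bondi value get
# a generic 1.8 A sphere.
.VDW_RADIUS <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
  Na = 2.27, K = 2.75, Li = 1.82, Mg = 1.73, Ca = 2.31,
  Zn = 1.39, Fe = 1.80, Se = 1.90
)

# Default valences used to infer implicit hydrogens on neutral atoms.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Na = 1, K = 1, Li = 1, Mg = 2, Ca = 2,
  Zn = 2, Fe = 2, Se = 2
)

# X-H bond lengths (Angstrom) for idealized hydrogen placement.
.XH_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34, B = 1.19, Si = 1.48, P = 1.42, Se = 1.46)

.elementMass <- function(el) {
  m <- .ATOMIC_MASS[el]
  if (anyNA(m)) stop("no atomic mass for element(s): ", paste(el[is.na(m)], collapse = ", "))
  unname(m)
}

.elementRadius <- function(el) {
  r <- .VDW_RADIUS[el]
  r[is.na(r)] <- 1.8
  unname(r)
}

# Gasteiger-Marsili electronegativity parameters chi(q) = a + b q + c q^2
# per orbital state (Tetrahedron 36, 3219 (1980)). Keys are element +
# hybridisation; the iterative partial-equalisation routine selects them
# from the perceived hybridisation.
.GASTEIGER <- rbind(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S.sp3  = c(10.14, 9.13, 1.38),
  S.sp2  = c(10.14, 9.13, 1.38),
  P.sp3  = c(8.90, 8.24, 0.96)
)
colnames(.GASTEIGER) <- c("a", "b", "c")
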