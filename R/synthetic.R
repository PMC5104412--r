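#' @include AllClasses.R AllGenerics.R sdf-io.R chem-graph.R descriptors.R
NULL

# ---- geometry builder ---------------------------------------------------
# Molecules are assembled from fragments (alkyl chains, a benzene ring,
# OH/NH2/COOH/halide substituents) on idealized geometry: tetrahedral
# zigzag chains (C-C 1.54 A), planar Kekule hexagons (C-C 1.39 A), standard
# single-bond lengths to substituents. Heavy-atom skeletons are completed
# with idealized explicit hydrogens and finally tilted out of the xy plane
# by a fixed rotation so that 3-D descriptors see non-degenerate
# coordinates.

.emptyMol <- function(name) {
  new("Molecule", name = name, comment = "",
      atoms = data.frame(element = character(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), charge = integer(0)),
      bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
      fields = character(0))
}

.addAtom <- function(mol, element, xyz, charge = 0L) {
  mol@atoms <- rbind(mol@atoms, data.frame(
    element = element, x = xyz[1], y = xyz[2], z = xyz[3], charge = as.integer(charge)))
  mol
}

.addBond <- function(mol, i, j, order = 1L) {
  mol@bonds <- rbind(mol@bonds, data.frame(i = as.integer(i), j = as.integer(j),
                                           order = as.integer(order)))
  mol
}

.rotXY <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2], v[3])
}

# zigzag carbon chain along +x starting at 'origin'; returns mol + indices
.addChain <- function(mol, n, origin = c(0, 0, 0)) {
  idx <- integer(n)
  for (k in seq_len(n)) {
    pos <- origin + c(1.258 * (k - 1), 0.889 * ((k - 1) %% 2), 0)
    mol <- .addAtom(mol, "C", pos)
    idx[k] <- nrow(mol@atoms)
    if (k > 1) mol <- .addBond(mol, idx[k - 1], idx[k], 1L)
  }
  list(mol = mol, idx = idx)
}

# planar Kekule hexagon centred at 'centre'; heteroPos replaces one carbon
# (1-based vertex) by the given element. Returns mol + vertex indices.
.addHexagon <- function(mol, centre = c(0, 0, 0), hetero = NULL, heteroPos = 1L,
                        orders = c(2L, 1L, 2L, 1L, 2L, 1L)) {
  idx <- integer(6)
  for (k in 1:6) {
    th <- pi / 3 * (k - 1)
    el <- if (!is.null(hetero) && k == heteroPos) hetero else "C"
    mol <- .addAtom(mol, el, centre + 1.39 * c(cos(th), sin(th), 0))
    idx[k] <- nrow(mol@atoms)
  }
  for (k in 1:6) mol <- .addBond(mol, idx[k], idx[k %% 6 + 1], orders[k])
  list(mol = mol, idx = idx)
}

# attach a substituent group to atom 'at' growing in unit direction 'dir'
.attach <- function(mol, at, dir, kind) {
  pos <- unlist(mol@atoms[at, c("x", "y", "z")])
  add1 <- function(mol, el, dist, charge = 0L, order = 1L, d = dir) {
    mol <- .addAtom(mol, el, pos + dist * d, charge)
    .addBond(mol, at, nrow(mol@atoms), order)
  }
  if (kind == "none") return(mol)
  if (kind == "OH") return(add1(mol, "O", 1.43))
  if (kind == "NH2") return(add1(mol, "N", 1.47))
  if (kind == "F") return(add1(mol, "F", 1.35))
  if (kind == "Cl") return(add1(mol, "Cl", 1.77))
  if (kind == "CH3") return(add1(mol, "C", 1.54))
  if (kind == "COOH" || kind == "COO-") {
    cpos <- pos + 1.52 * dir
    mol <- .addAtom(mol, "C", cpos)
    cIdx <- nrow(mol@atoms)
    mol <- .addBond(mol, at, cIdx, 1L)
    d1 <- .rotXY(dir, 120)
    d2 <- .rotXY(dir, -120)
    mol <- .addAtom(mol, "O", cpos + 1.23 * d1)
    mol <- .addBond(mol, cIdx, nrow(mol@atoms), 2L)
    mol <- .addAtom(mol, "O", cpos + 1.36 * d2,
                    charge = if (kind == "COO-") -1L else 0L)
    mol <- .addBond(mol, cIdx, nrow(mol@atoms), 1L)
    return(mol)
  }
  if (kind == "NH3+") {
    mol <- .addAtom(mol, "N", pos + 1.49 * dir, charge = 1L)
    return(.addBond(mol, at, nrow(mol@atoms), 1L))
  }
  stop("unknown substituent: ", kind)
}

# finalize: explicit hydrogens + fixed tilt out of the construction plane
.finishMol <- function(mol) {
  mol <- .addExplicitH(mol)
  xyz <- as.matrix(mol@atoms[, c("x", "y", "z")])
  a <- 10 * pi / 180; b <- 7 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  xyz <- xyz %*% t(Ry %*% Rx)
  mol@atoms$x <- round(xyz[, 1], 4)
  mol@atoms$y <- round(xyz[, 2], 4)
  mol@atoms$z <- round(xyz[, 3], 4)
  validObject(mol)
  mol
}

# assemble one molecule from a plan: chainLength (0..6), ring flag,
# substituents at the head and tail attachment points
.assembleMolecule <- function(name, chainLength, ring = FALSE,
                              headSub = "none", tailSub = "none") {
  if (chainLength == 0 && !ring) stop("empty plan")
  mol <- .emptyMol(name)
  head <- tail <- NA_integer_
  if (chainLength > 0) {
    ch <- .addChain(mol, chainLength)
    mol <- ch$mol
    head <- ch$idx[1]
    tail <- ch$idx[chainLength]
  }
  if (ring) {
    cx <- if (chainLength > 0) {
      unlist(mol@atoms[tail, c("x", "y", "z")]) + c(1.50 + 1.39, 0, 0)
    } else {
      c(0, 0, 0)
    }
    hx <- .addHexagon(mol, centre = cx)
    mol <- hx$mol
    if (chainLength > 0) {
      mol <- .addBond(mol, tail, hx$idx[4], 1L)  # vertex pointing back (-x)
      tail <- hx$idx[1]                          # para position grows +x
    } else {
      head <- hx$idx[4]
      tail <- hx$idx[1]
    }
  }
  if (!is.na(head) && headSub != "none") mol <- .attach(mol, head, c(-1, 0, 0), headSub)
  if (!is.na(tail) && tailSub != "none") mol <- .attach(mol, tail, c(1, 0, 0), tailSub)
  .finishMol(mol)
}

# ---- fixture library ----------------------------------------------------

#' Hand-curated fixture molecules
#'
#' A deterministic [MoleculeSet] of 16 small organic molecules with
#' idealized explicit-hydrogen 3-D geometry, spanning the structural
#' features the descriptor engine must handle: plain alkanes (methane,
#' n-butane), alcohols and acids (ethanol, phenol, acetic acid), aromatics
#' and heteroaromatics (benzene, toluene, pyridine), an amide (acetamide),
#' an ether, an amine, a halide, an sp carbon (propyne), a saturated ring
#' (cyclohexane), and a zwitterion (glycine as NH3+/COO-) echoing the
#' zwitterionic outlier problem of Caco-2 permeability models. All
#' descriptor expectations for these molecules are derivable by hand.
#'
#' @return a [MoleculeSet] with `source = "fixture"`.
#' @examples
#' fixtureLibrary()[["benzene"]]
#' @export
fixtureLibrary <- function() {
  mols <- list()
  add <- function(m) mols[[m@name]] <<- m

  methane <- .finishMol(.addAtom(.emptyMol("methane"), "C", c(0, 0, 0)))
  add(methane)
  add(.assembleMolecule("ethane", 2))
  add(.assembleMolecule("ethanol", 2, tailSub = "OH"))
  add(.assembleMolecule("n-butane", 4))
  add(.assembleMolecule("benzene", 0, ring = TRUE))
  add(.assembleMolecule("toluene", 1, ring = TRUE))
  add(.assembleMolecule("phenol", 0, ring = TRUE, tailSub = "OH"))
  add(.assembleMolecule("acetic_acid", 1, tailSub = "COOH"))
  add(.assembleMolecule("ethylamine", 2, tailSub = "NH2"))
  add(.assembleMolecule("chloroethane", 2, tailSub = "Cl"))

  # pyridine: hexagon with one nitrogen
  pyr <- .addHexagon(.emptyMol("pyridine"), hetero = "N", heteroPos = 1L)
  add(.finishMol(pyr$mol))

  # cyclohexane: saturated hexagon (all single bonds)
  cyh <- .addHexagon(.emptyMol("cyclohexane"), orders = rep(1L, 6))
  add(.finishMol(cyh$mol))

  # dimethyl ether: C-O-C
  dme <- .emptyMol("dimethyl_ether")
  dme <- .addAtom(dme, "C", c(0, 0, 0))
  dme <- .addAtom(dme, "O", c(1.22, 0.76, 0))
  dme <- .addAtom(dme, "C", c(2.44, 0, 0))
  dme <- .addBond(.addBond(dme, 1, 2), 2, 3)
  add(.finishMol(dme))

  # acetamide: CH3-C(=O)-NH2
  acm <- .emptyMol("acetamide")
  acm <- .addAtom(acm, "C", c(0, 0, 0))
  acm <- .addAtom(acm, "C", c(1.52, 0, 0))
  acm <- .addAtom(acm, "O", c(2.14, 1.07, 0))
  acm <- .addAtom(acm, "N", c(2.20, -1.18, 0))
  acm <- .addBond(acm, 1, 2)
  acm <- .addBond(acm, 2, 3, 2L)
  acm <- .addBond(acm, 2, 4)
  add(.finishMol(acm))

  # propyne: HC#C-CH3
  prp <- .emptyMol("propyne")
  prp <- .addAtom(prp, "C", c(0, 0, 0))
  prp <- .addAtom(prp, "C", c(1.20, 0, 0))
  prp <- .addAtom(prp, "C", c(2.66, 0, 0))
  prp <- .addBond(prp, 1, 2, 3L)
  prp <- .addBond(prp, 2, 3, 1L)
  add(.finishMol(prp))

  # glycine zwitterion: +H3N-CH2-COO-
  gly <- .emptyMol("glycine_zwitterion")
  gly <- .addAtom(gly, "C", c(0, 0, 0))
  gly <- .attach(gly, 1, c(-1, 0, 0), "NH3+")
  gly <- .attach(gly, 1, c(1, 0, 0), "COO-")
  add(.finishMol(gly))

  new("MoleculeSet", molecules = unname(mols), source = "fixture",
      propertyTag = NA_character_, nSkipped = 0L)
}

# ---- synthetic set generation ------------------------------------------

#' Configure a synthetic molecule set
#'
#' Builds a validated [SyntheticSetConfig]: `nMolecules` molecules will be
#' assembled from the fragment library, the named descriptors computed,
#' and the property written as
#' `intercept + sum(coefficients * descriptors) + Normal(0, noiseSigma)`.
#'
#' @param nMolecules number of molecules (at least
#'   `length(trueCoefficients) + 2`).
#' @param seed integer seed; the generated set (including the SDF bytes it
#'   writes) is a pure function of the configuration.
#' @param trueCoefficients named numeric vector of ground-truth weights;
#'   names must exist in [descriptorRegistry()].
#' @param trueIntercept ground-truth intercept.
#' @param noiseSigma Gaussian noise standard deviation on the property
#'   scale (0 = noiseless).
#' @param propertyTag SD field name to write the property to.
#' @return a [SyntheticSetConfig].
#' @seealso [generateSyntheticSet()]
#' @export
syntheticConfig <- function(nMolecules, seed,
                            trueCoefficients = c(
                              molecular_weight = -0.02,
                              hbd_count = 0.6,
                              rotatable_bond_count = -0.25,
                              aromatic_atom_proportion = -1.2
                            ),
                            trueIntercept = 0.5,
                            noiseSigma = 0.5,
                            propertyTag = "PROPERTY") {
  cfg <- new("SyntheticSetConfig",
    nMolecules = as.integer(nMolecules), seed = as.integer(seed),
    trueCoefficients = trueCoefficients, trueIntercept = trueIntercept,
    noiseSigma = noiseSigma, propertyTag = propertyTag)
  validObject(cfg)
  cfg
}

# run expr under a local RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic molecule set with known ground truth
#'
#' Assembles `nMolecules` chemically valid small organic molecules by
#' seeded sampling from a fragment library (alkyl chains of 1-6 carbons,
#' an optional benzene ring, and OH/NH2/COOH/F/Cl substituents) with
#' idealized 3-D geometry and explicit hydrogens, computes the descriptors
#' named in the configuration, and writes the property
#' `intercept + X beta + Normal(0, noiseSigma)` into the configured SD
#' field (17 significant digits). The generator seed is recorded in each
#' record's comment line. The result is fully reproducible from the
#' configuration: the same config yields byte-identical SDF output.
#'
#' @param config a [SyntheticSetConfig].
#' @return a [MoleculeSet] with `source = "synthetic"` and the property
#'   tag set.
#' @examples
#' set <- generateSyntheticSet(syntheticConfig(12, seed = 1, noiseSigma = 0))
#' propertyValues(set)[1:3]
#' @export
generateSyntheticSet <- function(config) {
  stopifnot(is(config, "SyntheticSetConfig"))
  validObject(config)
  reg <- descriptorRegistry()
  specs <- reg[names(config@trueCoefficients)]
  n <- config@nMolecules

  subs <- c("none", "OH", "NH2", "COOH", "F", "Cl")
  subW <- c(0.40, 0.18, 0.14, 0.10, 0.09, 0.09)
  mols <- .withSeed(config@seed, {
    lapply(seq_len(n), function(i) {
      ring <- stats::runif(1) < 0.4
      chainLength <- if (ring) sample(0:3, 1) else sample(1:6, 1)
      headSub <- if (chainLength > 0) sample(subs, 1, prob = subW) else "none"
      tailSub <- sample(subs, 1, prob = subW)
      m <- .assembleMolecule(sprintf("SYN%04d", i), chainLength, ring,
                             headSub, tailSub)
      m@comment <- sprintf("qsprlm synthetic seed=%d", config@seed)
      m
    })
  })
  set <- new("MoleculeSet", molecules = mols, source = "synthetic",
             propertyTag = config@propertyTag, nSkipped = 0L)
  X <- buildDescriptorMatrix(set, specs)
  if (any(X@missing)) stop("internal: synthetic molecules must yield complete descriptors")
  y <- config@trueIntercept +
    drop(X@values %*% config@trueCoefficients[colnames(X@values)])
  if (config@noiseSigma > 0) {
    # separate stream so structure sampling and noise stay decoupled
    y <- y + .withSeed(config@seed + 1L,
                       stats::rnorm(n, 0, config@noiseSigma))
  }
  for (i in seq_len(n)) {
    set@molecules[[i]]@fields[config@propertyTag] <- sprintf("%.17g", y[i])
  }
  set
}
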