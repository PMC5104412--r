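#' @include AllClasses.R AllGenerics.R
NULL

.spec <- function(name, family, requires3D = FALSE, parameters = list()) {
  new("DescriptorSpec", name = name, family = family,
      requires3D = requires3D, parameters = parameters)
}

#' The default descriptor registry
#'
#' Returns the named list of [DescriptorSpec] objects the engine computes
#' out of the box. These are the descriptors used by the published linear
#' models for aqueous solubility, blood-brain barrier permeation and Caco-2
#' permeability that this engine reproduces: size and constitution
#' (`molecular_weight`, `heavy_atom_count`, `molecular_volume` — additive
#' van der Waals sphere volume), hydrogen bonding (`hbd_count`,
#' `hba_count`), topology (`rotatable_bond_count`,
#' `aromatic_atom_proportion`, `topological_polar_surface_area` — Ertl
#' fragment method via Open Babel), lipophilicity (`clogp` —
#' Wildman-Crippen atomic contribution via Open Babel), 3-D shape
#' (`radius_of_gyration`, mass-weighted) and charged surface (`pnsa2` —
#' Stanton-Jurs total-charge-weighted partial negative surface area over a
#' Shrake-Rupley solvent-accessible surface with Gasteiger-Marsili charges;
#' `psa_3d` — polar-atom contribution to the same surface). Group-count
#' descriptors for arbitrary SMARTS patterns are added with
#' [smartsCountSpec()].
#'
#' @return named list of [DescriptorSpec].
#' @seealso [computeDescriptor()], [buildDescriptorMatrix()], [smartsCountSpec()]
#' @examples
#' names(descriptorRegistry())
#' @export
descriptorRegistry <- function() {
  specs <- list(
    .spec("molecular_weight", "constitutional"),
    .spec("heavy_atom_count", "constitutional"),
    .spec("molecular_volume", "constitutional"),
    .spec("clogp", "constitutional"),
    .spec("hbd_count", "hbond"),
    .spec("hba_count", "hbond"),
    .spec("rotatable_bond_count", "topological"),
    .spec("aromatic_atom_proportion", "topological"),
    .spec("topological_polar_surface_area", "topological"),
    .spec("psa_3d", "surface", requires3D = TRUE),
    .spec("pnsa2", "charge_surface", requires3D = TRUE),
    .spec("radius_of_gyration", "geometric", requires3D = TRUE)
  )
  names(specs) <- vapply(specs, function(s) s@name, character(1))
  specs
}

#' Define a SMARTS group-count descriptor
#'
#' Builds a [DescriptorSpec] of the `group_count` family that counts the
#' unique matches of a SMARTS pattern in each molecule (matching is
#' performed by Open Babel). Group counts generalise the classical
#' group-contribution descriptor tables used by fragment-based solubility
#' models.
#'
#' @param name descriptor id.
#' @param smarts SMARTS pattern, e.g. `"[OX2H]"` for hydroxyl groups.
#' @return a [DescriptorSpec].
#' @examples
#' spec <- smartsCountSpec("carbon_count", "[#6]")
#' computeDescriptor(fixtureLibrary()[["ethanol"]], spec)
#' @export
smartsCountSpec <- function(name, smarts) {
  if (missing(smarts) || is.null(smarts) || !nzchar(smarts)) {
    stop("group_count descriptor '", name, "' needs a SMARTS pattern")
  }
  .spec(name, "group_count", parameters = list(smarts = smarts))
}

# ---- native descriptor implementations ---------------------------------

.descMolecularWeight <- function(mol) {
  sum(.elementMass(mol@atoms$element)) + sum(.implicitH(mol)) * .ATOMIC_MASS[["H"]]
}

.descHeavyAtomCount <- function(mol) sum(mol@atoms$element != "H")

.descMolecularVolume <- function(mol) {
  r <- c(.elementRadius(mol@atoms$element),
         rep(.VDW_RADIUS[["H"]], sum(.implicitH(mol))))
  sum(4 / 3 * pi * r^3)
}

# H-bond donors: N/O/S heavy atoms carrying at least one hydrogen
# (explicit or implicit).
.descHbdCount <- function(mol) {
  el <- mol@atoms$element
  g <- .adjacency(mol)
  imp <- .implicitH(mol)
  sum(vapply(seq_along(el), function(i) {
    if (!el[i] %in% c("N", "O", "S")) return(FALSE)
    imp[i] > 0 || any(el[g$nbr[[i]]] == "H")
  }, logical(1)))
}

# H-bond acceptors: N and O atoms that are not positively charged,
# excluding pyrrole-type aromatic nitrogens (ring N donating its lone pair
# to the aromatic system: aromatic N with three sigma neighbours or an H)
# and amide nitrogens (N single-bonded to a carbonyl carbon).
.descHbaCount <- function(mol) {
  el <- mol@atoms$element
  chg <- mol@atoms$charge
  g <- .adjacency(mol)
  imp <- .implicitH(mol)
  arom <- .aromaticAtoms(mol)
  isCarbonyl <- vapply(seq_along(el), function(i) {
    el[i] == "C" && any(g$ord[[i]] == 2 & el[g$nbr[[i]]] == "O")
  }, logical(1))
  sum(vapply(seq_along(el), function(i) {
    if (!el[i] %in% c("N", "O") || chg[i] > 0) return(FALSE)
    if (el[i] == "N") {
      nH <- imp[i] + sum(el[g$nbr[[i]]] == "H")
      heavyDeg <- sum(el[g$nbr[[i]]] != "H")
      if (arom[i] && (nH > 0 || heavyDeg >= 3)) return(FALSE)   # pyrrole-type
      amide <- any(g$ord[[i]] == 1 & isCarbonyl[g$nbr[[i]]])
      if (amide) return(FALSE)
    }
    TRUE
  }, logical(1)))
}

# Rotatable bonds: non-ring single bonds between two non-terminal heavy
# atoms (terminal = only one heavy neighbour).
.descRotatableBonds <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(0)
  el <- mol@atoms$element
  g <- .adjacency(mol)
  heavyDeg <- vapply(seq_along(el), function(i) sum(el[g$nbr[[i]]] != "H"), integer(1))
  inRing <- .ringBondMask(mol)
  sum(b$order == 1L & !inRing &
        el[b$i] != "H" & el[b$j] != "H" &
        heavyDeg[b$i] >= 2 & heavyDeg[b$j] >= 2)
}

.descAromaticProportion <- function(mol) {
  heavy <- mol@atoms$element != "H"
  if (!any(heavy)) stop("molecule has no heavy atoms")
  sum(.aromaticAtoms(mol) & heavy) / sum(heavy)
}

.descRadiusOfGyration <- function(mol) {
  a <- mol@atoms
  m <- .elementMass(a$element)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(m * d2) / sum(m))
}

# Stanton-Jurs PNSA2: (sum of SAS over negatively charged atoms) x (total
# negative charge). Computed on the molecule with explicit hydrogens,
# Gasteiger-Marsili charges, Shrake-Rupley surface. Negative by
# construction whenever any atom carries negative charge.
.descPnsa2 <- function(mol, verbose = FALSE) {
  molH <- .addExplicitH(mol, verbose = verbose)
  q <- .gasteigerCharges(molH)
  sa <- .sasAreas(molH)
  neg <- q < 0
  sum(sa[neg]) * sum(q[neg])
}

# 3-D polar surface area: SAS contribution of N and O atoms plus hydrogens
# bonded to them.
.descPsa3d <- function(mol, verbose = FALSE) {
  molH <- .addExplicitH(mol, verbose = verbose)
  el <- molH@atoms$element
  g <- .adjacency(molH)
  polar <- el %in% c("N", "O")
  polarH <- vapply(seq_along(el), function(i) {
    el[i] == "H" && any(el[g$nbr[[i]]] %in% c("N", "O"))
  }, logical(1))
  sa <- .sasAreas(molH)
  sum(sa[polar | polarH])
}

# ---- dispatch ----------------------------------------------------------

# ob: optional list(obmol = <single OBMol ref>, props = <1-row prop table>)
# so that set-level computation can amortise the Open Babel conversion.
.computeOne <- function(mol, spec, ob = NULL) {
  if (spec@requires3D && !.has3D(mol)) {
    stop("descriptor '", spec@name, "' needs non-degenerate 3-D coordinates, ",
         "which molecule '", mol@name, "' lacks")
  }
  if (spec@family == "group_count") {
    smarts <- spec@parameters$smarts
    if (is.null(smarts)) stop("group_count descriptor '", spec@name, "' is unparameterized")
    refs <- if (is.null(ob)) .obMols(mol) else list(ob$obmol)
    return(.obSmartsCount(refs, smarts))
  }
  switch(spec@name,
    molecular_weight = .descMolecularWeight(mol),
    heavy_atom_count = .descHeavyAtomCount(mol),
    molecular_volume = .descMolecularVolume(mol),
    hbd_count = .descHbdCount(mol),
    hba_count = .descHbaCount(mol),
    rotatable_bond_count = .descRotatableBonds(mol),
    aromatic_atom_proportion = .descAromaticProportion(mol),
    radius_of_gyration = .descRadiusOfGyration(mol),
    pnsa2 = .descPnsa2(mol),
    psa_3d = .descPsa3d(mol),
    clogp = {
      p <- if (is.null(ob)) .obProps(.obMols(mol)) else ob$props
      as.numeric(p$logP[1])
    },
    topological_polar_surface_area = {
      p <- if (is.null(ob)) .obProps(.obMols(mol)) else ob$props
      as.numeric(p$TPSA[1])
    },
    stop("unknown descriptor: ", spec@name)
  )
}

#' Compute one descriptor on one molecule
#'
#' Deterministically evaluates a [DescriptorSpec] on a [Molecule].
#' Descriptors with `requires3D = TRUE` raise an error naming the molecule
#' and descriptor when the coordinates are degenerate (all atoms
#' coincident, or the all-zero z column of a 2-D file).
#'
#' @param mol a [Molecule].
#' @param spec a [DescriptorSpec] (from [descriptorRegistry()],
#'   [smartsCountSpec()] or a recipe).
#' @return a single numeric value; `group_count` descriptors return a
#'   non-negative integer-valued count.
#' @examples
#' eth <- fixtureLibrary()[["ethanol"]]
#' computeDescriptor(eth, descriptorRegistry()[["hbd_count"]])
#' @export
computeDescriptor <- function(mol, spec) {
  stopifnot(is(mol, "Molecule"), is(spec, "DescriptorSpec"))
  as.numeric(.computeOne(mol, spec))
}

#' Build the molecules x descriptors design matrix
#'
#' Evaluates every descriptor on every molecule of a set. Cells whose
#' descriptor cannot be computed (e.g. a 3-D descriptor on a flat molecule)
#' are flagged in the missing mask rather than aborting the build; a
#' summary of per-descriptor failure counts is logged. A descriptor that
#' fails on *all* molecules makes the column unusable and is a hard error.
#'
#' @param set a [MoleculeSet].
#' @param specs non-empty list of [DescriptorSpec] (default: the full
#'   registry).
#' @return a [DescriptorMatrix].
#' @seealso [computeDescriptor()], [descriptorRegistry()]
#' @export
buildDescriptorMatrix <- function(set, specs = descriptorRegistry()) {
  stopifnot(is(set, "MoleculeSet"))
  if (is(specs, "DescriptorSpec")) specs <- list(specs)
  if (!length(specs)) stop("no descriptors requested")
  nm <- unname(vapply(specs, function(s) s@name, character(1)))
  if (anyDuplicated(nm)) stop("duplicate descriptor names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(specs) <- nm
  mols <- set@molecules
  n <- length(mols)

  needsOB <- any(vapply(specs, function(s) {
    s@family == "group_count" || s@name %in% c("clogp", "topological_polar_surface_area")
  }, logical(1)))
  obRefs <- if (needsOB) .obMols(mols) else NULL
  needsProps <- any(nm %in% c("clogp", "topological_polar_surface_area"))
  obProps <- if (needsProps) .obProps(obRefs) else NULL

  vals <- matrix(NA_real_, n, length(specs),
                 dimnames = list(vapply(mols, function(m) m@name, character(1)), nm))
  miss <- matrix(FALSE, n, length(specs), dimnames = dimnames(vals))
  for (j in seq_along(specs)) {
    spec <- specs[[j]]
    if (spec@family == "group_count") {
      # one vectorised SMARTS pass over the whole set
      res <- tryCatch(.obSmartsCount(obRefs, spec@parameters$smarts),
                      error = function(e) rep(NA_real_, n))
      vals[, j] <- res
      miss[, j] <- is.na(res)
      next
    }
    for (i in seq_len(n)) {
      ob <- if (needsOB) list(obmol = obRefs[[i]], props = obProps[i, , drop = FALSE]) else NULL
      v <- tryCatch(.computeOne(mols[[i]], spec, ob = ob), error = function(e) NA_real_)
      vals[i, j] <- v
      miss[i, j] <- is.na(v)
    }
  }
  failures <- colSums(miss)
  if (any(failures > 0)) {
    message("descriptor failure counts: ",
            paste(sprintf("%s=%d", nm[failures > 0], failures[failures > 0]),
                  collapse = ", "))
  }
  dead <- nm[failures == n]
  if (length(dead)) {
    stop("descriptor(s) failed on every molecule: ", paste(dead, collapse = ", "))
  }
  new("DescriptorMatrix", values = vals, missing = miss)
}

#' Load a descriptor recipe file
#'
#' A recipe is a JSON or YAML document listing the descriptors of a model:
#' a `descriptors` array of registry names and an optional `groups` array
#' of `{name, smarts}` group-count definitions.
#'
#' @param path recipe file (`.json`, `.yml`/`.yaml`).
#' @return named list of [DescriptorSpec].
#' @export
loadRecipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("YAML recipes need the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  reg <- descriptorRegistry()
  specs <- list()
  for (d in doc$descriptors) {
    if (!d %in% names(reg)) stop("recipe names unknown descriptor '", d, "'")
    specs[[d]] <- reg[[d]]
  }
  if (!is.null(doc$groups)) {
    groups <- if (is.data.frame(doc$groups)) {
      split(doc$groups, seq_len(nrow(doc$groups)))
    } else {
      doc$groups
    }
    for (gr in groups) {
      specs[[gr$name]] <- smartsCountSpec(gr$name, gr$smarts)
    }
  }
  if (!length(specs)) stop("recipe defines no descriptors")
  specs
}

# ---- DescriptorMatrix methods ------------------------------------------

#' @rdname model-accessors
#' @export
setMethod("descriptorNames", "DescriptorMatrix", function(x) colnames(x@values))

#' @rdname model-accessors
#' @export
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)

#' @rdname model-accessors
#' @export
setMethod("missingMask", "DescriptorMatrix", function(x) x@missing)

#' @describeIn DescriptorMatrix number of molecules (rows).
#' @param x a `DescriptorMatrix`.
#' @export
setMethod("nrow", "DescriptorMatrix", function(x) base::nrow(x@values))

#' @describeIn DescriptorMatrix number of descriptors (columns).
#' @export
setMethod("ncol", "DescriptorMatrix", function(x) base::ncol(x@values))

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix: %d molecule(s) x %d descriptor(s); %d missing cell(s)\n",
              base::nrow(object@values), base::ncol(object@values), sum(object@missing)))
  cat("  descriptors:", paste(colnames(object@values), collapse = ", "), "\n")
})

#' @describeIn DescriptorMatrix coerce to a plain data.frame (missing
#'   cells become `NA`).
#' @param row.names,optional,... passed through per the generic signature.
#' @export
as.data.frame.DescriptorMatrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  as.data.frame(x@values, row.names = row.names, optional = optional, ...)
}
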