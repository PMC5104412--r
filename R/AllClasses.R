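#' @import methods
NULL

# Periodic-table subset covered by the engine: organic elements plus common
# counter-elements found in SD files of drug-like sets.
.ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I",
  "Na", "K", "Li", "Mg", "Ca", "Zn", "Fe", "Se"
)

#' Molecule: one connection-table record
#'
#' An S4 container for a single molecule as stored in one V2000 SD record:
#' atoms with Cartesian coordinates (in Angstrom) and formal charges, bonds
#' with integer orders (4 denotes an aromatic bond, as in the MDL
#' convention), and the record's SD data fields held verbatim.
#'
#' @slot name molecule title (line 1 of the record).
#' @slot comment record comment line (line 3); the synthetic generator
#'   records its seed here.
#' @slot atoms `data.frame` with columns `element` (character), `x`, `y`,
#'   `z` (numeric, Angstrom) and `charge` (integer formal charge).
#' @slot bonds `data.frame` with columns `i`, `j` (1-based atom indices)
#'   and `order` (integer in 1,2,3,4).
#' @slot fields named character vector of SD data fields (tag -> value).
#'
#' @examples
#' mol <- fixtureLibrary()[["ethanol"]]
#' atomCount(mol)
#' @export
setClass("Molecule", representation(
  name = "character",
  comment = "character",
  atoms = "data.frame",
  bonds = "data.frame",
  fields = "character"
))

setValidity("Molecule", function(object) {
  msg <- character()
  a <- object@atoms
  b <- object@bonds
  need <- c("element", "x", "y", "z", "charge")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  }
  if (!all(c("i", "j", "order") %in% names(b))) {
    return("bonds must have columns i, j, order")
  }
  bad <- setdiff(unique(a$element), .ELEMENTS)
  if (length(bad)) {
    msg <- c(msg, paste("unknown element symbol(s):", paste(bad, collapse = ", ")))
  }
  if (nrow(b)) {
    if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a))) {
      msg <- c(msg, "bond atom index out of range")
    } else if (any(b$i == b$j)) {
      msg <- c(msg, "bond connecting an atom to itself")
    } else {
      key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate bond between the same atom pair")
    }
    if (any(!b$order %in% 1:4)) msg <- c(msg, "bond order outside {1,2,3,4}")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MoleculeSet: an ordered collection of molecules
#'
#' Wraps the molecules of one multi-record SD file (or one synthetic set),
#' preserving file order, together with the name of the SD field that holds
#' the experimental property (if any) and the number of records that were
#' skipped during parsing.
#'
#' @slot molecules list of [Molecule] objects, in file order.
#' @slot source file path or `"synthetic"`.
#' @slot propertyTag SD field name holding the experimental property, or
#'   `NA_character_` when the set carries no property.
#' @slot nSkipped number of unparseable records skipped while reading.
#'
#' @export
setClass("MoleculeSet", representation(
  molecules = "list",
  source = "character",
  propertyTag = "character",
  nSkipped = "integer"
))

setValidity("MoleculeSet", function(object) {
  if (!all(vapply(object@molecules, is, logical(1), "Molecule"))) {
    return("all elements of 'molecules' must be Molecule objects")
  }
  if (length(object@propertyTag) != 1) return("propertyTag must be length 1")
  TRUE
})

#' DescriptorSpec: a named molecular descriptor
#'
#' Identifies one descriptor by name, the family it belongs to, whether it
#' needs non-degenerate 3-D coordinates, and any parameters (for the
#' `group_count` family the SMARTS pattern to count).
#'
#' @slot name unique descriptor id within a registry.
#' @slot family one of `constitutional`, `hbond`, `topological`, `surface`,
#'   `charge_surface`, `geometric`, `group_count`.
#' @slot requires3D does the descriptor need 3-D coordinates?
#' @slot parameters named list (e.g. `list(smarts = "[OX2H]")`).
#'
#' @export
setClass("DescriptorSpec", representation(
  name = "character",
  family = "character",
  requires3D = "logical",
  parameters = "list"
))

.FAMILIES <- c(
  "constitutional", "hbond", "topological", "surface",
  "charge_surface", "geometric", "group_count"
)

setValidity("DescriptorSpec", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name)) {
    return("name must be a single non-empty string")
  }
  if (!object@family %in% .FAMILIES) {
    return(paste("family must be one of:", paste(.FAMILIES, collapse = ", ")))
  }
  if (object@family %in% c("geometric", "charge_surface") && !isTRUE(object@requires3D)) {
    return("geometric and charge_surface descriptors must have requires3D = TRUE")
  }
  if (object@family == "group_count" && is.null(object@parameters$smarts)) {
    return("group_count descriptors need a 'smarts' parameter")
  }
  TRUE
})

#' DescriptorMatrix: molecules x descriptors design matrix
#'
#' Holds the numeric design matrix together with a logical mask of cells
#' whose descriptor could not be computed (e.g. a 3-D descriptor on a flat
#' molecule). Row names are molecule names, column names descriptor names.
#'
#' @slot values numeric matrix, `NA` only where `missing` is `TRUE`.
#' @slot missing logical matrix of the same shape.
#'
#' @export
setClass("DescriptorMatrix", representation(
  values = "matrix",
  missing = "matrix"
))

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  m <- object@missing
  if (!identical(dim(v), dim(m))) return("values and missing must have identical shape")
  if (is.null(colnames(v))) return("values must carry descriptor column names")
  if (any(is.na(v) & !m)) return("NA present in a cell not flagged missing")
  TRUE
})

#' QSPRModel: a fitted linear property model
#'
#' The result of [fitQSPR()]: algorithm id, the ordered descriptor list, the
#' least-squares intercept and coefficients on the algorithm's working scale,
#' any column centering/scaling parameters, the property projection used by
#' the Klopman variant, training statistics, and the descriptor specs needed
#' to rebuild the design matrix at prediction time.
#'
#' @slot algorithm `"mlr"`, `"centered"`, `"mcuv"` or `"klopman"`.
#' @slot descriptorNames ordered descriptor names.
#' @slot intercept intercept on the working scale.
#' @slot coefficients coefficient vector (length = number of descriptors).
#' @slot columnMeans column means (length 0 for `mlr`).
#' @slot columnScales column standard deviations (length 0 unless
#'   `mcuv`/`klopman`); strictly positive.
#' @slot projection list with `name` and `scale` for `klopman`, else empty.
#' @slot trainStats list: `r2`, `sigma`, `sigmaPlain`, `mue`, `deltaMax`,
#'   `n`, `p`, `nExcluded`, `sigmaDf`.
#' @slot specs list of [DescriptorSpec] matching `descriptorNames`.
#' @slot provenance free-text training-set description.
#'
#' @export
setClass("QSPRModel", representation(
  algorithm = "character",
  descriptorNames = "character",
  intercept = "numeric",
  coefficients = "numeric",
  columnMeans = "numeric",
  columnScales = "numeric",
  projection = "list",
  trainStats = "list",
  specs = "list",
  provenance = "character"
))

.ALGORITHMS <- c("mlr", "centered", "mcuv", "klopman")

setValidity("QSPRModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% .ALGORITHMS) {
    msg <- c(msg, paste("algorithm must be one of:", paste(.ALGORITHMS, collapse = ", ")))
  }
  p <- length(object@descriptorNames)
  if (length(object@coefficients) != p) {
    msg <- c(msg, "coefficients length must equal descriptorNames length")
  }
  if (length(object@columnScales) && any(object@columnScales <= 0)) {
    msg <- c(msg, "columnScales must be strictly positive")
  }
  if (object@algorithm %in% c("mcuv", "klopman")) {
    if (length(object@columnMeans) != p || length(object@columnScales) != p) {
      msg <- c(msg, "mcuv/klopman models must carry column means and scales")
    }
  } else if (object@algorithm == "centered") {
    if (length(object@columnMeans) != p) msg <- c(msg, "centered models must carry column means")
    if (length(object@columnScales)) msg <- c(msg, "centered models must not carry column scales")
  } else {
    if (length(object@columnMeans) || length(object@columnScales)) {
      msg <- c(msg, "mlr models carry neither means nor scales")
    }
  }
  if (object@algorithm == "klopman") {
    if (is.null(object@projection$name) || is.null(object@projection$scale)) {
      msg <- c(msg, "klopman models must carry a projection (name, scale)")
    } else if (object@projection$scale <= 0) {
      msg <- c(msg, "projection scale must be positive")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' PredictionReport: per-molecule predictions plus aggregate statistics
#'
#' @slot moleculeNames names of the evaluated molecules.
#' @slot predicted predicted property values (property units).
#' @slot experimental experimental values (length 0 when the set carries no
#'   property tag).
#' @slot residuals experimental minus predicted (length 0 without
#'   experimental values).
#' @slot stats list with `r2`, `sigma`, `mue`, `deltaMax`, `n` (empty when
#'   no experimental values are available).
#' @slot excluded `data.frame` (`molecule`, `reason`) of molecules dropped
#'   because a model descriptor could not be computed.
#' @slot algorithm algorithm id of the scoring model.
#'
#' @export
setClass("PredictionReport", representation(
  moleculeNames = "character",
  predicted = "numeric",
  experimental = "numeric",
  residuals = "numeric",
  stats = "list",
  excluded = "data.frame",
  algorithm = "character"
))

setValidity("PredictionReport", function(object) {
  if (length(object@experimental) &&
      length(object@experimental) != length(object@predicted)) {
    return("experimental and predicted lengths differ")
  }
  if (length(object@residuals) != length(object@experimental)) {
    return("residuals present iff experimental present, with equal length")
  }
  TRUE
})

#' SyntheticSetConfig: recipe for a synthetic molecule set
#'
#' Describes how [generateSyntheticSet()] builds a seeded SD molecule set
#' whose property field is a known linear function of computed descriptors
#' plus Gaussian noise.
#'
#' @slot nMolecules number of molecules to generate.
#' @slot seed integer PRNG seed; the whole set is reproducible from it.
#' @slot trueCoefficients named numeric vector, descriptor name -> weight.
#' @slot trueIntercept intercept of the generating linear model.
#' @slot noiseSigma standard deviation of the Gaussian noise added to the
#'   property (property units; 0 gives a noiseless set).
#' @slot propertyTag SD field name the property is written to.
#'
#' @export
setClass("SyntheticSetConfig", representation(
  nMolecules = "integer",
  seed = "integer",
  trueCoefficients = "numeric",
  trueIntercept = "numeric",
  noiseSigma = "numeric",
  propertyTag = "character"
))

setValidity("SyntheticSetConfig", function(object) {
  k <- length(object@trueCoefficients)
  if (k == 0 || is.null(names(object@trueCoefficients))) {
    return("trueCoefficients must be a named numeric vector")
  }
  if (object@nMolecules < k + 2) {
    return("nMolecules must be at least length(trueCoefficients) + 2")
  }
  if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
  reg <- names(descriptorRegistry())
  bad <- setdiff(names(object@trueCoefficients), reg)
  if (length(bad)) {
    return(paste("unknown descriptor(s) in trueCoefficients:", paste(bad, collapse = ", ")))
  }
  TRUE
})
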