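#' @include AllClasses.R AllGenerics.R
NULL

#' Stereographic projection of a property
#'
#' Maps the property axis onto a bounded interval before fitting, the
#' transformation used by the Klopman-style solubility algorithm: the model
#' is fitted to the projected property and predictions are mapped back.
#' The projection is the monotone bijection `theta = 2 atan(y / scale)`
#' from the real line onto `(-pi, pi)`, odd in `y` (`theta(0) = 0`);
#' `unprojectProperty()` is its inverse `y = scale tan(theta / 2)`. Inputs
#' to the inverse are clamped to the open interval so that any finite
#' linear-model output maps to a finite property value, monotonically.
#'
#' @param y numeric property values.
#' @param theta projected values.
#' @param scale positive scale constant of the projection (default 1,
#'   property units).
#' @return `projectProperty()`: values in `(-pi, pi)`;
#'   `unprojectProperty()`: property values.
#' @examples
#' y <- seq(-11.6, 1.6, by = 0.4)
#' all.equal(unprojectProperty(projectProperty(y)), y)
#' @export
projectProperty <- function(y, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0) {
    stop("projection scale must be a single positive number")
  }
  2 * atan(y / scale)
}

#' @rdname projectProperty
#' @export
unprojectProperty <- function(theta, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0) {
    stop("projection scale must be a single positive number")
  }
  eps <- 1e-9
  scale * tan(pmin(pmax(theta, -pi + eps), pi - eps) / 2)
}

# Shared fit/evaluation statistics. r2 = 1 - SSres/SStot; sigma is the
# residual standard deviation, df-corrected (sqrt(SSres/(n-p-1))) or plain
# (sqrt(SSres/n)); mue = mean |residual|; deltaMax = the signed residual
# (experimental - predicted) of largest magnitude, first occurrence on
# ties.
.fitStatistics <- function(y, yhat, p, sigmaDf = c("corrected", "plain")) {
  sigmaDf <- match.arg(sigmaDf)
  n <- length(y)
  res <- y - yhat
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) stop("experimental values are constant; r-squared is undefined")
  ssRes <- sum(res^2)
  sigma <- if (sigmaDf == "corrected") {
    if (n <= p + 1) stop("need n > p + 1 observations for the df-corrected sigma")
    sqrt(ssRes / (n - p - 1))
  } else {
    sqrt(ssRes / n)
  }
  list(
    r2 = 1 - ssRes / ssTot,
    sigma = sigma,
    sigmaPlain = sqrt(ssRes / n),
    mue = mean(abs(res)),
    deltaMax = if (n) unname(res[which.max(abs(res))]) else NA_real_,
    n = n, p = p, sigmaDf = sigmaDf
  )
}

.asDesign <- function(x) {
  if (is(x, "DescriptorMatrix")) {
    list(values = x@values, missing = x@missing)
  } else if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("d", seq_len(ncol(x)))
    list(values = x, missing = is.na(x))
  } else {
    stop("x must be a DescriptorMatrix or a numeric matrix")
  }
}

#' Fit a linear QSPR model
#'
#' Fits the property-descriptor relationship `P = c0 + sum(ci di)` by
#' ordinary least squares under one of four algorithms:
#'
#' * `"mlr"` — plain multivariate linear regression on the raw descriptors;
#' * `"centered"` — descriptors are mean-centered first (an affine
#'   reparameterisation: fitted values are identical to `"mlr"`);
#' * `"mcuv"` — mean-centered unit-variance autoscaling (z-scoring), again
#'   prediction-equivalent to `"mlr"`;
#' * `"klopman"` — the property itself is replaced by its stereographic
#'   projection ([projectProperty()]) and fitted with MCUV scaling;
#'   predictions are mapped back to property units.
#'
#' Rows whose property is missing (`NA`) are excluded and counted. Missing
#' descriptor cells among the rows actually used, a rank-deficient design
#' (named dependent columns), a zero-variance column under `"mcuv"`, or
#' fewer than `p + 2` usable rows are hard errors. The solver is a QR
#' decomposition with an explicit rank check — no silent pseudoinverse.
#'
#' Training statistics (`r2`, `sigma`, `mue`, `deltaMax`) are computed on
#' the property scale (un-projected for `"klopman"`), with
#' `sigma = sqrt(SSres / (n - p - 1))` by default (`sigmaDf = "plain"`
#' gives `sqrt(SSres / n)`).
#'
#' @param x a [DescriptorMatrix] (or plain numeric matrix with column
#'   names).
#' @param y numeric property vector, one value per row of `x`; `NA` marks
#'   a missing property.
#' @param algorithm one of `"mlr"`, `"centered"`, `"mcuv"`, `"klopman"`.
#' @param projectionScale positive scale of the stereographic projection
#'   (`"klopman"` only).
#' @param sigmaDf `"corrected"` (degrees-of-freedom corrected, default) or
#'   `"plain"`.
#' @param specs optional list of [DescriptorSpec] matching the columns of
#'   `x`; stored in the model so that prediction can rebuild descriptors
#'   from molecules. Filled automatically by [trainQSPR()].
#' @param provenance free-text note on the training set.
#' @return a [QSPRModel].
#' @seealso [trainQSPR()], [predict][predict,QSPRModel-method],
#'   [rawCoefficients()], [saveModel()]
#' @examples
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 1 + 2 * X[, 1] - X[, 3]
#' m <- fitQSPR(X, y, algorithm = "mcuv")
#' rawCoefficients(m)
#' @export
fitQSPR <- function(x, y, algorithm = c("mlr", "centered", "mcuv", "klopman"),
                    projectionScale = 1, sigmaDf = c("corrected", "plain"),
                    specs = list(), provenance = "") {
  algorithm <- match.arg(algorithm)
  sigmaDf <- match.arg(sigmaDf)
  d <- .asDesign(x)
  X <- d$values
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(x)")

  use <- !is.na(y)
  nExcluded <- sum(!use)
  if (nExcluded > 0) {
    message(nExcluded, " row(s) excluded from fitting: missing property value")
  }
  X <- X[use, , drop = FALSE]
  y <- y[use]
  if (any(d$missing[use, , drop = FALSE])) {
    bad <- colnames(X)[colSums(d$missing[use, , drop = FALSE]) > 0]
    stop("missing descriptor cells among training rows (",
         paste(bad, collapse = ", "), "); drop those molecules or descriptors first")
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need more than p + 1 = ", p + 1, " usable molecules, got ", n)

  yWork <- if (algorithm == "klopman") projectProperty(y, projectionScale) else y

  means <- numeric(0); scales <- numeric(0)
  Xw <- X
  if (algorithm %in% c("centered", "mcuv", "klopman")) {
    means <- colMeans(X)
    Xw <- sweep(Xw, 2, means)
  }
  if (algorithm %in% c("mcuv", "klopman")) {
    scales <- apply(X, 2, stats::sd)
    zero <- scales == 0
    if (any(zero)) {
      stop("zero-variance descriptor column(s): ",
           paste(colnames(X)[zero], collapse = ", "))
    }
    Xw <- sweep(Xw, 2, scales, "/")
  }

  Z <- cbind(`(intercept)` = 1, Xw)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dep <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("rank-deficient design matrix; linearly dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qz, yWork)
  fittedWork <- drop(Z %*% beta)
  fitted <- if (algorithm == "klopman") {
    unprojectProperty(fittedWork, projectionScale)
  } else {
    fittedWork
  }
  stats <- .fitStatistics(y, fitted, p, sigmaDf)
  stats$nExcluded <- nExcluded
  if (algorithm == "klopman") {
    stats$r2Projected <- 1 - sum((yWork - fittedWork)^2) / sum((yWork - mean(yWork))^2)
  }

  mdl <- new("QSPRModel",
    algorithm = algorithm,
    descriptorNames = colnames(X),
    intercept = unname(beta[1]),
    coefficients = unname(beta[-1]),
    columnMeans = unname(means),
    columnScales = unname(scales),
    projection = if (algorithm == "klopman") {
      list(name = "stereographic", scale = projectionScale)
    } else {
      list()
    },
    trainStats = stats,
    specs = specs,
    provenance = if (nzchar(provenance)) provenance else "unspecified training set"
  )
  validObject(mdl)
  mdl
}

#' Train a QSPR model straight from a molecule set
#'
#' Convenience wrapper: builds the descriptor matrix for `specs`, reads the
#' experimental property from the set's property tag, and calls
#' [fitQSPR()]. The descriptor specs are embedded in the returned model so
#' it can later predict directly on molecule sets.
#'
#' @param set a [MoleculeSet] whose property tag is set.
#' @param specs list of [DescriptorSpec] (default: full registry).
#' @inheritParams fitQSPR
#' @return a [QSPRModel].
#' @export
trainQSPR <- function(set, specs = descriptorRegistry(),
                      algorithm = c("mlr", "centered", "mcuv", "klopman"),
                      projectionScale = 1, sigmaDf = c("corrected", "plain")) {
  stopifnot(is(set, "MoleculeSet"))
  if (is.na(propertyTag(set))) {
    stop("molecule set has no property tag; set propertyTag(set) first")
  }
  X <- buildDescriptorMatrix(set, specs)
  y <- propertyValues(set)
  fitQSPR(X, y, algorithm = algorithm, projectionScale = projectionScale,
          sigmaDf = sigmaDf, specs = specs,
          provenance = paste0("trained on ", set@source, " (", length(set),
                              " molecules, tag ", propertyTag(set), ")"))
}

#' Coefficients on the raw descriptor scale
#'
#' Undoes the centering/scaling reparameterisation and returns the
#' intercept and slopes that apply directly to unscaled descriptor values.
#' For `"mlr"` this is the stored solution; for `"klopman"` the returned
#' coefficients act on the *projected* property scale.
#'
#' @param model a [QSPRModel].
#' @return list with `intercept` and named `coefficients`.
#' @export
rawCoefficients <- function(model) {
  stopifnot(is(model, "QSPRModel"))
  beta <- model@coefficients
  b0 <- model@intercept
  if (length(model@columnScales)) beta <- beta / model@columnScales
  if (length(model@columnMeans)) b0 <- b0 - sum(beta * model@columnMeans)
  list(intercept = b0, coefficients = stats::setNames(beta, model@descriptorNames))
}

#' Predict property values from a fitted model
#'
#' Applies the stored centering/scaling, evaluates the linear model, and —
#' for `"klopman"` models — maps the result back from the projected scale
#' to property units. `newdata` may be a [DescriptorMatrix], a plain
#' numeric matrix (columns matched by name), or a [MoleculeSet] (the
#' model's embedded descriptor specs are recomputed on it; molecules with
#' uncomputable descriptors yield `NA`).
#'
#' @param object a [QSPRModel].
#' @param newdata descriptor matrix or molecule set.
#' @param ... ignored.
#' @return named numeric vector of predictions in property units.
#' @export
setMethod("predict", "QSPRModel", function(object, newdata, ...) {
  if (is(newdata, "MoleculeSet")) {
    if (!length(object@specs)) {
      stop("model carries no descriptor specs; predict on a DescriptorMatrix instead")
    }
    newdata <- buildDescriptorMatrix(newdata, object@specs)
  }
  d <- .asDesign(newdata)
  X <- d$values
  missing <- setdiff(object@descriptorNames, colnames(X))
  if (length(missing)) {
    stop("newdata lacks descriptor column(s): ", paste(missing, collapse = ", "))
  }
  X <- X[, object@descriptorNames, drop = FALSE]
  if (length(object@columnMeans)) X <- sweep(X, 2, object@columnMeans)
  if (length(object@columnScales)) X <- sweep(X, 2, object@columnScales, "/")
  out <- drop(X %*% object@coefficients) + object@intercept
  if (object@algorithm == "klopman") {
    out <- unprojectProperty(out, object@projection$scale)
  }
  if (!is.null(rownames(d$values))) names(out) <- rownames(d$values)
  out
})

#' @rdname model-accessors
#' @export
setMethod("descriptorNames", "QSPRModel", function(x) x@descriptorNames)

#' @rdname model-accessors
#' @export
setMethod("algorithm", "QSPRModel", function(x) x@algorithm)

#' @rdname model-accessors
#' @export
setMethod("trainStats", "QSPRModel", function(x) x@trainStats)

#' @describeIn QSPRModel stored (working-scale) coefficients, intercept
#'   first — use [rawCoefficients()] for the unscaled parameterisation.
#' @param object a `QSPRModel`.
#' @param ... ignored.
#' @export
setMethod("coef", "QSPRModel", function(object, ...) {
  c(`(intercept)` = object@intercept,
    stats::setNames(object@coefficients, object@descriptorNames))
})

setMethod("show", "QSPRModel", function(object) {
  s <- object@trainStats
  cat(sprintf("QSPRModel (%s): %d descriptor(s)\n", object@algorithm,
              length(object@descriptorNames)))
  cat("  ", paste(object@descriptorNames, collapse = ", "), "\n", sep = "")
  if (length(object@projection)) {
    cat(sprintf("  projection: %s (scale %.3g)\n",
                object@projection$name, object@projection$scale))
  }
  cat(sprintf("  training: n = %d, r2 = %.4f, sigma = %.4f (%s df)\n",
              s$n, s$r2, s$sigma, s$sigmaDf))
})
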