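#' @include AllClasses.R AllGenerics.R regression.R
NULL

#' Score predictions against experimental values
#'
#' Computes the four statistics used to judge a property model:
#' `r2 = 1 - sum((e - p)^2) / sum((e - mean(e))^2)` (which can be negative
#' off the training set), the residual standard deviation `sigma`
#' (df-corrected by default, with `p` taken from the scoring model), the
#' mean unsigned error `MUE = mean(|e - p|)`, and `deltaMax`, the *signed*
#' residual of largest magnitude. The residual convention is configurable
#' and defaults to experimental minus predicted; ties in `|residual|` are
#' broken by first occurrence, so results are deterministic given file
#' order.
#'
#' @param predicted numeric vector of predictions.
#' @param experimental numeric vector of experimental values (same length,
#'   at least 2, no missing values, not constant).
#' @param p number of model descriptors (for the sigma df correction).
#' @param sigmaDf `"corrected"` (`sqrt(SSres/(n-p-1))`) or `"plain"`
#'   (`sqrt(SSres/n)`).
#' @param deltaSign `"exp-minus-pred"` (default) or `"pred-minus-exp"`.
#' @return list with `r2`, `sigma`, `mue`, `deltaMax`, `n`.
#' @examples
#' evaluatePredictions(c(1, 2, 6), c(1, 2, 3))
#' @export
evaluatePredictions <- function(predicted, experimental, p = 0,
                                sigmaDf = c("corrected", "plain"),
                                deltaSign = c("exp-minus-pred", "pred-minus-exp")) {
  sigmaDf <- match.arg(sigmaDf)
  deltaSign <- match.arg(deltaSign)
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental must have equal length")
  }
  if (length(predicted) < 2) stop("need at least 2 value pairs")
  if (anyNA(predicted) || anyNA(experimental)) stop("missing values are not allowed")
  s <- .fitStatistics(experimental, predicted, p, sigmaDf)
  if (deltaSign == "pred-minus-exp") s$deltaMax <- -s$deltaMax
  s[c("r2", "sigma", "mue", "deltaMax", "n")]
}

#' Predict and score a molecule set with a fitted model
#'
#' Rebuilds the model's descriptors on the set, predicts the property for
#' every molecule on which all descriptors are computable, and — when the
#' set carries an experimental property tag — attaches residuals and the
#' aggregate statistics of [evaluatePredictions()]. Molecules with an
#' uncomputable descriptor are excluded from predictions and statistics,
#' each logged with its reason; molecules with a missing experimental
#' value keep their prediction but are left out of the statistics.
#'
#' @param set a [MoleculeSet].
#' @param model a [QSPRModel] with embedded descriptor specs.
#' @param sigmaDf,deltaSign conventions passed to [evaluatePredictions()];
#'   `sigmaDf` defaults to the convention the model was trained with.
#' @return a [PredictionReport].
#' @seealso [writeReport()]
#' @export
predictionReport <- function(set, model,
                             sigmaDf = NULL,
                             deltaSign = c("exp-minus-pred", "pred-minus-exp")) {
  stopifnot(is(set, "MoleculeSet"), is(model, "QSPRModel"))
  deltaSign <- match.arg(deltaSign)
  if (is.null(sigmaDf)) sigmaDf <- model@trainStats$sigmaDf
  if (!length(model@specs)) stop("model carries no descriptor specs")

  X <- buildDescriptorMatrix(set, model@specs)
  nms <- moleculeNames(set)
  bad <- rowSums(X@missing) > 0
  excluded <- data.frame(molecule = character(0), reason = character(0))
  if (any(bad)) {
    reason <- apply(X@missing[bad, , drop = FALSE], 1, function(r) {
      paste("uncomputable:", paste(colnames(X@missing)[r], collapse = ", "))
    })
    excluded <- data.frame(molecule = nms[bad], reason = unname(reason))
    for (k in seq_len(nrow(excluded))) {
      message("excluding '", excluded$molecule[k], "': ", excluded$reason[k])
    }
  }
  if (all(bad)) stop("no molecule in the set is evaluable with this model")

  keep <- which(!bad)
  Xok <- new("DescriptorMatrix",
             values = X@values[keep, , drop = FALSE],
             missing = X@missing[keep, , drop = FALSE])
  pred <- predict(model, Xok)

  experimental <- numeric(0)
  residuals <- numeric(0)
  stats <- list()
  if (!is.na(propertyTag(set))) {
    expAll <- propertyValues(set)
    experimental <- unname(expAll[keep])
    residuals <- experimental - pred
    ok <- !is.na(experimental)
    if (sum(ok) >= 2) {
      stats <- evaluatePredictions(pred[ok], experimental[ok],
                                   p = length(model@descriptorNames),
                                   sigmaDf = sigmaDf, deltaSign = deltaSign)
    }
  }
  new("PredictionReport",
      moleculeNames = nms[keep], predicted = unname(pred),
      experimental = experimental,
      residuals = if (length(experimental)) unname(residuals) else numeric(0),
      stats = stats, excluded = excluded, algorithm = model@algorithm)
}

#' @describeIn PredictionReport per-molecule table with columns
#'   `molecule`, `predicted` and, when available, `experimental` and
#'   `residual`.
#' @param x a `PredictionReport`.
#' @param row.names,optional,... per the generic signature.
#' @export
as.data.frame.PredictionReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(molecule = x@moleculeNames, predicted = x@predicted)
  if (length(x@experimental)) {
    df$experimental <- x@experimental
    df$residual <- x@residuals
  }
  df
}

#' Write a prediction report to disk
#'
#' CSV output holds one row per molecule plus footer rows for `r2`,
#' `sigma`, `mue` and `delta_max` when statistics are available; JSON
#' output is a machine-readable document with `predictions`, `stats` and
#' `excluded` members.
#'
#' @param report a [PredictionReport].
#' @param path output path.
#' @param format `"csv"` or `"json"` (default: inferred from the file
#'   extension, falling back to CSV).
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = NULL) {
  stopifnot(is(report, "PredictionReport"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  df <- as.data.frame(report)
  if (format == "csv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = ","), con, sep = "\n")
    body <- apply(df, 1, function(r) paste(trimws(r), collapse = ","))
    writeLines(body, con, sep = "\n")
    if (length(report@stats)) {
      s <- report@stats
      pad <- function(lab, val) {
        paste(c(lab, format(val, digits = 10), rep("", ncol(df) - 2)), collapse = ",")
      }
      writeLines(c(pad("r2", s$r2), pad("sigma", s$sigma),
                   pad("mue", s$mue), pad("delta_max", s$deltaMax)), con, sep = "\n")
    }
  } else {
    doc <- list(predictions = df, stats = report@stats, excluded = report@excluded,
                algorithm = report@algorithm)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

setMethod("show", "PredictionReport", function(object) {
  cat(sprintf("PredictionReport (%s model): %d molecule(s) predicted, %d excluded\n",
              object@algorithm, length(object@predicted), nrow(object@excluded)))
  if (length(object@stats)) {
    s <- object@stats
    cat(sprintf("  r2 = %.4f, sigma = %.4f, MUE = %.4f, delta_max = %+.4f (n = %d)\n",
                s$r2, s$sigma, s$mue, s$deltaMax, s$n))
  } else {
    cat("  no experimental values: statistics absent\n")
  }
})
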