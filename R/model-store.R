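#' @include AllClasses.R regression.R
NULL

.MODEL_FORMAT_VERSION <- 1L

.specToList <- function(s) {
  list(name = s@name, family = s@family, requires3D = s@requires3D,
       parameters = s@parameters)
}

.specFromList <- function(l) {
  for (f in c("name", "family", "requires3D")) {
    if (is.null(l[[f]])) stop("corrupt model file: descriptor spec missing '", f, "'")
  }
  new("DescriptorSpec", name = l$name, family = l$family,
      requires3D = as.logical(l$requires3D),
      parameters = if (is.null(l$parameters)) list() else as.list(l$parameters))
}

#' Persist a fitted model as self-contained JSON
#'
#' Writes the model — algorithm, descriptor names and specs (including any
#' SMARTS parameters), intercept, coefficients, centering/scaling
#' parameters, projection, training statistics and provenance — as a JSON
#' document. Reals are serialised at full precision (17 significant
#' digits), so a reloaded model reproduces predictions bit-for-bit;
#' formatting is locale-independent.
#'
#' @param model a fitted [QSPRModel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "QSPRModel"))
  validObject(model)
  doc <- list(
    format_version = .MODEL_FORMAT_VERSION,
    generator = "qsprlm",
    algorithm = model@algorithm,
    descriptor_names = as.list(model@descriptorNames),
    intercept = model@intercept,
    coefficients = as.list(model@coefficients),
    column_means = as.list(model@columnMeans),
    column_scales = as.list(model@columnScales),
    projection = model@projection,
    train_stats = model@trainStats,
    specs = lapply(model@specs, .specToList),
    provenance = model@provenance
  )
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    TRUE
  }, error = function(e) {
    stop("cannot write model file '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Load a persisted model
#'
#' Reads a JSON model file written by [saveModel()], rejecting unknown
#' format versions outright and validating the reconstructed model
#' (coefficient/name length agreement, positive scales, projection
#' presence) before returning — a corrupt file never yields a partially
#' loaded model.
#'
#' @param path model file path.
#' @return a [QSPRModel].
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
    stop("schema error: '", path, "' is not a valid model file (",
         conditionMessage(e), ")")
  })
  if (is.null(doc$format_version)) stop("schema error: missing format_version")
  if (!identical(as.integer(doc$format_version), .MODEL_FORMAT_VERSION)) {
    stop("unknown model format version ", doc$format_version,
         " (this build reads version ", .MODEL_FORMAT_VERSION, ")")
  }
  required <- c("algorithm", "descriptor_names", "intercept", "coefficients",
                "train_stats")
  for (f in required) {
    if (is.null(doc[[f]])) stop("schema error: missing required field '", f, "'")
  }
  toNum <- function(x) as.numeric(unlist(x, use.names = FALSE))
  mdl <- tryCatch({
    m <- new("QSPRModel",
      algorithm = doc$algorithm,
      descriptorNames = as.character(unlist(doc$descriptor_names)),
      intercept = as.numeric(doc$intercept),
      coefficients = toNum(doc$coefficients),
      columnMeans = toNum(doc$column_means),
      columnScales = toNum(doc$column_scales),
      projection = if (length(doc$projection)) doc$projection else list(),
      trainStats = doc$train_stats,
      specs = lapply(doc$specs, .specFromList),
      provenance = as.character(doc$provenance)
    )
    validObject(m)
    m
  }, error = function(e) {
    stop("corrupt model file '", path, "': ", conditionMessage(e))
  })
  mdl
}
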