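#' @include AllClasses.R
NULL

#' Accessors for molecule and molecule-set objects
#'
#' `molecules()` returns the list of [Molecule] objects; `moleculeNames()`
#' the molecule titles; `propertyTag()` the SD field holding the
#' experimental property (`NA` if unset); `propertyValues()` the parsed
#' numeric property vector (`NA` where the field is absent or not a number);
#' `atomCount()`/`bondCount()` the sizes of a molecule's connection table;
#' `sdFields()` the raw SD data fields; `nSkipped()` the number of records
#' skipped while reading the file.
#'
#' @param x a [Molecule] or [MoleculeSet].
#' @param value replacement value.
#' @return See individual descriptions.
#' @name accessors
#' @examples
#' set <- fixtureLibrary()
#' length(set)
#' moleculeNames(set)[1:3]
NULL

#' @rdname accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname accessors
#' @export
setGeneric("moleculeNames", function(x) standardGeneric("moleculeNames"))

#' @rdname accessors
#' @export
setGeneric("propertyTag", function(x) standardGeneric("propertyTag"))

#' @rdname accessors
#' @export
setGeneric("propertyTag<-", function(x, value) standardGeneric("propertyTag<-"))

#' @rdname accessors
#' @export
setGeneric("propertyValues", function(x) standardGeneric("propertyValues"))

#' @rdname accessors
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname accessors
#' @export
setGeneric("bondCount", function(x) standardGeneric("bondCount"))

#' @rdname accessors
#' @export
setGeneric("sdFields", function(x) standardGeneric("sdFields"))

#' @rdname accessors
#' @export
setGeneric("nSkipped", function(x) standardGeneric("nSkipped"))

#' Accessors for descriptor matrices and fitted models
#'
#' `descriptorNames()` returns the ordered descriptor names of a
#' [DescriptorMatrix] or [QSPRModel]; `descriptorValues()` the numeric
#' matrix; `missingMask()` the logical mask of uncomputable cells;
#' `algorithm()` the fitting algorithm id; `trainStats()` the training
#' statistics list.
#'
#' @param x a [DescriptorMatrix] or [QSPRModel].
#' @return See individual descriptions.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @rdname model-accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' @rdname model-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname model-accessors
#' @export
setGeneric("algorithm", function(x) standardGeneric("algorithm"))

#' @rdname model-accessors
#' @export
setGeneric("trainStats", function(x) standardGeneric("trainStats"))
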