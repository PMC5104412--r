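#' @include AllClasses.R AllGenerics.R
NULL

# ---- V2000 record parsing ----------------------------------------------

# Legacy atom-block charge codes (column 37-39), superseded by M CHG.
.LEGACY_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

.fw_int <- function(line, from, to) {
  s <- trimws(substr(line, from, to))
  if (!nzchar(s)) return(NA_integer_)
  suppressWarnings(as.integer(s))
}

.fw_num <- function(line, from, to) {
  s <- trimws(substr(line, from, to))
  if (!nzchar(s)) return(NA_real_)
  suppressWarnings(as.numeric(s))
}

# Parse the lines of one SD record (without the $$$$ terminator) into a
# Molecule. Signals condition class "sdfV3000" for V3000 records and
# ordinary errors for anything malformed; callers decide skip policy.
.parseRecord <- function(lines) {
  if (length(lines) < 4) stop("record shorter than a V2000 header")
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    stop(structure(
      class = c("sdfV3000", "error", "condition"),
      list(message = "V3000 record", call = NULL)
    ))
  }
  na <- .fw_int(counts, 1, 3)
  nb <- .fw_int(counts, 4, 6)
  if (is.na(na) || is.na(nb) || na < 1 || nb < 0) stop("unparseable counts line")
  if (length(lines) < 4 + na + nb) stop("connection table truncated")

  atomLines <- lines[5:(4 + na)]
  el <- trimws(substr(atomLines, 32, 34))
  x <- vapply(atomLines, .fw_num, numeric(1), 1, 10)
  y <- vapply(atomLines, .fw_num, numeric(1), 11, 20)
  z <- vapply(atomLines, .fw_num, numeric(1), 21, 30)
  if (anyNA(c(x, y, z)) || any(!nzchar(el))) stop("malformed atom block")
  ccode <- vapply(atomLines, .fw_int, integer(1), 37, 39)
  charge <- ifelse(is.na(ccode), 0L, unname(.LEGACY_CHARGE[as.character(ccode)]))
  charge[is.na(charge)] <- 0L

  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (nb > 0) {
    bondLines <- lines[(5 + na):(4 + na + nb)]
    bi <- vapply(bondLines, .fw_int, integer(1), 1, 3)
    bj <- vapply(bondLines, .fw_int, integer(1), 4, 6)
    bo <- vapply(bondLines, .fw_int, integer(1), 7, 9)
    if (anyNA(c(bi, bj, bo))) stop("malformed bond block")
    bonds <- data.frame(i = bi, j = bj, order = bo, row.names = NULL)
  }

  # properties block up to M END; M CHG resets all legacy charges
  rest <- lines[-seq_len(4 + na + nb)]
  endAt <- which(grepl("^M  END", rest))
  props <- if (length(endAt)) rest[seq_len(endAt[1] - 1)] else character(0)
  chgLines <- props[grepl("^M  CHG", props)]
  if (length(chgLines)) {
    charge[] <- 0L
    for (cl in chgLines) {
      nn <- .fw_int(cl, 7, 9)
      if (is.na(nn) || nn < 1) stop("malformed M CHG line")
      for (k in seq_len(nn)) {
        at <- .fw_int(cl, 10 + (k - 1) * 8, 13 + (k - 1) * 8)
        cv <- .fw_int(cl, 14 + (k - 1) * 8, 17 + (k - 1) * 8)
        if (is.na(at) || is.na(cv) || at < 1 || at > na) stop("malformed M CHG entry")
        charge[at] <- cv
      }
    }
  }

  fields <- character(0)
  if (length(endAt)) {
    dataLines <- rest[-seq_len(endAt[1])]
    tagAt <- which(grepl("^>", dataLines))
    for (t in tagAt) {
      tag <- sub("^>.*<([^>]+)>.*$", "\\1", dataLines[t])
      if (identical(tag, dataLines[t])) next  # no <TAG> on the line
      vals <- character(0)
      k <- t + 1
      while (k <= length(dataLines) && nzchar(trimws(dataLines[k])) &&
             !grepl("^>", dataLines[k])) {
        vals <- c(vals, dataLines[k])
        k <- k + 1
      }
      fields[tag] <- paste(vals, collapse = "\n")
    }
  }

  mol <- new("Molecule",
    name = trimws(lines[1]), comment = lines[3],
    atoms = data.frame(element = el, x = unname(x), y = unname(y), z = unname(z),
                       charge = charge, row.names = NULL),
    bonds = bonds, fields = fields
  )
  validObject(mol)
  mol
}

#' Read a multi-record SD (SDF) file
#'
#' Parses a V2000 multi-record MDL SD file into a [MoleculeSet]. Records
#' are split at `$$$$` terminators; SD data fields are captured verbatim;
#' formal charges are taken from `M  CHG` lines (which supersede the legacy
#' atom-block charge column). Records that fail to parse, including V3000
#' records, are skipped with a warning and counted in `nSkipped()` — never
#' silently dropped.
#'
#' @param path path to an SD file with at least one valid record.
#' @param propertyTag optional name of the SD field holding the
#'   experimental property. Molecules lacking the field, or whose field
#'   does not parse as a number, are flagged (a warning is emitted and
#'   [propertyValues()] returns `NA` for them).
#' @return a [MoleculeSet], in file order.
#' @seealso [writeSDF()], [propertyValues()]
#' @examples
#' f <- tempfile(fileext = ".sdf")
#' writeSDF(fixtureLibrary(), f)
#' set <- readSDF(f)
#' length(set)
#' @export
readSDF <- function(path, propertyTag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) stop("no parseable V2000 records in ", path)
  recEnds <- grep("^\\${4}", lines)
  if (!length(recEnds)) {
    # tolerate a single-record .mol file without terminator
    recEnds <- length(lines)
  }
  starts <- c(1L, head(recEnds, -1) + 1L)
  mols <- list()
  nSkipped <- 0L
  nV3000 <- 0L
  for (r in seq_along(recEnds)) {
    rec <- lines[starts[r]:recEnds[r]]
    rec <- rec[!grepl("^\\${4}", rec)]
    if (!any(nzchar(trimws(rec)))) next  # trailing blank block
    mol <- tryCatch(.parseRecord(rec), sdfV3000 = function(e) {
      nV3000 <<- nV3000 + 1L
      NULL
    }, error = function(e) {
      nSkipped <<- nSkipped + 1L
      message("skipping record ", r, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(mol)) {
      if (!nzchar(mol@name)) mol@name <- sprintf("MOL%04d", r)
      mols[[length(mols) + 1L]] <- mol
    }
  }
  if (nV3000 > 0) {
    nSkipped <- nSkipped + nV3000
    warning(nV3000, " V3000 record(s) skipped (only V2000 is supported)")
  } else if (nSkipped > 0) {
    warning(nSkipped, " unparseable record(s) skipped")
  }
  if (!length(mols)) stop("no parseable V2000 records in ", path)
  set <- new("MoleculeSet",
    molecules = mols, source = path,
    propertyTag = if (is.null(propertyTag)) NA_character_ else propertyTag,
    nSkipped = nSkipped
  )
  if (!is.null(propertyTag)) {
    bad <- is.na(propertyValues(set))
    if (any(bad)) {
      warning(sum(bad), " molecule(s) missing a numeric '", propertyTag,
              "' field: ", paste(moleculeNames(set)[bad], collapse = ", "))
    }
  }
  set
}

# ---- V2000 writing ------------------------------------------------------

.formatV2000 <- function(mol) {
  a <- mol@atoms
  b <- mol@bonds
  out <- c(
    mol@name,
    "  qsprlm",
    if (length(mol@comment) && nzchar(mol@comment)) mol@comment else "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element)
  )
  if (nrow(b)) out <- c(out, sprintf("%3d%3d%3d  0", b$i, b$j, b$order))
  charged <- which(a$charge != 0L)
  # M CHG lines hold at most 8 atom/charge pairs each
  while (length(charged)) {
    take <- charged[seq_len(min(8, length(charged)))]
    charged <- charged[-seq_len(min(8, length(charged)))]
    out <- c(out, paste0(
      sprintf("M  CHG%3d", length(take)),
      paste0(sprintf("%4d%4d", take, a$charge[take]), collapse = "")
    ))
  }
  out <- c(out, "M  END")
  for (tag in names(mol@fields)) {
    out <- c(out, paste0("> <", tag, ">"),
             strsplit(mol@fields[[tag]], "\n", fixed = TRUE)[[1]], "")
  }
  c(out, "$$$$")
}

#' Write a molecule set as a multi-record SD (SDF) file
#'
#' Emits V2000 connection tables with `M  CHG` lines for formal charges and
#' one `> <TAG>` block per SD data field, records separated by `$$$$`.
#' Output is deterministic: writing the same set twice yields byte-identical
#' files.
#'
#' @param set a non-empty [MoleculeSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSDF()]
#' @export
writeSDF <- function(set, path) {
  stopifnot(is(set, "MoleculeSet"))
  if (!length(set@molecules)) stop("refusing to write an empty MoleculeSet")
  lines <- unlist(lapply(set@molecules, .formatV2000), use.names = FALSE)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  # fixed LF endings for cross-platform byte identity
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# Full SDF text of a set (used by the Open Babel bridge).
.sdfText <- function(mols) {
  paste0(paste(unlist(lapply(mols, .formatV2000), use.names = FALSE),
               collapse = "\n"), "\n")
}

# ---- accessors & methods -----------------------------------------------

#' @rdname accessors
#' @export
setMethod("molecules", "MoleculeSet", function(x) x@molecules)

#' @rdname accessors
#' @export
setMethod("moleculeNames", "MoleculeSet", function(x) {
  vapply(x@molecules, function(m) m@name, character(1))
})

#' @rdname accessors
#' @export
setMethod("propertyTag", "MoleculeSet", function(x) x@propertyTag)

#' @rdname accessors
#' @export
setReplaceMethod("propertyTag", "MoleculeSet", function(x, value) {
  x@propertyTag <- as.character(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("propertyValues", "MoleculeSet", function(x) {
  tag <- x@propertyTag
  if (is.na(tag)) stop("molecule set has no property tag")
  vals <- vapply(x@molecules, function(m) {
    v <- m@fields[tag]
    if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(trimws(v)))
  }, numeric(1))
  names(vals) <- moleculeNames(x)
  vals
})

#' @rdname accessors
#' @export
setMethod("atomCount", "Molecule", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("bondCount", "Molecule", function(x) nrow(x@bonds))

#' @rdname accessors
#' @export
setMethod("sdFields", "Molecule", function(x) x@fields)

#' @rdname accessors
#' @export
setMethod("nSkipped", "MoleculeSet", function(x) x@nSkipped)

#' @describeIn MoleculeSet number of molecules.
#' @param x a `MoleculeSet`.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@molecules))

#' @describeIn MoleculeSet extract one [Molecule] by index or name.
#' @param i index or molecule name.
#' @export
setMethod("[[", "MoleculeSet", function(x, i) {
  if (is.character(i)) i <- match(i, moleculeNames(x))
  x@molecules[[i]]
})

#' @describeIn MoleculeSet subset to a smaller `MoleculeSet`.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, moleculeNames(x))
  initialize(x, molecules = x@molecules[i])
})

setMethod("show", "Molecule", function(object) {
  nh <- sum(object@atoms$element != "H")
  cat(sprintf("Molecule '%s': %d atoms (%d heavy), %d bonds, %d SD field(s)\n",
              object@name, nrow(object@atoms), nh, nrow(object@bonds),
              length(object@fields)))
})

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet of %d molecule(s) from %s\n",
              length(object@molecules), object@source))
  if (!is.na(object@propertyTag)) {
    cat("  property tag: ", object@propertyTag, "\n", sep = "")
  }
  if (object@nSkipped > 0) cat("  records skipped on read:", object@nSkipped, "\n")
})
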