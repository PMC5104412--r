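# Bridge to Open Babel via ChemmineOB. Molecules cross as V2000 text from
# our own writer, so formal charges (M CHG) survive. Open Babel requires
# the SDF stream to end with a newline to count its input objects;
# .sdfText() guarantees that.

.obMols <- function(mols) {
  if (is(mols, "MoleculeSet")) mols <- mols@molecules
  if (is(mols, "Molecule")) mols <- list(mols)
  refs <- ChemmineOB::forEachMol("SDF", .sdfText(mols), identity)
  if (length(refs) != length(mols)) {
    stop("Open Babel read ", length(refs), " of ", length(mols), " molecules")
  }
  refs
}

# SMARTS match count per molecule (unique matches, the group-count
# convention: each distinct atom tuple counted once).
.obSmartsCount <- function(obmols, smarts) {
  counts <- tryCatch(
    ChemmineOB::smartsSearch_OB(obmols, smarts, uniqueMatches = TRUE),
    error = function(e) stop("invalid SMARTS pattern '", smarts, "': ",
                             conditionMessage(e))
  )
  as.numeric(counts)
}

# Open Babel descriptor table (logP = Wildman-Crippen atomic contribution,
# TPSA = Ertl fragment contribution) for a list of OBMol refs.
.obProps <- function(obmols) {
  ChemmineOB::prop_OB(obmols)
}
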