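# Shared fixtures and small utilities for the suite.

fx <- fixtureLibrary()

# rigid-body transform: rotate about an arbitrary axis, then translate
rigidTransform <- function(mol, axis = c(0.3, 0.5, 0.8), angle = 1.1,
                           shift = c(3.2, -1.4, 0.7)) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(mol@atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  mol@atoms$x <- xyz[, 1]
  mol@atoms$y <- xyz[, 2]
  mol@atoms$z <- xyz[, 3]
  mol
}

# relabel atoms with a fixed permutation, remapping the bond table
permuteAtoms <- function(mol, perm) {
  inv <- order(perm)
  mol@atoms <- mol@atoms[perm, ]
  rownames(mol@atoms) <- NULL
  mol@bonds$i <- inv[mol@bonds$i]
  mol@bonds$j <- inv[mol@bonds$j]
  validObject(mol)
  mol
}

# a two-record SDF (ethanol, benzene) with a LOGS property field
writeTwoRecordSDF <- function(path, logs = c("-0.77", "-2.13")) {
  set <- fx[c("ethanol", "benzene")]
  set@molecules[[1]]@fields["LOGS"] <- logs[1]
  set@molecules[[2]]@fields["LOGS"] <- logs[2]
  writeSDF(set, path)
  path
}

# independent normal-equations OLS oracle (never used by the package)
normalEquationsFit <- function(X, y) {
  Z <- cbind(1, X)
  drop(solve(t(Z) %*% Z) %*% t(Z) %*% y)
}

# random full-rank regression fixture
randomFixture <- function(n = 30, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", seq_len(p))))
  beta <- rnorm(p + 1)
  y <- drop(cbind(1, X) %*% beta) + rnorm(n, 0, 0.3)
  list(X = X, y = y, beta = beta)
}

defaultSynthSpecs <- function() {
  descriptorRegistry()[c("molecular_weight", "hbd_count",
                         "rotatable_bond_count", "aromatic_atom_proportion")]
}
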