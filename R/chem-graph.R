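# Internal molecular-graph utilities: adjacency, implicit hydrogens, ring
# perception, a pragmatic aromaticity model, and idealized hydrogen
# placement for surface descriptors.

.adjacency <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  ord <- vector("list", n)
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]; o <- b$order[k]
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(nbr = adj, ord = ord)
}

# Implicit hydrogen count per atom from default valences, counting an
# aromatic (order 4) bond as 1.5 and rounding the total bond order.
# Formal charge shifts the valence of N/O-group elements by its sign
# (N+ -> 4, N- -> 2, O- -> 1, O+ -> 3); halogens/carbanions are left to
# explicit hydrogens in the file.
.implicitH <- function(mol) {
  g <- .adjacency(mol)
  el <- mol@atoms$element
  chg <- mol@atoms$charge
  n <- length(el)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (el[i] == "H") next
    val <- .DEFAULT_VALENCE[el[i]]
    if (is.na(val)) next
    if (el[i] %in% c("N", "P", "O", "S")) val <- val + chg[i]
    o <- g$ord[[i]]
    bsum <- if (length(o)) sum(ifelse(o == 4, 1.5, o)) else 0
    out[i] <- max(0L, as.integer(round(val - round(bsum))))
  }
  out
}

# Is bond k part of a ring? True iff its endpoints stay connected after
# removing the bond (breadth-first search on the remaining graph).
.ringBondMask <- function(mol) {
  b <- mol@bonds
  g <- .adjacency(mol)
  n <- nrow(mol@atoms)
  vapply(seq_len(nrow(b)), function(k) {
    from <- b$i[k]; to <- b$j[k]
    seen <- rep(FALSE, n)
    seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (idx in seq_along(g$nbr[[v]])) {
        w <- g$nbr[[v]][idx]
        if (v == from && w == to) next
        if (v == to && w == from) next
        if (!seen[w]) {
          if (w == to) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

# Enumerate simple cycles of length 5 or 6 (as ordered atom index vectors,
# deduplicated up to rotation/reflection). Exhaustive DFS; molecules here
# are desk-scale so this is cheap.
.cycles56 <- function(mol) {
  g <- .adjacency(mol)
  n <- nrow(mol@atoms)
  found <- list()
  keys <- character(0)
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in g$nbr[[v]]) {
      if (w == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% keys) {
          keys <<- c(keys, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (!w %in% path && length(path) < 6 && w > path[1]) {
        dfs(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  # keep only cycles whose sorted-key set is a real simple cycle of size 5/6
  found[vapply(found, function(p) length(p) %in% c(5L, 6L), logical(1))]
}

# Pragmatic aromaticity perception. An atom is aromatic if it lies on a
# 5- or 6-cycle that is either marked aromatic in the file (all bond
# order 4) or matches a Kekule pattern: 6-cycles need 3 alternating double
# bonds; 5-cycles need 2 doubles with the remaining (lone-pair) atom being
# N, O or S. Covers benzenoids, pyridines, pyrrole/furan/thiophene — the
# chemistry the engine's fixtures and generator produce; fused exotica are
# out of scope (documented).
.aromaticAtoms <- function(mol) {
  n <- nrow(mol@atoms)
  arom <- rep(FALSE, n)
  if (!nrow(mol@bonds)) return(arom)
  b <- mol@bonds
  bondOrder <- function(i, j) {
    k <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
    if (length(k)) b$order[k[1]] else 0L
  }
  el <- mol@atoms$element
  for (cyc in .cycles56(mol)) {
    m <- length(cyc)
    ords <- vapply(seq_len(m), function(t) {
      bondOrder(cyc[t], cyc[t %% m + 1])
    }, integer(1))
    ok <- FALSE
    if (all(ords == 4L)) {
      ok <- TRUE
    } else if (m == 6 && sum(ords == 2L) == 3 && sum(ords == 1L) == 3) {
      # alternation: no two adjacent ring bonds both double
      ok <- !any(ords == 2L & c(ords[-1], ords[1]) == 2L)
      ok <- ok && all(el[cyc] %in% c("C", "N"))
    } else if (m == 5 && sum(ords == 2L) == 2 && sum(ords == 1L) == 3) {
      dbl <- which(ords == 2L)
      onDouble <- unique(c(cyc[dbl], cyc[dbl %% m + 1]))
      lonepair <- setdiff(cyc, onDouble)
      ok <- length(lonepair) == 1 && el[lonepair] %in% c("N", "O", "S") &&
        all(el[cyc] %in% c("C", "N", "O", "S"))
    }
    if (ok) arom[cyc] <- TRUE
  }
  arom
}

# Hybridisation per atom from bond orders: any triple or two doubles -> sp;
# any double or aromatic bond -> sp2; else sp3.
.hybridisation <- function(mol) {
  g <- .adjacency(mol)
  arom <- .aromaticAtoms(mol)
  vapply(seq_len(nrow(mol@atoms)), function(i) {
    o <- g$ord[[i]]
    if (length(o) == 0) return("sp3")
    if (any(o == 3) || sum(o == 2) >= 2) return("sp")
    if (any(o == 2) || any(o == 4) || arom[i]) return("sp2")
    "sp3"
  }, character(1))
}

.norm1 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# Add idealized explicit hydrogens for atoms carrying implicit ones.
# Directions are built from the atom's neighbour geometry only, so the
# construction is rotation-equivariant; an atom with no neighbours falls
# back to fixed tetrahedral directions in the global frame. Bond lengths
# come from .XH_LENGTH. Returns the molecule (fields preserved) and
# messages how many hydrogens were added when verbose.
.addExplicitH <- function(mol, verbose = FALSE) {
  nh <- .implicitH(mol)
  if (!any(nh > 0)) return(mol)
  g <- .adjacency(mol)
  a <- mol@atoms
  newAtoms <- list()
  newBonds <- list()
  tet <- 109.471 * pi / 180
  fixedDirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  for (i in which(nh > 0)) {
    k <- nh[i]
    len <- .XH_LENGTH[a$element[i]]
    if (is.na(len)) len <- 1.1
    pos <- c(a$x[i], a$y[i], a$z[i])
    nbrs <- g$nbr[[i]]
    if (length(nbrs) == 0) {
      dirs <- fixedDirs[seq_len(min(k, 4)), , drop = FALSE]
    } else {
      units <- t(vapply(nbrs, function(w) {
        .norm1(c(a$x[w], a$y[w], a$z[w]) - pos)
      }, numeric(3)))
      d0 <- .norm1(-colSums(units))
      if (k == 1) {
        dirs <- matrix(d0, 1)
      } else {
        # orthonormal frame anchored on the first neighbour direction
        ref <- units[1, ]
        v <- ref - sum(ref * d0) * d0
        if (sqrt(sum(v^2)) < 1e-8) v <- c(d0[2], d0[3], d0[1])  # degenerate: any transversal
        v <- .norm1(v)
        w <- c(
          d0[2] * v[3] - d0[3] * v[2],
          d0[3] * v[1] - d0[1] * v[3],
          d0[1] * v[2] - d0[2] * v[1]
        )
        half <- tet / 2
        dirs <- t(vapply(seq_len(k), function(t) {
          phi <- 2 * pi * (t - 1) / k + pi / k
          .norm1(cos(half) * d0 + sin(half) * (cos(phi) * v + sin(phi) * w))
        }, numeric(3)))
      }
    }
    for (t in seq_len(nrow(dirs))) {
      hp <- pos + len * dirs[t, ]
      newAtoms[[length(newAtoms) + 1L]] <- data.frame(
        element = "H", x = hp[1], y = hp[2], z = hp[3], charge = 0L
      )
      newBonds[[length(newBonds) + 1L]] <- data.frame(
        i = i, j = nrow(a) + length(newAtoms), order = 1L
      )
    }
  }
  if (verbose) {
    message("added ", length(newAtoms), " idealized explicit hydrogen(s) to '",
            mol@name, "' for a surface/volume descriptor")
  }
  mol@atoms <- rbind(a, do.call(rbind, newAtoms))
  mol@bonds <- rbind(mol@bonds, do.call(rbind, newBonds))
  validObject(mol)
  mol
}

# Non-degenerate 3-D coordinates: not all atoms coincident and not the
# classic 2-D SDF signature of an all-zero z column (single atoms pass).
.has3D <- function(mol) {
  a <- mol@atoms
  if (nrow(a) == 1) return(TRUE)
  spread <- max(apply(a[, c("x", "y", "z")], 2, function(v) diff(range(v))))
  if (spread < 1e-6) return(FALSE)
  !all(abs(a$z) < 1e-8)
}
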