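# Numeric solvent-accessible surface areas by Shrake-Rupley sphere
# sampling: each atom carries a deterministic spherical point set at radius
# vdW + probe; a point survives if it lies outside every other atom's
# probe-expanded sphere; the atom's SAS is its sphere area times the
# surviving fraction.
#
# The point set is fixed in space, so a rigid rotation of the input would
# nudge the sampled areas. To keep surface descriptors rotation-invariant
# the coordinates are first canonicalised into a deterministic
# principal-axes frame built from the atom positions themselves (exact
# invariance whenever the coordinate covariance has distinct eigenvalues;
# highly symmetric tops are documented as a limitation).

.spherePoints <- function(n = 960L) {
  # Fibonacci (golden-spiral) sphere: deterministic, near-uniform
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.canonicalFrame <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xyz) < 3) return(xc)
  cv <- crossprod(xc) / nrow(xc)
  ev <- eigen(cv, symmetric = TRUE)
  R <- ev$vectors
  # deterministic, rotation-equivariant signs: each axis is flipped so the
  # atom with the largest |projection| projects positively (the decision
  # depends only on projections, which a rigid rotation leaves unchanged)
  for (k in 1:3) {
    pr <- xc %*% R[, k]
    j <- which.max(abs(pr))
    if (pr[j] < 0) R[, k] <- -R[, k]
  }
  xc %*% R
}

# Per-atom solvent-accessible surface area (A^2).
.sasAreas <- function(mol, probe = 1.4, nPoints = 960L) {
  a <- mol@atoms
  xyz <- .canonicalFrame(as.matrix(a[, c("x", "y", "z")]))
  r <- .elementRadius(a$element) + probe
  n <- nrow(a)
  pts <- .spherePoints(nPoints)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, nPoints)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      keep <- keep & d2 > r[j]^2
      if (!any(keep)) break
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(keep) / nPoints
  }
  areas
}
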