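# Gasteiger-Marsili partial charges by iterative partial equalisation of
# orbital electronegativity (PEOE). chi(q) = a + b q + c q^2 per atom; at
# iteration t the charge transferred across each bond is damped by (1/2)^t
# and normalised by chi+ (the electronegativity of the donor's cation
# state; 20.02 for hydrogen). Atoms whose element/hybridisation has no
# published parameters keep their formal charge and do not exchange.

.gasteigerKey <- function(el, hyb) {
  key <- switch(el,
    H = "H", F = "F", Cl = "Cl", Br = "Br", I = "I",
    C = paste0("C.", hyb), N = paste0("N.", hyb),
    O = paste0("O.", hyb), S = paste0("S.", hyb), P = "P.sp3",
    NA_character_
  )
  if (!is.na(key) && !key %in% rownames(.GASTEIGER)) key <- NA_character_
  key
}

# mol must carry fully explicit hydrogens (the descriptor layer ensures
# this). Returns one partial charge per atom; formal charges seed q0 and
# are conserved in total.
.gasteigerCharges <- function(mol, iterations = 8L) {
  el <- mol@atoms$element
  hyb <- .hybridisation(mol)
  n <- length(el)
  keys <- vapply(seq_len(n), function(i) .gasteigerKey(el[i], hyb[i]), character(1))
  par <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  ok <- !is.na(keys)
  par[ok, ] <- .GASTEIGER[keys[ok], , drop = FALSE]
  chiPlus <- ifelse(el == "H", 20.02, rowSums(par))
  q <- as.numeric(mol@atoms$charge)
  b <- mol@bonds
  active <- ok[b$i] & ok[b$j]
  for (t in seq_len(iterations)) {
    chi <- par[, "a"] + par[, "b"] * q + par[, "c"] * q^2
    damp <- 0.5^t
    dq <- numeric(n)
    for (k in which(active)) {
      i <- b$i[k]; j <- b$j[k]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j  # donor: lower electronegativity
      transfer <- (chi[j] - chi[i]) / chiPlus[lo] * damp
      dq[i] <- dq[i] + transfer
      dq[j] <- dq[j] - transfer
    }
    q <- q + dq
  }
  q
}
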