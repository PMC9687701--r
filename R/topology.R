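# Topology: bond graph construction, derivation of angle/dihedral/improper
# terms, nonbonded exclusions (1-2 and 1-3 excluded, 1-4 kept at full
# strength) and one-off resolution of forcefield parameters into flat
# per-term arrays.

slabBonds <- function(slabAtoms, offset = 0L) {
  bonds <- list()
  xyz <- as.matrix(slabAtoms[, c("x", "y", "z")])
  # hydroxyl O-H pairs
  oIdx <- which(slabAtoms$type == "OHM")
  hIdx <- which(slabAtoms$type == "HOM")
  if (length(oIdx) && length(hIdx)) {
    d2 <- outer(rowSums(xyz[oIdx, , drop = FALSE]^2),
                rowSums(xyz[hIdx, , drop = FALSE]^2), "+") -
      2 * xyz[oIdx, , drop = FALSE] %*% t(xyz[hIdx, , drop = FALSE])
    for (a in seq_along(oIdx)) {
      b <- which.min(d2[a, ])
      if (d2[a, b] < 1.3^2)
        bonds[[length(bonds) + 1L]] <- c(oIdx[a], hIdx[b])
    }
  }
  # phosphate P-O bonds (each P to its 4 tetrahedral oxygens)
  pIdx <- which(slabAtoms$type == "PHO")
  opIdx <- which(slabAtoms$type == "OPH")
  if (length(pIdx) && length(opIdx)) {
    d2 <- outer(rowSums(xyz[pIdx, , drop = FALSE]^2),
                rowSums(xyz[opIdx, , drop = FALSE]^2), "+") -
      2 * xyz[pIdx, , drop = FALSE] %*% t(xyz[opIdx, , drop = FALSE])
    for (a in seq_along(pIdx)) {
      near <- order(d2[a, ])[1:4]
      near <- near[d2[a, near] < 2.0^2]
      for (b in near) bonds[[length(bonds) + 1L]] <- c(pIdx[a], opIdx[b])
    }
  }
  if (!length(bonds)) return(NULL)
  do.call(rbind, bonds) + offset
}

waterBonds <- function(waterAtoms, offset = 0L) {
  if (!nrow(waterAtoms)) return(NULL)
  o <- which(waterAtoms$name == "OW")
  do.call(rbind, lapply(o, function(i) rbind(c(i, i + 1L), c(i, i + 2L)))) +
    offset
}

#' Bond list of a model
#'
#' Row matrix of 1-based atom-index pairs: template connectivity plus
#' peptide links for the protein chains, O-H and P-O bonds in the mineral,
#' and the two O-H bonds of each water.
#'
#' @param model a [CompositeModel-class] or [TripleHelixModel-class]
#' @return integer matrix with two columns
#' @export
modelBonds <- function(model) {
  if (is(model, "TripleHelixModel")) return(proteinBonds(model@atoms))
  stopifnot(is(model, "CompositeModel"))
  nH <- nrow(model@helix@atoms)
  nS <- nrow(model@slab@atoms)
  out <- list(proteinBonds(model@helix@atoms),
              slabBonds(model@slab@atoms, offset = nH),
              waterBonds(model@waters, offset = nH + nS))
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# ---- parameter lookup with CHARMM-style X wildcards --------------------

matchTypes <- function(tableTypes, tupleTypes) {
  # score of the best wildcard match (forward or reversed), NA if none
  score <- function(tt) {
    ok <- tableTypes == tt | tableTypes == "X"
    if (all(ok)) sum(tableTypes != "X") else NA_integer_
  }
  s <- c(score(tupleTypes), score(rev(tupleTypes)))
  if (all(is.na(s))) NA_integer_ else max(s, na.rm = TRUE)
}

lookupTerm <- function(table, typeCols, tuples, what) {
  # tuples: character matrix, one row per term; returns row index into table
  tt <- as.matrix(table[, typeCols, drop = FALSE])
  apply(tuples, 1, function(tu) {
    scores <- vapply(seq_len(nrow(tt)), function(r) {
      s <- suppressWarnings(matchTypes(tt[r, ], tu))
      if (is.na(s)) -1L else s
    }, numeric(1))
    best <- which(scores == max(scores) & scores >= 0)
    if (!length(best))
      stop("no ", what, " parameter for type tuple (",
           paste(tu, collapse = ", "), ")")
    tail(best, 1L)
  })
}

# ---- system assembly ---------------------------------------------------

#' Build a typed simulation system
#'
#' Resolves the model topology against a parameter set once, producing the
#' flat arrays the energy/force and dynamics routines consume: bonds,
#' Urey-Bradley 1-3 terms, valence angles, dihedrals, impropers, per-atom
#' masses/charges/Lennard-Jones parameters and the 1-2/1-3 exclusion list.
#'
#' @param model a [CompositeModel-class] or [TripleHelixModel-class]
#' @param params a [ForceFieldParameters-class]
#' @return an object of class "MDSystem"
#' @export
buildSystem <- function(model, params = defaultForceField()) {
  at <- atoms(model)
  n <- nrow(at)
  typeTab <- params@atoms
  ti <- match(at$type, typeTab$type)
  if (anyNA(ti))
    stop("atom type(s) absent from the parameter set: ",
         paste(unique(at$type[is.na(ti)]), collapse = ", "))

  bonds <- modelBonds(model)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  storage.mode(bonds) <- "integer"

  # adjacency
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  # angles: all neighbour pairs around each centre
  angleRows <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (cc in seq_len(ncol(cmb)))
        angleRows[[length(angleRows) + 1L]] <- c(cmb[1, cc], j, cmb[2, cc])
    }
  }
  angles <- if (length(angleRows)) do.call(rbind, angleRows)
            else matrix(integer(0), ncol = 3)

  # proper dihedrals: i-j-k-l over each central bond
  dihRows <- list()
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i != l) dihRows[[length(dihRows) + 1L]] <- c(i, j, k, l)
    }
  }
  dihedrals <- if (length(dihRows)) unique(do.call(rbind, dihRows))
               else matrix(integer(0), ncol = 4)

  # impropers at trigonal sp2 centres (type C with exactly 3 neighbours):
  # quadruple (centre, nb1, nb2, terminal) with the terminal picked by
  # priority O > OC > N2
  impRows <- list()
  prio <- c(O = 1, OC = 2, N2 = 3)
  for (j in which(at$type == "C")) {
    nb <- adj[[j]]
    if (length(nb) == 3) {
      pr <- prio[at$type[nb]]
      if (all(is.na(pr))) next
      d <- nb[which.min(pr)]
      rest <- sort(setdiff(nb, d))
      impRows[[length(impRows) + 1L]] <- c(j, rest[1], rest[2], d)
    }
  }
  impropers <- if (length(impRows)) do.call(rbind, impRows)
               else matrix(integer(0), ncol = 4)

  # resolve parameters
  ty <- at$type
  bondPar <- if (nrow(bonds)) {
    key <- paste(pmin(ty[bonds[, 1]], ty[bonds[, 2]]),
                 pmax(ty[bonds[, 1]], ty[bonds[, 2]]))
    tabKey <- paste(pmin(params@bonds$typeI, params@bonds$typeJ),
                    pmax(params@bonds$typeI, params@bonds$typeJ))
    idx <- match(key, tabKey)
    if (anyNA(idx)) {
      bad <- unique(key[is.na(idx)])
      stop("no bond parameter for type pair(s): ", paste(bad, collapse = "; "))
    }
    list(kb = params@bonds$kb[idx], r0 = params@bonds$r0[idx])
  } else list(kb = numeric(0), r0 = numeric(0))

  anglePar <- if (nrow(angles)) {
    tuples <- cbind(ty[angles[, 1]], ty[angles[, 2]], ty[angles[, 3]])
    idx <- lookupTerm(params@angles, c("typeI", "typeJ", "typeK"),
                      tuples, "angle")
    list(ktheta = params@angles$ktheta[idx],
         theta0 = degToRad(params@angles$theta0[idx]),
         kub = params@angles$kub[idx], rub0 = params@angles$rub0[idx])
  } else list(ktheta = numeric(0), theta0 = numeric(0),
              kub = numeric(0), rub0 = numeric(0))

  dihPar <- if (nrow(dihedrals)) {
    tuples <- cbind(ty[dihedrals[, 1]], ty[dihedrals[, 2]],
                    ty[dihedrals[, 3]], ty[dihedrals[, 4]])
    idx <- lookupTerm(params@dihedrals,
                      c("typeI", "typeJ", "typeK", "typeL"),
                      tuples, "dihedral")
    list(kphi = params@dihedrals$kphi[idx], n = params@dihedrals$n[idx])
  } else list(kphi = numeric(0), n = integer(0))

  impPar <- if (nrow(impropers)) {
    tuples <- cbind(ty[impropers[, 1]], ty[impropers[, 2]],
                    ty[impropers[, 3]], ty[impropers[, 4]])
    idx <- lookupTerm(params@impropers,
                      c("typeI", "typeJ", "typeK", "typeL"),
                      tuples, "improper")
    list(komega = params@impropers$komega[idx],
         omega0 = degToRad(params@impropers$omega0[idx]))
  } else list(komega = numeric(0), omega0 = numeric(0))

  # Urey-Bradley terms ride on angles with kub > 0
  ubSel <- which(anglePar$kub > 0)
  ub <- angles[ubSel, c(1, 3), drop = FALSE]
  ubPar <- list(kub = anglePar$kub[ubSel], rub0 = anglePar$rub0[ubSel])

  # exclusions: 1-2 and 1-3
  exclKeys <- unique(c(
    pairKey(bonds[, 1], bonds[, 2], n),
    if (nrow(angles)) pairKey(angles[, 1], angles[, 3], n)))

  structure(list(
    atoms = at, n = n,
    pos = as.matrix(at[, c("x", "y", "z")]),
    mass = typeTab$mass[ti],
    charge = at$charge,
    epsilon = typeTab$epsilon[ti],
    rminHalf = typeTab$rminHalf[ti],
    bonds = bonds, bondPar = bondPar,
    angles = angles, anglePar = anglePar,
    ub = ub, ubPar = ubPar,
    dihedrals = dihedrals, dihPar = dihPar,
    impropers = impropers, impPar = impPar,
    exclKeys = sort(exclKeys),
    coulombConstant = params@coulombConstant),
    class = "MDSystem")
}

pairKey <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (as.numeric(lo) - 1) * n + hi
}

#' @export
print.MDSystem <- function(x, ...) {
  cat(sprintf(
    "MDSystem: %d atoms, %d bonds, %d angles (%d UB), %d dihedrals, %d impropers\n",
    x$n, nrow(x$bonds), nrow(x$angles), nrow(x$ub), nrow(x$dihedrals),
    nrow(x$impropers)))
  invisible(x)
}
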