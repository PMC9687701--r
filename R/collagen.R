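# Collagen triple-helix construction.
#
# The builder places residues on a right-handed triple-helical scaffold
# (axial rise 2.86 A per residue, ~10.5 residues per superhelical turn,
# chains phased by 120 degrees) using united-heavy-atom residue templates
# with polar hydroxyl hydrogens.  Template geometry is approximate; models
# intended for dynamics are relaxed by energy minimisation first.

COLLAGEN_RISE <- 2.86      # A per residue along the helix axis
COLLAGEN_TWIST <- 360 / 10.5  # deg per residue, right-handed
COLLAGEN_CA_RADIUS <- 2.6  # A, radial position of the C-alpha trace

alpha1Repeat <- function() {
  c(rep(c("PRO", "HYP", "GLY"), 4), "GLU", "LYS", "GLY",
    rep(c("PRO", "HYP", "GLY"), 5))
}

alpha2Repeat <- function() head(alpha1Repeat(), 29L)

#' Canonical collagen chain sequences
#'
#' Single-repeat sequences of the type I collagen alpha1 (30 residues) and
#' alpha2 (29 residues) chains: Gly-X-Y triplets of proline/hydroxyproline/
#' glycine with one GLU-LYS-GLY triplet.
#'
#' @param chainType "alpha1" or "alpha2"
#' @param residues optional custom single-repeat residue vector
#' @param nRepeats tandem repeat count
#' @return a [ChainSequence-class]
#' @export
collagenChainSequence <- function(chainType = c("alpha1", "alpha2"),
                                  residues = NULL, nRepeats = 1L) {
  chainType <- match.arg(chainType)
  if (is.null(residues))
    residues <- if (chainType == "alpha1") alpha1Repeat() else alpha2Repeat()
  if (!is.numeric(nRepeats) || nRepeats < 1 || nRepeats != as.integer(nRepeats))
    stop("nRepeats must be an integer >= 1")
  new("ChainSequence", chainType = chainType, residues = residues,
      nRepeats = as.integer(nRepeats))
}

# Residue templates.  Each atom: name, element, forcefield type, charge and
# offsets from the C-alpha position in the local frame (ax = along helix
# axis, rad = radially outward, tan = tangential).  `bonds` lists in-residue
# connectivity by atom name; "N-" in code marks the inter-residue peptide
# bond handled by the builder.
residueTemplates <- function() {
  bb <- data.frame(
    name = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    type = c("N", "CT", "C", "O"),
    charge = c(-0.40, 0.25, 0.55, -0.40),
    ax = c(-1.15, 0.00, 1.15, 1.15),
    rad = c(-0.20, 0.00, -0.20, 0.54),
    tan = c(-0.45, 0.00, 0.45, -0.53),
    stringsAsFactors = FALSE)
  bbBonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  side <- function(name, element, type, charge, ax, rad, tan) {
    data.frame(name = name, element = element, type = type, charge = charge,
               ax = ax, rad = rad, tan = tan, stringsAsFactors = FALSE)
  }
  tpl <- list()
  tpl$GLY <- list(atoms = bb, bonds = bbBonds)
  proSide <- rbind(
    side("CB", "C", "CT", 0.00, 0.00, 1.45, 0.50),
    side("CG", "C", "CT", 0.00, -1.20, 2.20, 0.45),
    side("CD", "C", "CT", 0.00, -1.95, 1.05, -0.10))
  proBonds <- c(bbBonds, list(c("CA", "CB"), c("CB", "CG"),
                              c("CG", "CD"), c("CD", "N")))
  tpl$PRO <- list(atoms = rbind(bb, proSide), bonds = proBonds)
  hypAtoms <- rbind(bb, proSide,
    side("OD1", "O", "OH1", -0.66, -1.35, 3.55, 0.75),
    side("HD1", "H", "HO", 0.43, -0.85, 4.20, 1.15))
  hypAtoms$charge[hypAtoms$name == "CG"] <- 0.23
  tpl$HYP <- list(atoms = hypAtoms,
                  bonds = c(proBonds, list(c("CG", "OD1"), c("OD1", "HD1"))))
  tpl$GLU <- list(atoms = rbind(bb,
    side("CB", "C", "CT", 0.00, 0.00, 1.45, 0.50),
    side("CG", "C", "CT", 0.00, 0.45, 2.75, 0.95),
    side("CD", "C", "C", 0.50, 0.10, 4.15, 1.20),
    side("OE1", "O", "OC", -0.75, 1.00, 4.95, 1.35),
    side("OE2", "O", "OC", -0.75, -1.05, 4.55, 1.40)),
    bonds = c(bbBonds, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                            c("CD", "OE1"), c("CD", "OE2"))))
  tpl$LYS <- list(atoms = rbind(bb,
    side("CB", "C", "CT", 0.00, 0.00, 1.45, 0.50),
    side("CG", "C", "CT", 0.00, 0.45, 2.75, 0.95),
    side("CD", "C", "CT", 0.00, 0.00, 4.05, 1.30),
    side("CE", "C", "CT", 0.25, 0.45, 5.35, 1.65),
    side("NZ", "N", "N3", 0.75, 0.00, 6.60, 1.95)),
    bonds = c(bbBonds, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                            c("CD", "CE"), c("CE", "NZ"))))
  tpl$VAL <- list(atoms = rbind(bb,
    side("CB", "C", "CT", 0.00, 0.00, 1.45, 0.50),
    side("CG1", "C", "CT", 0.00, 0.90, 2.50, 1.00),
    side("CG2", "C", "CT", 0.00, -1.05, 2.35, 0.85)),
    bonds = c(bbBonds, list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"))))
  tpl$ARG <- list(atoms = rbind(bb,
    side("CB", "C", "CT", 0.00, 0.00, 1.45, 0.50),
    side("CG", "C", "CT", 0.00, 0.45, 2.75, 0.95),
    side("CD", "C", "CT", 0.00, 0.00, 4.05, 1.30),
    side("NE", "N", "N2", -0.40, 0.45, 5.30, 1.60),
    side("CZ", "C", "C", 0.80, 0.00, 6.55, 1.90),
    side("NH1", "N", "N2", 0.30, 0.95, 7.45, 2.10),
    side("NH2", "N", "N2", 0.30, -1.00, 7.40, 2.15)),
    bonds = c(bbBonds, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                            c("CD", "NE"), c("NE", "CZ"),
                            c("CZ", "NH1"), c("CZ", "NH2"))))
  tpl$ASP <- list(atoms = rbind(bb,
    side("CB", "C", "CT", 0.00, 0.00, 1.45, 0.50),
    side("CG", "C", "C", 0.50, 0.45, 2.75, 0.95),
    side("OD1", "O", "OC", -0.75, 1.35, 3.55, 1.15),
    side("OD2", "O", "OC", -0.75, -0.65, 3.55, 1.25)),
    bonds = c(bbBonds, list(c("CA", "CB"), c("CB", "CG"),
                            c("CG", "OD1"), c("CG", "OD2"))))
  tpl$CYS <- list(atoms = rbind(bb,
    side("CB", "C", "CT", 0.20, 0.00, 1.45, 0.50),
    side("SG", "S", "S", -0.20, 0.45, 3.10, 1.05)),
    bonds = c(bbBonds, list(c("CA", "CB"), c("CB", "SG"))))
  tpl
}

# cycle a repeat sequence to an exact residue count
cycleSequence <- function(repeatSeq, n) {
  rep(repeatSeq, length.out = n)
}

placeChain <- function(resnames, chainId, phaseDeg, templates) {
  out <- vector("list", length(resnames))
  for (i in seq_along(resnames)) {
    rn <- resnames[i]
    if (is.null(templates[[rn]]))
      stop("unknown residue code '", rn, "' in chain ", chainId)
    tpl <- templates[[rn]]$atoms
    xAx <- (i - 1) * COLLAGEN_RISE
    ang <- degToRad(phaseDeg + (i - 1) * COLLAGEN_TWIST)
    radhat <- c(0, cos(ang), sin(ang))
    tanhat <- c(0, -sin(ang), cos(ang))   # xhat x radhat
    pos <- cbind(xAx + tpl$ax,
                 tpl$rad * radhat[2] + tpl$tan * tanhat[2] +
                   COLLAGEN_CA_RADIUS * radhat[2],
                 tpl$rad * radhat[3] + tpl$tan * tanhat[3] +
                   COLLAGEN_CA_RADIUS * radhat[3])
    out[[i]] <- data.frame(
      element = tpl$element, name = tpl$name, resname = rn,
      resid = i, chain = chainId, type = tpl$type, charge = tpl$charge,
      x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build a collagen triple-helix model
#'
#' Places two alpha1 chains (A, B) and one alpha2 chain (C) on a
#' right-handed triple-helical scaffold along +X.  With the default
#' configuration (`nRepeats = NULL`) the repeat sequences are cycled so the
#' model carries exactly `totalResidues` residues in total (342 + 342 + 330
#' for the canonical 1014); with an explicit `nRepeats` each chain is that
#' many tandem repeats.
#'
#' @param alpha1,alpha2 [ChainSequence-class] objects (single repeats)
#' @param nRepeats tandem repeats per chain, or NULL for the default build
#' @param totalResidues total residue target for the default build
#' @param targetLength optional helix length (nm); when given, chains are
#'   truncated so the built length does not exceed it
#' @return a [TripleHelixModel-class]
#' @examples
#' helix <- buildCollagenHelix(nRepeats = 1)
#' residueCount(helix)  # 89
#' @export
buildCollagenHelix <- function(alpha1 = collagenChainSequence("alpha1"),
                               alpha2 = collagenChainSequence("alpha2"),
                               nRepeats = NULL, totalResidues = 1014L,
                               targetLength = NULL) {
  stopifnot(is(alpha1, "ChainSequence"), is(alpha2, "ChainSequence"))
  templates <- residueTemplates()
  if (is.null(nRepeats)) {
    n1 <- length(alpha1@residues)  # 30
    n2 <- length(alpha2@residues)  # 29
    per1 <- round(totalResidues * n1 / (2 * n1 + n2))
    per2 <- totalResidues - 2 * per1
    counts <- c(per1, per1, per2)
  } else {
    if (!is.numeric(nRepeats) || nRepeats < 1 ||
        nRepeats != as.integer(nRepeats))
      stop("nRepeats must be an integer >= 1")
    counts <- c(length(alpha1@residues) * nRepeats,
                length(alpha1@residues) * nRepeats,
                length(alpha2@residues) * nRepeats)
  }
  if (!is.null(targetLength)) {
    maxRes <- floor(targetLength * 10 / COLLAGEN_RISE) + 1L
    counts <- pmin(counts, maxRes)
  }
  seqs <- list(cycleSequence(alpha1@residues, counts[1]),
               cycleSequence(alpha1@residues, counts[2]),
               cycleSequence(alpha2@residues, counts[3]))
  chains <- c("A", "B", "C")
  atomsDf <- do.call(rbind, lapply(1:3, function(k)
    placeChain(seqs[[k]], chains[k], (k - 1) * 120, templates)))
  rownames(atomsDf) <- NULL
  # centre the helix on the axis origin
  atomsDf$x <- atomsDf$x - mean(range(atomsDf$x))
  lenNm <- diff(range(atomsDf$x)) / 10
  diamNm <- 2 * max(sqrt(atomsDf$y^2 + atomsDf$z^2)) / 10
  reps <- if (is.null(nRepeats)) 1L else as.integer(nRepeats)
  new("TripleHelixModel",
      chains = list(
        collagenChainSequence("alpha1", alpha1@residues, reps),
        collagenChainSequence("alpha1", alpha1@residues, reps),
        collagenChainSequence("alpha2", alpha2@residues, reps)),
      atoms = atomsDf, residueCount = as.integer(sum(counts)),
      length = lenNm, diameter = diamNm)
}

# bond list (pairs of row indices into an atom table) for protein chains,
# built from residue templates plus peptide C(i)-N(i+1) links
proteinBonds <- function(atomsDf) {
  templates <- residueTemplates()
  keys <- paste(atomsDf$chain, atomsDf$resid, atomsDf$name)
  idx <- setNames(seq_len(nrow(atomsDf)), keys)
  bonds <- list()
  resTab <- unique(atomsDf[, c("chain", "resid", "resname")])
  for (r in seq_len(nrow(resTab))) {
    ch <- resTab$chain[r]; ri <- resTab$resid[r]; rn <- resTab$resname[r]
    for (b in templates[[rn]]$bonds) {
      i <- idx[paste(ch, ri, b[1])]
      j <- idx[paste(ch, ri, b[2])]
      if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1L]] <- c(i, j)
    }
    jN <- idx[paste(ch, ri + 1L, "N")]
    iC <- idx[paste(ch, ri, "C")]
    if (!is.na(jN) && !is.na(iC)) bonds[[length(bonds) + 1L]] <- c(iC, jN)
  }
  do.call(rbind, bonds)
}
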