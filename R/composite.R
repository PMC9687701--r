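# Composite assembly: orienting the helix over the mineral slab, hydration
# shells, glycine substitution (osteogenesis imperfecta variants) and crack
# defects.

# minimum distance between two coordinate sets, restricted to atoms near
# the interface to keep the pair count manageable
minCrossDistance <- function(A, B, slack = 12) {
  zaMin <- min(A[, 3]); zbMax <- max(B[, 3])
  A2 <- A[A[, 3] < zaMin + slack, , drop = FALSE]
  B2 <- B[B[, 3] > zbMax - slack, , drop = FALSE]
  d2 <- outer(rowSums(A2^2), rowSums(B2^2), "+") - 2 * A2 %*% t(B2)
  sqrt(max(0, min(d2)))
}

#' Assemble an oriented collagen-hydroxyapatite composite
#'
#' Rotates the helix in the XZ plane so its axis makes `orientationDeg`
#' degrees with the +X load axis, then places it above the +Z face of the
#' slab so that the minimum helix-slab atom distance equals `gap`.
#'
#' @param helix a [TripleHelixModel-class] (built along +X)
#' @param slab a [CrystalSlab-class]
#' @param orientationDeg angle in degrees, in [0, 90]
#' @param hydrated logical; use [hydrate()] to actually add waters
#' @param gap minimum helix-slab distance (Angstrom)
#' @param clashDistance steric clash threshold (Angstrom)
#' @return a [CompositeModel-class]
#' @export
assembleComposite <- function(helix, slab, orientationDeg, hydrated = FALSE,
                              gap = 3.0, clashDistance = 1.5) {
  stopifnot(is(helix, "TripleHelixModel"), is(slab, "CrystalSlab"))
  if (!is.numeric(orientationDeg) || length(orientationDeg) != 1 ||
      orientationDeg < 0 || orientationDeg > 90)
    stop("orientationDeg must lie in [0, 90]")
  if (gap < 0) stop("gap must be >= 0")

  slabAtoms <- slab@atoms
  # slab top face at z = 0, centred in x/y
  slabAtoms$x <- slabAtoms$x - mean(range(slabAtoms$x))
  slabAtoms$y <- slabAtoms$y - mean(range(slabAtoms$y))
  slabAtoms$z <- slabAtoms$z - max(slabAtoms$z)
  slab@atoms <- slabAtoms

  th <- degToRad(orientationDeg)
  hx <- as.matrix(helix@atoms[, c("x", "y", "z")])
  # rotate about +Y: +X axis tips towards +Z by theta
  rot <- cbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  hx <- hx %*% t(rot)
  hx[, 1] <- hx[, 1] - mean(range(hx[, 1]))
  hx[, 2] <- hx[, 2] - mean(range(hx[, 2]))

  slabXYZ <- as.matrix(slabAtoms[, c("x", "y", "z")])
  # iterate the vertical offset until min distance == gap
  hx[, 3] <- hx[, 3] - min(hx[, 3]) + gap
  for (it in 1:30) {
    d <- minCrossDistance(hx, slabXYZ)
    if (abs(d - gap) < 1e-9) break
    hx[, 3] <- hx[, 3] + (gap - d)
  }
  helix@atoms[, c("x", "y", "z")] <- hx

  d <- minCrossDistance(hx, slabXYZ)
  if (d < clashDistance) {
    stop(sprintf(
      "steric clash: minimum helix-slab distance %.3f A below threshold %.2f A",
      d, clashDistance))
  }
  new("CompositeModel", helix = helix, slab = slab,
      orientationDeg = orientationDeg, hydrated = FALSE,
      waters = emptyAtomTable(),
      provenance = list(orientationDeg = orientationDeg, gap = gap,
                        clashDistance = clashDistance,
                        minHelixSlabDistance = d,
                        helixAxis = as.numeric(rot %*% c(1, 0, 0)),
                        surface = slab@exposedSurface,
                        hydrationRequested = hydrated))
}

#' Helix axis direction of a composite model
#'
#' For a composite assembled by [assembleComposite()] this is the exact
#' rotated build axis recorded in the provenance; otherwise the principal
#' axis of the C-alpha trace (first principal component).
#'
#' @param model a [CompositeModel-class] or [TripleHelixModel-class]
#' @return length-3 unit vector (sign chosen with positive X component)
#' @export
helixAxis <- function(model) {
  if (is(model, "CompositeModel") &&
      !is.null(model@provenance$helixAxis))
    return(normalize(model@provenance$helixAxis))
  at <- if (is(model, "CompositeModel")) model@helix@atoms else model@atoms
  ca <- at[at$name == "CA", c("x", "y", "z")]
  v <- prcomp(ca, center = TRUE)$rotation[, 1]
  if (v[1] < 0) v <- -v
  unname(normalize(v))
}

# rigid water template: O-H 0.9572 A, H-O-H 104.52 deg, in the xy plane
waterTemplate <- function() {
  ang <- degToRad(104.52 / 2)
  rbind(O = c(0, 0, 0),
        H1 = 0.9572 * c(sin(ang), cos(ang), 0),
        H2 = 0.9572 * c(-sin(ang), cos(ang), 0))
}

randomRotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Hydrate a composite model
#'
#' Places rigid three-site waters within `shellThickness` of any solute
#' atom at the bulk-water number density (0.0334 molecules/A^3), keeping
#' every water oxygen at least `exclusion` Angstrom from solute atoms and
#' from other water oxygens.  Placement is random but fully determined by
#' `seed`.
#'
#' @param model a [CompositeModel-class]
#' @param shellThickness shell thickness (Angstrom); 0 leaves the model
#'   unchanged
#' @param seed RNG seed for the placement
#' @param exclusion minimum water-solute / water-water oxygen distance (A)
#' @param density target number density (molecules/A^3)
#' @param mcSamples Monte-Carlo samples for the accessible-volume estimate
#' @return the hydrated [CompositeModel-class]
#' @export
hydrate <- function(model, shellThickness, seed = 42L, exclusion = 2.4,
                    density = 0.0334, mcSamples = 20000L) {
  stopifnot(is(model, "CompositeModel"))
  if (shellThickness < 0) stop("shellThickness must be >= 0")
  if (shellThickness == 0) return(model)

  solute <- rbind(model@helix@atoms, model@slab@atoms)
  S <- as.matrix(solute[, c("x", "y", "z")])
  lo <- apply(S, 2, min) - shellThickness
  hi <- apply(S, 2, max) + shellThickness
  boxV <- prod(hi - lo)

  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(as.integer(seed))

  minD2 <- function(P, batch = 2000L) {
    # squared distance from each row of P to the nearest solute atom
    out <- numeric(nrow(P))
    s2 <- rowSums(S^2)
    for (b in seq(1, nrow(P), by = batch)) {
      ii <- b:min(b + batch - 1L, nrow(P))
      d2 <- outer(rowSums(P[ii, , drop = FALSE]^2), s2, "+") -
        2 * P[ii, , drop = FALSE] %*% t(S)
      out[ii] <- apply(d2, 1, min)
    }
    pmax(out, 0)
  }

  mc <- cbind(runif(mcSamples, lo[1], hi[1]), runif(mcSamples, lo[2], hi[2]),
              runif(mcSamples, lo[3], hi[3]))
  d2 <- minD2(mc)
  accessible <- d2 <= shellThickness^2 & d2 >= exclusion^2
  vAcc <- boxV * mean(accessible)
  nTarget <- round(density * vAcc)

  placed <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  maxTries <- 200L * max(1, nTarget)
  while (nrow(placed) < nTarget && tries < maxTries) {
    n <- min(4L * (nTarget - nrow(placed)) + 16L, 5000L)
    cand <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                  runif(n, lo[3], hi[3]))
    tries <- tries + n
    d2 <- minD2(cand)
    cand <- cand[d2 <= shellThickness^2 & d2 >= exclusion^2, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      if (nrow(placed) >= nTarget) break
      if (nrow(placed) == 0 ||
          min(rowSums(sweep(placed, 2, cand[r, ])^2)) >= exclusion^2)
        placed <- rbind(placed, cand[r, ])
    }
  }

  nW <- nrow(placed)
  waters <- emptyAtomTable()
  if (nW > 0) {
    tpl <- waterTemplate()
    coords <- do.call(rbind, lapply(seq_len(nW), function(i) {
      sweep(tpl %*% t(randomRotation()), 2, placed[i, ], "+")
    }))
    waters <- data.frame(
      element = rep(c("O", "H", "H"), nW),
      name = rep(c("OW", "HW1", "HW2"), nW),
      resname = "HOH", resid = rep(seq_len(nW), each = 3L),
      chain = "W", type = rep(c("OT", "HT", "HT"), nW),
      charge = rep(c(-0.834, 0.417, 0.417), nW),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
  }
  model@waters <- waters
  model@hydrated <- TRUE
  model@provenance <- c(model@provenance, list(
    hydration = list(shellThickness = shellThickness, seed = seed,
                     exclusion = exclusion, density = density,
                     accessibleVolume = vAcc, nWaters = nW,
                     nTarget = nTarget)))
  model
}

#' Substitute glycine residues (osteogenesis imperfecta variants)
#'
#' Replaces targeted GLY residues of the helix with one of the disease
#' variants (VAL, ARG, ASP, GLU, CYS): backbone atoms are left untouched
#' and the variant's side chain is grafted onto the C-alpha using the
#' residue's local helix frame.
#'
#' @param model a [CompositeModel-class] or [TripleHelixModel-class]
#' @param variant one of "VAL", "ARG", "ASP", "GLU", "CYS"
#' @param positions "all", or a data.frame with columns chain and resid
#' @return the modified model (same class as the input)
#' @export
applyGlySubstitution <- function(model, variant = c("VAL", "ARG", "ASP",
                                                    "GLU", "CYS"),
                                 positions = "all") {
  variant <- match.arg(variant)
  isComposite <- is(model, "CompositeModel")
  helix <- if (isComposite) model@helix else model
  stopifnot(is(helix, "TripleHelixModel"))
  at <- helix@atoms

  resTab <- unique(at[, c("chain", "resid", "resname")])
  if (identical(positions, "all")) {
    targets <- resTab[resTab$resname == "GLY", c("chain", "resid")]
  } else {
    targets <- as.data.frame(positions)
    if (!all(c("chain", "resid") %in% names(targets)))
      stop("positions must be 'all' or a data.frame with chain and resid")
    for (r in seq_len(nrow(targets))) {
      hit <- resTab$chain == targets$chain[r] & resTab$resid == targets$resid[r]
      if (!any(hit))
        stop(sprintf("no residue %s:%d in the model",
                     targets$chain[r], targets$resid[r]))
      if (resTab$resname[hit] != "GLY")
        stop(sprintf("residue %s:%d is %s, not GLY; refusing to substitute",
                     targets$chain[r], targets$resid[r], resTab$resname[hit]))
    }
  }

  templates <- residueTemplates()
  tpl <- templates[[variant]]$atoms
  sideTpl <- tpl[!tpl$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  chainPhase <- c(A = 0, B = 120, C = 240)

  newRows <- list()
  for (r in seq_len(nrow(targets))) {
    ch <- targets$chain[r]; ri <- targets$resid[r]
    sel <- at$chain == ch & at$resid == ri
    at$resname[sel] <- variant
    if (nrow(sideTpl)) {
      caRow <- at[sel & at$name == "CA", ]
      ang <- degToRad(chainPhase[[ch]] + (ri - 1) * COLLAGEN_TWIST)
      radhat <- c(0, cos(ang), sin(ang))
      tanhat <- c(0, -sin(ang), cos(ang))
      pos <- cbind(caRow$x + sideTpl$ax,
                   caRow$y + sideTpl$rad * radhat[2] + sideTpl$tan * tanhat[2],
                   caRow$z + sideTpl$rad * radhat[3] + sideTpl$tan * tanhat[3])
      newRows[[length(newRows) + 1L]] <- data.frame(
        element = sideTpl$element, name = sideTpl$name, resname = variant,
        resid = ri, chain = ch, type = sideTpl$type, charge = sideTpl$charge,
        x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
    }
  }
  if (length(newRows)) at <- rbind(at, do.call(rbind, newRows))
  ord <- order(match(at$chain, c("A", "B", "C")), at$resid,
               match(at$name, c("N", "CA", "C", "O"), nomatch = 99L))
  at <- at[ord, , drop = FALSE]
  rownames(at) <- NULL
  helix@atoms <- at

  if (isComposite) {
    model@helix <- helix
    model@provenance <- c(model@provenance, list(
      substitution = list(variant = variant, count = nrow(targets))))
    model
  } else helix
}

#' Construct a crack geometry
#'
#' @param shape "ellipsoid" (dimensions = semi-axes) or "slit" (dimensions =
#'   half-length along `orientation`, half-height along Z, half-opening)
#' @param center Cartesian centre (Angstrom)
#' @param dimensions three non-negative lengths (Angstrom)
#' @param orientation crack axis (defaults to the +X load axis)
#' @return a [CrackGeometry-class]
#' @export
crackGeometry <- function(shape = c("ellipsoid", "slit"), center = c(0, 0, 0),
                          dimensions = c(0, 0, 0),
                          orientation = c(1, 0, 0)) {
  shape <- match.arg(shape)
  new("CrackGeometry", shape = shape, center = as.numeric(center),
      dimensions = as.numeric(dimensions),
      orientation = normalize(as.numeric(orientation)))
}

# logical vector: which rows of an atom table fall strictly inside a crack
atomsInsideCrack <- function(atomsDf, crack) {
  if (all(crack@dimensions == 0)) return(rep(FALSE, nrow(atomsDf)))
  P <- sweep(as.matrix(atomsDf[, c("x", "y", "z")]), 2, crack@center)
  u <- crack@orientation
  # orthonormal frame: u, v (in XY if possible), w
  v <- if (abs(u[3]) < 0.9) normalize(c(-u[2], u[1], 0)) else c(1, 0, 0)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  loc <- cbind(P %*% u, P %*% v, P %*% w)
  d <- pmax(crack@dimensions, 1e-12)
  if (crack@shape == "ellipsoid") {
    rowSums(sweep(loc, 2, d, "/")^2) < 1
  } else {
    abs(loc[, 1]) < d[1] & abs(loc[, 2]) < d[2] & abs(loc[, 3]) < d[3]
  }
}

#' Carve a crack into a composite model
#'
#' Removes every atom strictly inside the crack region (helix, mineral and
#' water atoms alike); bonds crossing the void vanish with their atoms
#' because connectivity is derived from the surviving atoms.  A crack that
#' would swallow more than half of the model is refused.
#'
#' @param model a [CompositeModel-class]
#' @param crack a [CrackGeometry-class]
#' @return the cracked [CompositeModel-class]; the provenance records the
#'   removed-atom count
#' @export
introduceCrack <- function(model, crack) {
  stopifnot(is(model, "CompositeModel"), is(crack, "CrackGeometry"))
  inH <- atomsInsideCrack(model@helix@atoms, crack)
  inS <- atomsInsideCrack(model@slab@atoms, crack)
  inW <- if (nrow(model@waters)) atomsInsideCrack(model@waters, crack)
         else logical(0)
  nRemoved <- sum(inH) + sum(inS) + sum(inW)
  nTotal <- nAtoms(model)
  if (nRemoved > 0.5 * nTotal)
    stop(sprintf(
      "crack would remove %d of %d atoms (> 50%%); model no longer meaningful",
      nRemoved, nTotal))
  model@helix@atoms <- model@helix@atoms[!inH, , drop = FALSE]
  # keep the residue bookkeeping of the helix consistent
  model@helix@residueCount <- as.integer(length(unique(paste(
    model@helix@atoms$chain, model@helix@atoms$resid))))
  model@slab@atoms <- model@slab@atoms[!inS, , drop = FALSE]
  if (length(inW)) model@waters <- model@waters[!inW, , drop = FALSE]
  model@provenance <- c(model@provenance, list(
    crack = list(shape = crack@shape, center = crack@center,
                 dimensions = crack@dimensions, removed = nRemoved)))
  model
}
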