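# CHARMM-style potential energy and analytic forces.
#
#   E = E_INTRA + E_INTER
#   E_INTRA = sum kb (r - r0)^2 + sum ktheta (theta - theta0)^2
#           + sum kub (r13 - rub0)^2 + sum kphi (1 - cos(n phi))
#           + sum komega (omega - omega0)^2
#   E_INTER = sum C qi qj / r + sum eps [(Rmin/r)^12 - 2 (Rmin/r)^6]
#
# The torsion term follows the printed k(1 - cos n phi) form by default; the
# conventional CHARMM k(1 + cos(n phi - delta)) is available via
# `charmmDihedral = TRUE` (delta = 0).

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# accumulate per-term contributions into per-atom rows
addRows <- function(F, idx, M) {
  S <- rowsum(M, idx)
  rows <- as.integer(rownames(S))
  F[rows, ] <- F[rows, ] + S
  F
}

newBreakdown <- function(bond = 0, angle = 0, ub = 0, dihedral = 0,
                         improper = 0, coulomb = 0, vdw = 0) {
  intra <- bond + angle + ub + dihedral + improper
  inter <- coulomb + vdw
  structure(list(bond = bond, angle = angle, ub = ub, dihedral = dihedral,
                 improper = improper, intra = intra, coulomb = coulomb,
                 vdw = vdw, inter = inter, total = intra + inter),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf(
    paste0("Energy (kcal/mol): total %.4f\n  intra %.4f",
           " (bond %.4f, angle %.4f, UB %.4f, dihedral %.4f, improper %.4f)\n",
           "  inter %.4f (coulomb %.4f, vdw %.4f)\n"),
    x$total, x$intra, x$bond, x$angle, x$ub, x$dihedral, x$improper,
    x$inter, x$coulomb, x$vdw))
  invisible(x)
}

# torsion angles and gradients for quadruples; returns list(phi, g1..g4)
torsionGeometry <- function(p1, p2, p3, p4, grad = TRUE) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- rowCross(b1, b2); n2 <- rowCross(b2, b3)
  nb2 <- rowNorms(b2)
  phi <- atan2(rowSums(rowCross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
  if (!grad) return(list(phi = phi))
  n1sq <- pmax(rowSums(n1 * n1), 1e-12)
  n2sq <- pmax(rowSums(n2 * n2), 1e-12)
  g1 <- -n1 * (nb2 / n1sq)
  g4 <- n2 * (nb2 / n2sq)
  c1 <- rowSums(b1 * b2) / nb2^2
  c3 <- rowSums(b3 * b2) / nb2^2
  g2 <- -g1 * (1 + c1) + g4 * c3
  g3 <- -g4 * (1 + c3) + g1 * c1
  list(phi = phi, g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

wrapAngle <- function(x) atan2(sin(x), cos(x))

#' Internal coordinates of a conformation
#'
#' Bond lengths, Urey-Bradley 1-3 distances, valence angles, proper
#' dihedrals and improper torsions of a typed system at the given (or
#' stored) coordinates.
#'
#' @param system an "MDSystem" from [buildSystem()]
#' @param positions optional N x 3 coordinate matrix
#' @return list with components bonds, ub (Angstrom), angles (rad, [0, pi]),
#'   dihedrals, impropers (rad, (-pi, pi])
#' @export
internalCoordinates <- function(system, positions = NULL) {
  pos <- if (is.null(positions)) system$pos else positions
  out <- list(bonds = numeric(0), ub = numeric(0), angles = numeric(0),
              dihedrals = numeric(0), impropers = numeric(0))
  if (nrow(system$bonds))
    out$bonds <- rowNorms(pos[system$bonds[, 1], , drop = FALSE] -
                          pos[system$bonds[, 2], , drop = FALSE])
  if (nrow(system$ub))
    out$ub <- rowNorms(pos[system$ub[, 1], , drop = FALSE] -
                       pos[system$ub[, 2], , drop = FALSE])
  if (nrow(system$angles)) {
    u <- pos[system$angles[, 1], , drop = FALSE] -
      pos[system$angles[, 2], , drop = FALSE]
    v <- pos[system$angles[, 3], , drop = FALSE] -
      pos[system$angles[, 2], , drop = FALSE]
    cth <- rowSums(u * v) / (rowNorms(u) * rowNorms(v))
    out$angles <- acos(pmin(1, pmax(-1, cth)))
  }
  if (nrow(system$dihedrals))
    out$dihedrals <- torsionGeometry(
      pos[system$dihedrals[, 1], , drop = FALSE],
      pos[system$dihedrals[, 2], , drop = FALSE],
      pos[system$dihedrals[, 3], , drop = FALSE],
      pos[system$dihedrals[, 4], , drop = FALSE], grad = FALSE)$phi
  if (nrow(system$impropers))
    out$impropers <- torsionGeometry(
      pos[system$impropers[, 1], , drop = FALSE],
      pos[system$impropers[, 2], , drop = FALSE],
      pos[system$impropers[, 3], , drop = FALSE],
      pos[system$impropers[, 4], , drop = FALSE], grad = FALSE)$phi
  out
}

# all candidate nonbonded pairs (i < j, 1-2/1-3 excluded)
nonbondedCandidates <- function(system) {
  if (!is.null(system$nbCand)) return(system$nbCand)
  n <- system$n
  if (n < 2) return(list(ii = integer(0), jj = integer(0)))
  ii <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  keep <- !(pairKey(ii, jj, n) %in% system$exclKeys)
  list(ii = ii[keep], jj = jj[keep])
}

# Verlet-style neighbour list; memory-bounded for large systems
neighborList <- function(system, pos, cutoff, skin = 2.0) {
  n <- system$n
  if (n <= 3000) {
    cand <- nonbondedCandidates(system)
    d <- pos[cand$ii, , drop = FALSE] - pos[cand$jj, , drop = FALSE]
    keep <- rowSums(d * d) <= (cutoff + skin)^2
    return(list(ii = cand$ii[keep], jj = cand$jj[keep]))
  }
  rc2 <- (cutoff + skin)^2
  iiAll <- list(); jjAll <- list()
  blk <- 256L
  s2 <- rowSums(pos^2)
  for (b in seq(1L, n - 1L, by = blk)) {
    bi <- b:min(b + blk - 1L, n - 1L)
    d2 <- outer(s2[bi], s2, "+") - 2 * pos[bi, , drop = FALSE] %*% t(pos)
    hit <- which(d2 <= rc2, arr.ind = TRUE)
    ii <- bi[hit[, 1]]; jj <- hit[, 2]
    sel <- jj > ii
    ii <- ii[sel]; jj <- jj[sel]
    sel <- !(pairKey(ii, jj, n) %in% system$exclKeys)
    iiAll[[length(iiAll) + 1L]] <- ii[sel]
    jjAll[[length(jjAll) + 1L]] <- jj[sel]
  }
  list(ii = unlist(iiAll), jj = unlist(jjAll))
}

#' Potential energy and analytic forces
#'
#' Evaluates the full potential at the given coordinates and returns the
#' per-term energy breakdown, the per-atom force matrix (exact negative
#' gradient) and, optionally, the internal virial.
#'
#' @param system an "MDSystem" from [buildSystem()]
#' @param positions optional N x 3 coordinate matrix (defaults to the
#'   system's build coordinates)
#' @param cutoff nonbonded cutoff (Angstrom; `Inf` for none)
#' @param pairs optional precomputed neighbour list (list with ii, jj)
#' @param shift shift Coulomb and van der Waals terms to zero at the cutoff?
#' @param charmmDihedral use k(1 + cos(n phi)) instead of k(1 - cos(n phi))
#' @param virial also accumulate the internal virial (3 x 3, kcal/mol)
#' @return list with `energy` ("EnergyBreakdown"), `forces` (N x 3,
#'   kcal/mol/A) and `virial` (3 x 3 or NULL)
#' @export
totalEnergyAndForces <- function(system, positions = NULL, cutoff = 12,
                                 pairs = NULL, shift = TRUE,
                                 charmmDihedral = FALSE, virial = FALSE) {
  pos <- if (is.null(positions)) system$pos else positions
  n <- system$n
  F <- matrix(0, n, 3)
  eBond <- eAngle <- eUB <- eDih <- eImp <- eCoul <- eVdw <- 0

  if (nrow(system$bonds)) {
    i <- system$bonds[, 1]; j <- system$bonds[, 2]
    d <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
    r <- rowNorms(d)
    dr <- r - system$bondPar$r0
    eBond <- sum(system$bondPar$kb * dr^2)
    coef <- -2 * system$bondPar$kb * dr / r
    F <- addRows(F, i, d * coef)
    F <- addRows(F, j, -d * coef)
  }
  if (nrow(system$ub)) {
    i <- system$ub[, 1]; j <- system$ub[, 2]
    d <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
    r <- rowNorms(d)
    dr <- r - system$ubPar$rub0
    eUB <- sum(system$ubPar$kub * dr^2)
    coef <- -2 * system$ubPar$kub * dr / r
    F <- addRows(F, i, d * coef)
    F <- addRows(F, j, -d * coef)
  }
  if (nrow(system$angles)) {
    ai <- system$angles[, 1]; aj <- system$angles[, 2]; ak <- system$angles[, 3]
    u <- pos[ai, , drop = FALSE] - pos[aj, , drop = FALSE]
    v <- pos[ak, , drop = FALSE] - pos[aj, , drop = FALSE]
    nu <- rowNorms(u); nv <- rowNorms(v)
    cth <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    sth <- pmax(sqrt(1 - cth^2), 1e-8)
    dth <- th - system$anglePar$theta0
    eAngle <- sum(system$anglePar$ktheta * dth^2)
    dEdth <- 2 * system$anglePar$ktheta * dth
    gi <- (u * (cth / nu) - v / nv) / (nu * sth)
    gk <- (v * (cth / nv) - u / nu) / (nv * sth)
    F <- addRows(F, ai, -gi * dEdth)
    F <- addRows(F, ak, -gk * dEdth)
    F <- addRows(F, aj, (gi + gk) * dEdth)
  }
  if (nrow(system$dihedrals)) {
    tg <- torsionGeometry(pos[system$dihedrals[, 1], , drop = FALSE],
                          pos[system$dihedrals[, 2], , drop = FALSE],
                          pos[system$dihedrals[, 3], , drop = FALSE],
                          pos[system$dihedrals[, 4], , drop = FALSE])
    nphi <- system$dihPar$n * tg$phi
    if (charmmDihedral) {
      eDih <- sum(system$dihPar$kphi * (1 + cos(nphi)))
      dEdphi <- -system$dihPar$kphi * system$dihPar$n * sin(nphi)
    } else {
      eDih <- sum(system$dihPar$kphi * (1 - cos(nphi)))
      dEdphi <- system$dihPar$kphi * system$dihPar$n * sin(nphi)
    }
    F <- addRows(F, system$dihedrals[, 1], -tg$g1 * dEdphi)
    F <- addRows(F, system$dihedrals[, 2], -tg$g2 * dEdphi)
    F <- addRows(F, system$dihedrals[, 3], -tg$g3 * dEdphi)
    F <- addRows(F, system$dihedrals[, 4], -tg$g4 * dEdphi)
  }
  if (nrow(system$impropers)) {
    tg <- torsionGeometry(pos[system$impropers[, 1], , drop = FALSE],
                          pos[system$impropers[, 2], , drop = FALSE],
                          pos[system$impropers[, 3], , drop = FALSE],
                          pos[system$impropers[, 4], , drop = FALSE])
    dw <- wrapAngle(tg$phi - system$impPar$omega0)
    eImp <- sum(system$impPar$komega * dw^2)
    dEdw <- 2 * system$impPar$komega * dw
    F <- addRows(F, system$impropers[, 1], -tg$g1 * dEdw)
    F <- addRows(F, system$impropers[, 2], -tg$g2 * dEdw)
    F <- addRows(F, system$impropers[, 3], -tg$g3 * dEdw)
    F <- addRows(F, system$impropers[, 4], -tg$g4 * dEdw)
  }

  if (is.null(pairs)) pairs <- nonbondedCandidates(system)
  if (length(pairs$ii)) {
    d <- pos[pairs$ii, , drop = FALSE] - pos[pairs$jj, , drop = FALSE]
    r2 <- rowSums(d * d)
    keep <- if (is.finite(cutoff)) r2 <= cutoff^2 else rep(TRUE, length(r2))
    if (any(keep)) {
      ii <- pairs$ii[keep]; jj <- pairs$jj[keep]
      d <- d[keep, , drop = FALSE]
      r <- sqrt(r2[keep])
      if (any(r <= 0)) stop("nonbonded pair at zero distance")
      qq <- system$coulombConstant * system$charge[ii] * system$charge[jj]
      eps <- sqrt(system$epsilon[ii] * system$epsilon[jj])
      rmin <- system$rminHalf[ii] + system$rminHalf[jj]
      s6 <- (rmin / r)^6
      eC <- qq / r
      eV <- eps * (s6^2 - 2 * s6)
      if (shift && is.finite(cutoff)) {
        s6c <- (rmin / cutoff)^6
        eC <- eC - qq / cutoff
        eV <- eV - eps * (s6c^2 - 2 * s6c)
      }
      eCoul <- sum(eC)
      eVdw <- sum(eV)
      coef <- (qq / r + 12 * eps * s6 * (s6 - 1)) / (r * r)
      F <- addRows(F, ii, d * coef)
      F <- addRows(F, jj, -d * coef)
    }
  }

  W <- NULL
  if (virial) W <- crossprod(F, pos)   # sum_i F_i (x) r_i
  list(energy = newBreakdown(eBond, eAngle, eUB, eDih, eImp, eCoul, eVdw),
       forces = F, virial = W)
}

#' Bonded (intramolecular) energy breakdown
#'
#' @inheritParams totalEnergyAndForces
#' @return an "EnergyBreakdown" with zero nonbonded components
#' @export
intraEnergy <- function(system, positions = NULL, charmmDihedral = FALSE) {
  sys2 <- system
  sys2$nbCand <- list(ii = integer(0), jj = integer(0))
  totalEnergyAndForces(sys2, positions, cutoff = 0,
                       charmmDihedral = charmmDihedral)$energy
}

#' Nonbonded (intermolecular) energy breakdown
#'
#' Coulomb and 12-6 van der Waals sums over the non-excluded pairs.
#'
#' @inheritParams totalEnergyAndForces
#' @export
interEnergy <- function(system, positions = NULL, cutoff = Inf,
                        shift = FALSE) {
  sys2 <- system
  sys2$bonds <- matrix(integer(0), ncol = 2)
  sys2$ub <- matrix(integer(0), ncol = 2)
  sys2$angles <- matrix(integer(0), ncol = 3)
  sys2$dihedrals <- matrix(integer(0), ncol = 4)
  sys2$impropers <- matrix(integer(0), ncol = 4)
  totalEnergyAndForces(sys2, positions, cutoff = cutoff,
                       shift = shift)$energy
}

#' Pairwise van der Waals energy (CHARMM 12-6 form)
#'
#' `eps * ((rmin/r)^12 - 2 (rmin/r)^6)`: the minimum of the curve sits at
#' `r = rmin` with depth `-eps`.
#'
#' @param r pair distance(s), Angstrom (> 0)
#' @param epsilon well depth (kcal/mol)
#' @param rmin position of the minimum (Angstrom)
#' @export
vdwPairEnergy <- function(r, epsilon, rmin) {
  if (any(r <= 0)) stop("pair distance must be positive")
  s6 <- (rmin / r)^6
  epsilon * (s6^2 - 2 * s6)
}

#' Pairwise Coulomb energy
#'
#' @param r pair distance(s), Angstrom (> 0)
#' @param qi,qj charges (e)
#' @param k Coulomb constant (kcal A / (mol e^2))
#' @export
coulombPairEnergy <- function(r, qi, qj, k = COULOMB_KCAL) {
  if (any(r <= 0)) stop("pair distance must be positive")
  k * qi * qj / r
}

#' Single-torsion energy term
#'
#' @param phi dihedral angle(s), rad
#' @param kphi force constant (kcal/mol)
#' @param n multiplicity
#' @param charmm use the conventional `k (1 + cos(n phi - delta))` form
#' @param delta phase (rad), only used when `charmm = TRUE`
#' @export
dihedralTermEnergy <- function(phi, kphi, n, charmm = FALSE, delta = 0) {
  if (charmm) kphi * (1 + cos(n * phi - delta))
  else kphi * (1 - cos(n * phi))
}
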