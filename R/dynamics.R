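# Steered tensile molecular dynamics: velocity-Verlet/BAOAB integration,
# constant-velocity spring pulling, virial stress and stress-strain
# extraction.
#
# Internal units: Angstrom, fs, amu, kcal/mol.  Friction and pull speed are
# taken in the conventional 1/ps and A/ps and converted internally.

#' Construct a tensile pulling protocol
#'
#' @param fixedSelection,pulledSelection disjoint atom index vectors; the
#'   fixed atoms are frozen, the pulled atoms are tethered to anchors that
#'   advance along `pullAxis`
#' @param pullAxis load axis (defaults to +X); normalised internally
#' @param pullSpeed anchor speed, Angstrom/ps (0 = no pulling)
#' @param springConstant steering spring, kcal/mol/A^2
#' @param timestep fs
#' @param temperature Langevin target (K); 0 disables the thermostat (NVE)
#' @param friction Langevin friction, 1/ps; 0 disables the thermostat
#' @param nSteps number of integration steps
#' @param saveInterval frame stride (steps)
#' @param cutoff nonbonded cutoff (Angstrom)
#' @param seed RNG seed (initial velocities and thermostat noise)
#' @return a [TensileProtocol-class]
#' @export
tensileProtocol <- function(fixedSelection, pulledSelection,
                            pullAxis = c(1, 0, 0), pullSpeed = 1.0,
                            springConstant = 10, timestep = 1,
                            temperature = 300, friction = 1,
                            nSteps = 1000L, saveInterval = 10L,
                            cutoff = 12, seed = 42L) {
  new("TensileProtocol", pullAxis = normalize(as.numeric(pullAxis)),
      pullSpeed = pullSpeed,
      fixedSelection = as.integer(fixedSelection),
      pulledSelection = as.integer(pulledSelection),
      springConstant = springConstant, timestep = timestep,
      temperature = temperature, friction = friction,
      nSteps = as.integer(nSteps), saveInterval = as.integer(saveInterval),
      cutoff = cutoff, seed = as.integer(seed))
}

#' Minimise the potential energy
#'
#' Limited-memory BFGS on the free coordinates using the analytic gradient.
#'
#' @param system an "MDSystem"
#' @param positions optional starting coordinates
#' @param fixed atom indices to hold in place
#' @param maxit iteration budget
#' @param cutoff nonbonded cutoff (Angstrom)
#' @return list with `positions`, `energy` (final breakdown) and `value`
#' @export
minimizeEnergy <- function(system, positions = NULL, fixed = integer(0),
                           maxit = 300, cutoff = 12) {
  pos <- if (is.null(positions)) system$pos else positions
  free <- setdiff(seq_len(system$n), fixed)
  x0 <- as.numeric(pos[free, ])
  assemble <- function(x) {
    p <- pos
    p[free, ] <- matrix(x, ncol = 3)
    p
  }
  last <- list(x = NULL, ef = NULL)   # fn/gr come in pairs; evaluate once
  evalAt <- function(x) {
    if (is.null(last$x) || !identical(last$x, x))
      last <<- list(x = x, ef = totalEnergyAndForces(system, assemble(x),
                                                     cutoff = cutoff))
    last$ef
  }
  fn <- function(x) evalAt(x)$energy$total
  gr <- function(x) -as.numeric(evalAt(x)$forces[free, ])
  opt <- optim(x0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit))
  posOut <- assemble(opt$par)
  list(positions = posOut,
       energy = totalEnergyAndForces(system, posOut, cutoff = cutoff)$energy,
       value = opt$value, convergence = opt$convergence)
}

# Maxwell-Boltzmann velocities (A/fs)
maxwellVelocities <- function(system, temperature) {
  if (temperature <= 0) return(matrix(0, system$n, 3))
  sdv <- sqrt(BOLTZMANN_KCAL * temperature * ACCEL_UNIT / system$mass)
  matrix(rnorm(3 * system$n), ncol = 3) * sdv
}

kineticEnergy <- function(system, vel) {
  0.5 * KE_UNIT * sum(system$mass * rowSums(vel * vel))
}

instantaneousTemperature <- function(system, vel, nFrozen = 0L) {
  dof <- max(1L, 3L * (system$n - nFrozen))
  2 * kineticEnergy(system, vel) / (dof * BOLTZMANN_KCAL)
}

#' Run steered tensile molecular dynamics
#'
#' Velocity-Verlet integration (BAOAB splitting when the Langevin
#' thermostat is active).  Fixed atoms do not move; pulled atoms feel
#' harmonic springs towards anchors advancing at `pullSpeed` along the
#' pull axis.  Trajectories are bitwise reproducible for a fixed seed.
#'
#' @param model a [CompositeModel-class]/[TripleHelixModel-class], or a
#'   prebuilt "MDSystem"
#' @param params a [ForceFieldParameters-class] (ignored when `model` is
#'   already an "MDSystem")
#' @param protocol a [TensileProtocol-class]
#' @param minimize relax the structure before integrating?
#' @param minimizeSteps iteration budget for the initial minimisation
#' @param crossSection fixed reference cross-section (A^2) for the virial
#'   stress; NULL uses the instantaneous bounding-box cross-section
#' @param neighborEvery rebuild the Verlet neighbour list every this many
#'   steps
#' @return a [Trajectory-class]
#' @export
runTensile <- function(model, params = defaultForceField(), protocol,
                       minimize = TRUE, minimizeSteps = 200,
                       crossSection = NULL, neighborEvery = 20L) {
  system <- if (inherits(model, "MDSystem")) model
            else buildSystem(model, params)
  stopifnot(is(protocol, "TensileProtocol"))
  n <- system$n
  fixed <- protocol@fixedSelection
  pulled <- protocol@pulledSelection
  if (length(c(fixed, pulled)) &&
      (max(c(fixed, pulled)) > n || min(c(fixed, pulled)) < 1))
    stop("fixed/pulled selections out of range")
  axis <- protocol@pullAxis
  dt <- protocol@timestep
  kspr <- protocol@springConstant
  vpull <- protocol@pullSpeed * 1e-3       # A/fs
  gam <- protocol@friction * 1e-3          # 1/fs
  useThermostat <- protocol@temperature > 0 && gam > 0
  cutoff <- protocol@cutoff

  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(protocol@seed)

  pos <- system$pos
  if (minimize)
    pos <- minimizeEnergy(system, pos, fixed = fixed,
                          maxit = minimizeSteps, cutoff = cutoff)$positions
  vel <- maxwellVelocities(system, protocol@temperature)
  vel[fixed, ] <- 0

  anchors <- pos[pulled, , drop = FALSE]
  cFix <- colMeans(pos[fixed, , drop = FALSE])
  cPull <- colMeans(pos[pulled, , drop = FALSE])
  L0 <- abs(sum((cPull - cFix) * axis))
  if (!length(fixed) || !length(pulled) || L0 <= 0) L0 <- NA_real_

  invMass <- ACCEL_UNIT / system$mass
  c1 <- exp(-gam * dt)
  c2 <- sqrt(pmax(0, 1 - c1^2))
  sigv <- sqrt(BOLTZMANN_KCAL * protocol@temperature * ACCEL_UNIT /
               system$mass)

  pairs <- neighborList(system, pos, cutoff)
  evalForces <- function(p, t) {
    ef <- totalEnergyAndForces(system, p, cutoff = cutoff, pairs = pairs,
                               virial = TRUE)
    Fext <- matrix(0, n, 3)
    espr <- 0
    if (length(pulled) && kspr > 0) {
      target <- anchors + matrix(axis, nrow(anchors), 3, byrow = TRUE) *
        (vpull * t)
      dx <- p[pulled, , drop = FALSE] - target
      Fext[pulled, ] <- -kspr * dx
      espr <- 0.5 * kspr * sum(dx * dx)
    }
    list(energy = ef$energy, Fint = ef$forces, Fext = Fext,
         virial = ef$virial, espr = espr)
  }

  fe <- evalForces(pos, 0)
  nFrames <- protocol@nSteps %/% protocol@saveInterval + 1L
  times <- numeric(nFrames)
  positions <- velocities <- stress <- vector("list", nFrames)
  appliedStrain <- numeric(nFrames)
  eRows <- vector("list", nFrames)

  stressTensor <- function(p, W) {
    ext <- apply(p, 2, range)
    span <- pmax(ext[2, ] - ext[1, ], 1e-6)
    lenAxis <- abs(sum(span * abs(axis)))
    area <- if (is.null(crossSection)) prod(span) / lenAxis else crossSection
    V <- area * lenAxis
    -W / V * kcalPerMolA3ToMPa()
  }

  record <- function(slot, t, p, v, fe) {
    times[slot] <<- t
    positions[[slot]] <<- p
    velocities[[slot]] <<- v
    stress[[slot]] <<- stressTensor(p, fe$virial)
    appliedStrain[slot] <<- if (is.na(L0)) NA_real_ else vpull * t / L0
    e <- fe$energy
    eRows[[slot]] <<- data.frame(
      bond = e$bond, angle = e$angle, ub = e$ub, dihedral = e$dihedral,
      improper = e$improper, coulomb = e$coulomb, vdw = e$vdw,
      potential = e$total, spring = fe$espr,
      kinetic = kineticEnergy(system, v),
      temperature = instantaneousTemperature(system, v, length(fixed)))
  }
  record(1L, 0, pos, vel, fe)

  slot <- 1L
  for (step in seq_len(protocol@nSteps)) {
    t <- step * dt
    acc <- (fe$Fint + fe$Fext) * invMass
    vel <- vel + 0.5 * dt * acc
    vel[fixed, ] <- 0
    if (useThermostat) {
      pos <- pos + 0.5 * dt * vel
      vel <- c1 * vel + c2 * sigv * matrix(rnorm(3 * n), ncol = 3)
      vel[fixed, ] <- 0
      pos <- pos + 0.5 * dt * vel
    } else {
      pos <- pos + dt * vel
    }
    if (step %% neighborEvery == 0L)
      pairs <- neighborList(system, pos, cutoff)
    fe <- evalForces(pos, t)
    if (!is.finite(fe$energy$total) || abs(fe$energy$total) > 1e8)
      stop("integration failure at step ", step,
           ": energy diverged (", format(fe$energy$total), " kcal/mol)")
    acc <- (fe$Fint + fe$Fext) * invMass
    vel <- vel + 0.5 * dt * acc
    vel[fixed, ] <- 0
    if (step %% protocol@saveInterval == 0L) {
      slot <- slot + 1L
      record(slot, t, pos, vel, fe)
    }
  }

  new("Trajectory", times = times[seq_len(slot)],
      positions = positions[seq_len(slot)],
      velocities = velocities[seq_len(slot)],
      energies = do.call(rbind, eRows[seq_len(slot)]),
      stress = stress[seq_len(slot)],
      appliedStrain = appliedStrain[seq_len(slot)],
      protocol = protocol,
      metadata = list(n = n, L0 = L0, crossSection = crossSection,
                      minimized = minimize))
}

#' Virial stress tensor from pairwise interactions
#'
#' `sigma = -(1/V) sum_p r_p (x) f_p` over interacting pairs, where `r_p`
#' is the separation vector (on atom i, `ri - rj`) and `f_p` the force the
#' pair exerts on atom i; tension is positive.  An optional kinetic term
#' `(1/V) sum_i m_i v_i (x) v_i` can be added (off by default).
#'
#' @param pairVectors P x 3 matrix of pair separation vectors (Angstrom)
#' @param pairForces P x 3 matrix of pair forces (kcal/mol/A)
#' @param volume reference volume (A^3, > 0)
#' @param masses,velocities optional per-atom masses (amu) and velocities
#'   (A/fs) for the kinetic contribution
#' @return 3 x 3 symmetric stress tensor in MPa
#' @export
virialStress <- function(pairVectors, pairForces, volume,
                         masses = NULL, velocities = NULL) {
  if (!is.numeric(volume) || length(volume) != 1 || volume <= 0)
    stop("reference volume must be positive")
  pairVectors <- matrix(pairVectors, ncol = 3)
  pairForces <- matrix(pairForces, ncol = 3)
  W <- -crossprod(pairVectors, pairForces)
  W <- (W + t(W)) / 2
  if (!is.null(masses) && !is.null(velocities)) {
    velocities <- matrix(velocities, ncol = 3)
    W <- W + KE_UNIT * crossprod(velocities * masses, velocities)
  }
  W / volume * kcalPerMolA3ToMPa()
}

#' Centred moving average
#'
#' Window `w` averages offsets `(0:(w-1)) - floor((w-1)/2)` around each
#' sample; only positions where the full window fits are returned, so the
#' output is shorter than the input by `w - 1` samples (`w = 1` is the
#' identity).
#'
#' @param x numeric vector
#' @param window positive integer, at most `length(x)`
#' @return list with `values` and `index` (positions into `x`)
#' @export
movingAverage <- function(x, window) {
  if (window < 1 || window != as.integer(window))
    stop("window must be a positive integer")
  if (window > length(x))
    stop("window (", window, ") exceeds series length (", length(x), ")")
  w <- as.integer(window)
  if (w == 1L) return(list(values = x, index = seq_along(x)))
  off <- (0:(w - 1L)) - (w - 1L) %/% 2L
  idx <- (1L - min(off)):(length(x) - max(off))
  vals <- rowMeans(vapply(off, function(o) x[idx + o],
                          numeric(length(idx))))
  list(values = vals, index = idx)
}

#' Reduce a trajectory to a stress-strain curve
#'
#' Stress is the pull-axis normal component of the per-frame virial tensor,
#' smoothed by a centred moving average; engineering strain is measured
#' from the axis-projected separation of the fixed- and pulled-selection
#' centroids, relative to the first frame.
#'
#' @param traj a [Trajectory-class] from [runTensile()]
#' @param window moving-average window (frames), >= 1
#' @return a [StressStrainCurve-class]
#' @export
extractStressStrain <- function(traj, window = 1L) {
  stopifnot(is(traj, "Trajectory"))
  nf <- length(traj@times)
  if (window > nf)
    stop("window (", window, ") exceeds the ", nf, " available frames")
  prot <- traj@protocol
  axis <- prot@pullAxis
  fixed <- prot@fixedSelection
  pulled <- prot@pulledSelection
  if (!length(fixed) || !length(pulled))
    stop("trajectory protocol lacks fixed/pulled selections")
  sepOf <- function(p) abs(sum((colMeans(p[pulled, , drop = FALSE]) -
                                colMeans(p[fixed, , drop = FALSE])) * axis))
  L <- vapply(traj@positions, sepOf, numeric(1))
  strainRaw <- (L - L[1]) / L[1]
  stressRaw <- vapply(traj@stress, function(S)
    as.numeric(t(axis) %*% S %*% axis), numeric(1))
  sm <- movingAverage(stressRaw, window)
  st <- movingAverage(strainRaw, window)
  strain <- st$values
  nFixed <- sum(diff(strain) < 0)
  strain <- cummax(strain)   # guard against thermal jitter of the centroids
  new("StressStrainCurve", strain = strain, stress = sm$values,
      rawStress = stressRaw[sm$index], smoothingWindow = as.integer(window),
      metadata = c(traj@metadata,
                   list(seed = prot@seed, window = as.integer(window),
                        monotonicityClamped = nFixed)))
}
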