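# Integrator correctness, steering, virial stress and curve extraction.

# minimal two-atom harmonic system for closed-form checks
dimerSystem <- function(kb = 50, r0 = 1.5, mass = 12) {
  structure(list(
    atoms = data.frame(chain = c("A", "A")), n = 2L,
    pos = rbind(c(0, 0, 0), c(r0, 0, 0)),
    mass = rep(mass, 2), charge = c(0, 0),
    epsilon = c(0, 0), rminHalf = c(1, 1),
    bonds = rbind(c(1L, 2L)), bondPar = list(kb = kb, r0 = r0),
    angles = matrix(integer(0), ncol = 3),
    anglePar = list(ktheta = numeric(0), theta0 = numeric(0),
                    kub = numeric(0), rub0 = numeric(0)),
    ub = matrix(integer(0), ncol = 2),
    ubPar = list(kub = numeric(0), rub0 = numeric(0)),
    dihedrals = matrix(integer(0), ncol = 4),
    dihPar = list(kphi = numeric(0), n = integer(0)),
    impropers = matrix(integer(0), ncol = 4),
    impPar = list(komega = numeric(0), omega0 = numeric(0)),
    exclKeys = pairKeyOracle(1L, 2L, 2L),
    coulombConstant = 332.0637), class = "MDSystem")
}

test_that("a quasi-statically pulled harmonic dimer follows Hooke's law", {
  kb <- 50; r0 <- 1.5
  sys <- dimerSystem(kb, r0)
  # stiff steering spring, slow pull, strong friction: quasi-static
  prot <- tensileProtocol(fixedSelection = 1L, pulledSelection = 2L,
                          pullSpeed = 1, springConstant = 400,
                          timestep = 0.5, temperature = 0, friction = 20,
                          nSteps = 8000, saveInterval = 200, seed = 1)
  # cold Langevin acts as an overdamped relaxer towards the moving anchor
  traj <- runTensile(sys, protocol = prot, minimize = FALSE)
  # at each late frame the bond tension balances the spring force:
  # kbond extension follows the analytic series solution; compare the
  # realised bond force with 2 kb (r - r0) from the realised geometry
  late <- tail(seq_along(traj@times), 10)
  for (f in late) {
    p <- traj@positions[[f]]
    r <- sqrt(sum((p[2, ] - p[1, ])^2))
    anchor <- r0 + 1e-3 * traj@times[f]
    springForce <- 400 * (anchor - r)
    bondForce <- 2 * kb * (r - r0)
    expect_equal(bondForce, springForce, tolerance = 0.02)
  }
})

test_that("NVE runs conserve energy with dt^2 scaling", {
  sys <- tinySystem()
  drift <- function(dt, steps) {
    prot <- tensileProtocol(integer(0), integer(0), pullSpeed = 0,
                            springConstant = 0, timestep = dt,
                            temperature = 0, friction = 0,
                            nSteps = steps, saveInterval = steps / 10,
                            seed = 3)
    sys2 <- sys
    mn <- minimizeEnergy(sys, maxit = 200)
    sys2$pos <- mn$positions +
      matrix(rnorm(3 * sys$n, sd = 0.01), ncol = 3)
    traj <- runTensile(sys2, protocol = prot, minimize = FALSE)
    E <- traj@energies$potential + traj@energies$kinetic
    list(drift = abs(E[length(E)] - E[1]) / abs(E[1]),
         fluct = sd(E) / abs(mean(E)))
  }
  set.seed(5)
  d1 <- drift(0.25, 2000)
  set.seed(5)
  d2 <- drift(1.0, 500)     # same simulated time, 4x the step
  expect_lt(d1$drift, 1e-4)
  # energy error grows ~ dt^2: the coarse run fluctuates much more
  expect_gt(d2$fluct / max(d1$fluct, 1e-12), 4)
})

test_that("zero-temperature, zero-pull dynamics leave a minimum stationary", {
  sys <- tinySystem()
  mn <- minimizeEnergy(sys, maxit = 600)
  sys2 <- sys; sys2$pos <- mn$positions
  prot <- tensileProtocol(integer(0), integer(0), pullSpeed = 0,
                          springConstant = 0, timestep = 0.5,
                          temperature = 0, friction = 0, nSteps = 200,
                          saveInterval = 200, seed = 1)
  traj <- runTensile(sys2, protocol = prot, minimize = FALSE)
  disp <- sqrt(max(rowSums((traj@positions[[2]] - mn$positions)^2)))
  expect_lt(disp, 0.05)
})

test_that("trajectories are bitwise reproducible under a fixed seed", {
  sys <- tinySystem()
  prot <- tensileProtocol(1:10, (sys$n - 9):sys$n, pullSpeed = 2,
                          springConstant = 10, timestep = 1,
                          temperature = 150, friction = 2, nSteps = 200,
                          saveInterval = 20, seed = 42)
  t1 <- runTensile(sys, protocol = prot, minimize = TRUE,
                   minimizeSteps = 50)
  t2 <- runTensile(sys, protocol = prot, minimize = TRUE,
                   minimizeSteps = 50)
  expect_identical(t1@positions, t2@positions)
  expect_identical(t1@velocities, t2@velocities)
  t3 <- runTensile(sys, protocol = tensileProtocol(
    1:10, (sys$n - 9):sys$n, pullSpeed = 2, springConstant = 10,
    timestep = 1, temperature = 150, friction = 2, nSteps = 200,
    saveInterval = 20, seed = 43), minimize = TRUE, minimizeSteps = 50)
  expect_false(identical(t1@positions, t3@positions))
})

test_that("the Langevin thermostat holds the setpoint within 15%", {
  sys <- tinySystem()
  prot <- tensileProtocol(integer(0), integer(0), pullSpeed = 0,
                          springConstant = 0, timestep = 0.5,
                          temperature = 200, friction = 5,
                          nSteps = 3000, saveInterval = 30, seed = 2)
  traj <- runTensile(sys, protocol = prot, minimize = TRUE,
                     minimizeSteps = 200)
  tail_T <- mean(tail(traj@energies$temperature, 40))
  expect_lt(abs(tail_T - 200) / 200, 0.15)
})

test_that("integration failure is reported with the offending step", {
  sys <- dimerSystem()
  sys$pos[2, 1] <- 1e4          # absurd stretch: colossal forces
  prot <- tensileProtocol(integer(0), integer(0), pullSpeed = 0,
                          springConstant = 0, timestep = 100,
                          temperature = 0, friction = 0, nSteps = 50,
                          saveInterval = 10, seed = 1)
  expect_error(runTensile(sys, protocol = prot, minimize = FALSE),
               "integration failure at step")
})

test_that("virial stress follows the pairwise dyadic definition", {
  # no interactions: zero tensor
  expect_equal(virialStress(matrix(0, 0, 3), matrix(0, 0, 3), 100),
               matrix(0, 3, 3))
  # single stretched bond along x: sigma_xx = f r / V (tension positive)
  f <- 3; r <- 1.8; V <- 250
  rij <- matrix(c(r, 0, 0), 1)        # r1 - r2
  fij <- matrix(c(-f, 0, 0), 1)       # force on atom 1, pulled towards 2
  S <- virialStress(rij, fij, V)
  conv <- kcalPerMolA3ToMPa()
  expect_equal(S[1, 1], f * r / V * conv, tolerance = 1e-12)
  expect_equal(S[2, 2], 0); expect_equal(S[3, 3], 0)
  expect_equal(max(abs(S - t(S))), 0)
  # rotating the pair 90 degrees about z moves sigma_xx to sigma_yy
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  S2 <- virialStress(rij %*% t(R), fij %*% t(R), V)
  expect_equal(S2[2, 2], S[1, 1], tolerance = 1e-12)
  expect_equal(S2[1, 1], 0, tolerance = 1e-12)
  expect_error(virialStress(rij, fij, 0), "volume")
})

test_that("the stress unit conversion matches an independent unit chain", {
  # 1 kcal/mol/A^3 -> MPa via J, m and the Avogadro number, assembled in a
  # different order than the package constant
  indep <- (4184 / 1e-30) / 6.02214076e23 * 1e-6
  expect_equal(kcalPerMolA3ToMPa(), indep, tolerance = 1e-12)
  expect_equal(kcalPerMolA3ToMPa(), 6947.7, tolerance = 1e-4)
})

test_that("moving averages follow the centred-window convention", {
  x <- c(5, 5, 5, 5, 5, 5)
  expect_equal(movingAverage(x, 3)$values, rep(5, 4))
  expect_identical(movingAverage(x, 1)$values, x)
  # linear ramp: interior unchanged, ends shortened
  N <- 20; ramp <- seq(1, N)
  for (w in c(3, 5, 7)) {
    sm <- movingAverage(ramp, w)
    h <- (w - 1) / 2
    expect_equal(sm$index, (h + 1):(N - h))
    expect_equal(sm$values, ramp[sm$index])   # direct convolution oracle
  }
  # explicit convolution oracle on a random series
  set.seed(8)
  y <- rnorm(15)
  sm <- movingAverage(y, 5)
  oracle <- vapply(3:13, function(i) mean(y[(i - 2):(i + 2)]), numeric(1))
  expect_equal(sm$values, oracle, tolerance = 1e-12)
  expect_error(movingAverage(y, 16), "exceeds")
  expect_error(movingAverage(y, 0), "positive")
})

test_that("stress-strain extraction smooths stress and measures strain", {
  sys <- tinySystem()
  sel <- helixSelections(sys)
  prot <- tensileProtocol(sel$fixed, sel$pulled, pullSpeed = 4,
                          springConstant = 20, timestep = 1,
                          temperature = 100, friction = 5, nSteps = 600,
                          saveInterval = 10, seed = 9)
  traj <- runTensile(sys, protocol = prot, minimize = TRUE,
                     minimizeSteps = 200)
  expect_error(extractStressStrain(traj, window = 1000), "exceeds")
  cur1 <- extractStressStrain(traj, window = 1)
  cur5 <- extractStressStrain(traj, window = 5)
  expect_s4_class(cur5, "StressStrainCurve")
  expect_true(all(diff(strainOf(cur5)) >= 0))
  expect_gt(max(strainOf(cur5)), 0.01)
  # window 1 is the identity on the stress series
  expect_equal(stressOf(cur1), stressOf(cur1, raw = TRUE))
  # smoothing shrinks the series per the centred convention
  expect_equal(length(stressOf(cur5)), length(stressOf(cur1)) - 4)
})

test_that("smoothed toy-composite pulls rise monotonically to their maximum", {
  sys <- toySystem()
  sel <- helixSelections(sys)
  ok <- 0; nrep <- 5
  for (seed in seq_len(nrep)) {
    prot <- tensileProtocol(sel$fixed, sel$pulled, pullSpeed = 8,
                            springConstant = 20, timestep = 1,
                            temperature = 100, friction = 5,
                            nSteps = 1200, saveInterval = 20, seed = seed)
    traj <- runTensile(sys, protocol = prot, minimize = TRUE,
                       minimizeSteps = 250)
    cur <- extractStressStrain(traj, window = 21)
    s <- stressOf(cur)
    upTo <- which.max(s)
    mono <- if (upTo > 2) all(diff(s[1:upTo]) > -1e-6) else TRUE
    ok <- ok + mono
  }
  expect_gte(ok / nrep, 0.9)
})
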