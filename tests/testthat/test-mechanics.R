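# Curve reduction, constitutive fits and the published-equation evaluators.

test_that("UTS takes the curve maximum with the earliest-strain tie rule", {
  eps <- seq(0, 0.4, by = 0.01)
  inc <- stressStrainCurve(eps, 100 * eps)
  expect_equal(ultimateTensileStrength(inc)$uts, 40)
  expect_equal(ultimateTensileStrength(inc)$strain, 0.4)

  # dense-grid scan of the un-hydrated 0-degree polynomial
  poly <- referenceConstitutive(0, "unhydrated")
  grid <- seq(0, 0.40, by = 1e-4)
  cur <- stressStrainCurve(grid, evaluateConstitutive(poly, grid))
  got <- ultimateTensileStrength(cur)
  oracle <- hornerOracle(poly@coefficients, grid)
  expect_equal(got$uts, max(oracle), tolerance = 1e-12)
  expect_identical(got$strain, grid[which.max(oracle)])

  tie <- stressStrainCurve(c(0, 0.1, 0.2, 0.3), c(1, 7, 7, 2))
  expect_equal(ultimateTensileStrength(tie)$strain, 0.1)
  expect_error(ultimateTensileStrength(stressStrainCurve(numeric(0),
                                                         numeric(0))),
               "empty")
})

test_that("toughness integrates the curve and is additive over intervals", {
  eps <- seq(0, 0.3, length.out = 400)
  expect_equal(toughness(stressStrainCurve(eps, rep(0, 400))), 0)
  k <- 250
  expect_equal(toughness(stressStrainCurve(eps, k * eps)),
               k * 0.3^2 / 2, tolerance = 1e-5)
  # fine-grid Riemann oracle on a wiggly curve
  f <- function(e) 40 * sin(20 * e) + 120 * e
  tz <- toughness(stressStrainCurve(eps, f(eps)))
  fine <- seq(0, 0.3, length.out = 2e5)
  riemann <- sum(f(head(fine, -1) / 2 + fine[-1] / 2)) * diff(fine)[1]
  expect_equal(tz, riemann, tolerance = 1e-5)
  # superadditivity over a split
  cut <- 200
  t1 <- toughness(stressStrainCurve(eps[1:cut], f(eps[1:cut])))
  t2 <- toughness(stressStrainCurve(eps[cut:400], f(eps[cut:400])))
  expect_equal(t1 + t2, tz, tolerance = 1e-10)
  expect_error(toughness(stressStrainCurve(c(0, 0.2, 0.1), c(1, 2, 3))),
               "non-decreasing")
})

test_that("elastic modulus recovers known slopes", {
  eps <- seq(0, 0.1, length.out = 200)
  cur <- stressStrainCurve(eps, 2000 * eps)   # 2 GPa
  expect_equal(elasticModulus(cur, c(0, 0.05)), 2, tolerance = 1e-12)
  expect_equal(elasticModulus(cur, c(0.02, 0.09)), 2, tolerance = 1e-12)
  expect_error(elasticModulus(stressStrainCurve(c(0.2, 0.3), c(1, 2)),
                              c(0, 0.05)), "degenerate")
  # recovery under noise: slope within 5% in >= 95% of 100 seeds
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    y <- 2000 * eps + rnorm(200, 0, 1)
    E <- elasticModulus(stressStrainCurve(eps, y), c(0, 0.1))
    hits <- hits + (abs(E - 2) / 2 < 0.05)
  }
  expect_gte(hits, 95)
})

test_that("constitutive fits agree with the normal-equations oracle", {
  poly <- referenceConstitutive(30, "hydrated")   # degree 4
  eps <- seq(0, 0.4, length.out = 100)
  clean <- stressStrainCurve(eps, evaluateConstitutive(poly, eps),
                             metadata = list(orientation = 30,
                                             hydration = "hydrated"))
  fit <- fitConstitutivePolynomial(clean, 4)
  expect_equal(coef(fit), poly@coefficients, tolerance = 1e-6)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  expect_equal(fit@orientation, 30)

  set.seed(21)
  noisy <- stressStrainCurve(eps, evaluateConstitutive(poly, eps) +
                             rnorm(100, 0, 5))
  fitN <- fitConstitutivePolynomial(noisy, 4, orientation = 30,
                                    hydration = "hydrated")
  expect_lt(fitN@rSquared, 1)
  oracle <- normalEquationsPoly(strainOf(noisy), stressOf(noisy), 4)
  expect_equal(coef(fitN), oracle, tolerance = 1e-9)

  short <- stressStrainCurve(seq(0, 1, length.out = 5), rnorm(5))
  expect_error(fitConstitutivePolynomial(short, 6), "samples")
  # round trip: evaluating the fit reproduces the generator polynomial
  expect_equal(evaluateConstitutive(fit, eps),
               evaluateConstitutive(poly, eps), tolerance = 1e-6)
})

test_that("published constitutive constants are evaluated exactly at zero strain", {
  expect_equal(evaluateConstitutive(
    referenceConstitutive(0, "unhydrated"), 0), -3.508)
  expect_equal(evaluateConstitutive(
    referenceConstitutive(45, "hydrated"), 0), -0.4357)
  for (p in referenceConstitutive())
    expect_identical(evaluateConstitutive(p, 0),
                     p@coefficients[length(p@coefficients)])
  expect_error(referenceConstitutive(17), "no reference")
})

test_that("orientation lines reproduce the published E-theta coefficients", {
  grid <- referenceModulusGrid()
  # least squares on the Ca columns matches the printed OH-surface lines
  # and vice versa (documented label swap)
  caUn <- fitOrientationLine(grid, "unhydrated", "Ca")
  expect_equal(caUn$slope, -0.0227, tolerance = 0.005)
  expect_equal(caUn$intercept, 3.2177, tolerance = 0.001)
  ohUn <- fitOrientationLine(grid, "unhydrated", "OH")
  expect_equal(ohUn$slope, -0.023, tolerance = 0.005)
  expect_equal(ohUn$intercept, 3.2159, tolerance = 0.001)
  # normal-equations oracle
  d <- gridData(grid)
  sel <- d$hydration == "hydrated" & d$surface == "OH"
  X <- cbind(1, d$orientation[sel])
  beta <- solve(t(X) %*% X, t(X) %*% d$E[sel])[, 1]
  ohHy <- fitOrientationLine(grid, "hydrated", "OH")
  expect_equal(ohHy$intercept, beta[1], tolerance = 1e-9)
  expect_equal(ohHy$slope, beta[2], tolerance = 1e-9)
  # two-point degenerate-slope sanity
  tiny <- new("ModulusGrid",
              data = data.frame(orientation = c(0, 90),
                                hydration = "unhydrated", surface = "Ca",
                                E = c(1, 1)),
              observations = data.frame())
  line <- fitOrientationLine(tiny, "unhydrated", "Ca")
  expect_equal(line$slope, 0)
  expect_equal(line$intercept, 1)
  expect_error(fitOrientationLine(grid, "unhydrated", "Mg"), "no grid")
})

test_that("the UTS prediction cubic evaluates as printed", {
  # centred terms vanish at the knot
  knot <- 40.83332
  expect_equal(evaluateUTSPrediction(knot),
               100.12452 - 1.1096903 * knot, tolerance = 1e-9)
  # term-by-term arithmetic oracle at 0
  oracle0 <- 100.12452 - 1.1096903 * 0 +
    0.0134039 * (0 - 40.83332)^2 + 0.0002412 * (0 - 40.83333)^3
  expect_equal(evaluateUTSPrediction(0), oracle0, tolerance = 1e-12)
  # strength is highest longitudinally
  expect_gt(evaluateUTSPrediction(0), evaluateUTSPrediction(90))
  expect_error(evaluateUTSPrediction(120), "theta")
})

test_that("the bivariate stress surface sums its 20 printed monomials", {
  surf <- referenceRegressionSurface()
  expect_equal(nrow(surf$terms), 20L)
  expect_equal(evaluateRegressionSurface(surf, 0, 0), 1.936)
  # independent evaluation order
  set.seed(2)
  for (k in 1:10) {
    th <- runif(1, 0, 90); ep <- runif(1, 0, 0.4)
    direct <- sum(surf$terms$coef * th^surf$terms$i * ep^surf$terms$j)
    expect_equal(evaluateRegressionSurface(surf, th, ep), direct,
                 tolerance = 1e-12)
  }
  # theta = 0 collapses to the strain-only sub-polynomial
  ep <- 0.21
  sub <- surf$terms[surf$terms$i == 0, ]
  expect_equal(evaluateRegressionSurface(surf, 0, ep),
               sum(sub$coef * ep^sub$j), tolerance = 1e-12)
})

test_that("surface refits recover known coefficients and noise scale", {
  surf <- referenceRegressionSurface()
  set.seed(31)
  design <- expand.grid(theta = c(0, 20, 30, 45, 60, 90),
                        eps = seq(0.01, 0.35, length.out = 12))
  truth <- evaluateRegressionSurface(surf, design$theta, design$eps)
  clean <- data.frame(design, stress = truth)
  fit <- fitRegressionSurface(clean)
  expect_equal(fit$terms$coef, surf$terms$coef, tolerance = 1e-6)
  expect_equal(fit$metrics$rSquared, 1, tolerance = 1e-9)

  # RMSE estimates the injected noise SD (sigma = 8) within 15% over seeds
  rmses <- vapply(1:50, function(seed) {
    set.seed(seed)
    noisy <- data.frame(design, stress = truth + rnorm(nrow(design), 0, 8))
    fitRegressionSurface(noisy)$metrics$rmse
  }, numeric(1))
  expect_lt(abs(mean(rmses) - 8) / 8, 0.15)

  expect_error(fitRegressionSurface(clean[1:10, ]), "at least")
  expect_error(fitRegressionSurface(
    data.frame(theta = rep(c(0, 20), 15), eps = runif(30),
               stress = rnorm(30))), ">= 3 orientations")
})

test_that("sensitivity grids report per-orientation maxima", {
  polys <- referenceConstitutive(hydration = "unhydrated")
  sg <- sensitivityGrid(polys)
  expect_equal(sg$theta, c(0, 20, 30, 45, 60, 90))
  # longitudinal loading carries the global maximum, above perpendicular
  expect_equal(which.max(sg$maxStress), 1L)
  expect_gt(sg$maxStress[1], sg$maxStress[6])
  # single-point grids return the evaluated value itself
  one <- sensitivityGrid(polys, thetaGrid = 0, epsGrid = 0.1)
  expect_equal(one$maxStress,
               evaluateConstitutive(referenceConstitutive(0, "unhydrated"),
                                    0.1))
  # ten-fold grid refinement moves each maximum by < 0.5%
  fine <- sensitivityGrid(polys, epsGrid = seq(0, 0.40, by = 1e-5))
  expect_lt(max(abs(fine$maxStress - sg$maxStress) /
                pmax(abs(fine$maxStress), 1e-9)), 0.005)
  expect_error(sensitivityGrid(polys, thetaGrid = numeric(0)), "non-empty")
})
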