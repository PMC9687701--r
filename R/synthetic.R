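# Synthetic data with known ground truth: stress-strain curve families
# around the reference constitutive polynomials, modulus grids around the
# linear orientation laws, and miniature composites for fast dynamics
# smoke tests.

withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(as.integer(seed))
  expr
}

#' Noise level matching a target R-squared
#'
#' For homoscedastic Gaussian noise around a deterministic signal, the
#' expected coefficient of determination of a correctly-specified fit is
#' `R^2 = var(signal) / (var(signal) + sd^2)`; inverting gives the noise
#' SD that reproduces a stated R^2:
#' `sd = sd(signal) * sqrt((1 - R^2)/R^2)`.
#'
#' @param poly a [ConstitutivePolynomial-class] (or coefficient vector)
#' @param targetR2 desired R^2 in (0, 1)
#' @param strainRange strain interval of the design
#' @param nPoints design size used to evaluate the signal SD
#' @return noise standard deviation (MPa)
#' @export
noiseSdForTargetR2 <- function(poly, targetR2, strainRange = c(0, 0.40),
                               nPoints = 500L) {
  if (targetR2 <= 0 || targetR2 >= 1) stop("targetR2 must lie in (0, 1)")
  eps <- seq(strainRange[1], strainRange[2], length.out = nPoints)
  sig <- evaluateConstitutive(poly, eps)
  sd(sig) * sqrt((1 - targetR2) / targetR2)
}

#' Generate synthetic stress-strain curve families
#'
#' Samples `sigma(eps) = P(eps) + N(0, sd^2)` i.i.d. on a uniform strain
#' grid, with `P` the reference constitutive polynomial of each requested
#' condition.  By default the noise SD of each condition is calibrated to
#' that condition's published R^2 via [noiseSdForTargetR2()], so refitting
#' the correct degree recovers R^2 values bracketing the published ones.
#'
#' @param orientations subset of c(0, 20, 30, 45, 60, 90), degrees
#' @param hydration "unhydrated" or "hydrated"
#' @param noiseSd noise SD in MPa; NULL calibrates per condition
#' @param nPoints samples per curve
#' @param strainRange strain interval
#' @param replicates curves per condition
#' @param seed RNG seed; output is reproducible
#' @return list of [StressStrainCurve-class]; each carries its ground
#'   truth (coefficients, noise SD, condition) in `metadata`
#' @export
generateStressStrain <- function(orientations = REF_ORIENTATIONS,
                                 hydration = "unhydrated", noiseSd = NULL,
                                 nPoints = 500L, strainRange = c(0, 0.40),
                                 replicates = 1L, seed = 1L) {
  bad <- setdiff(orientations, REF_ORIENTATIONS)
  if (length(bad))
    stop("no reference constitutive polynomial for orientation(s) ",
         paste(bad, collapse = ", "))
  withSeed(seed, {
    out <- list()
    eps <- seq(strainRange[1], strainRange[2], length.out = nPoints)
    for (th in orientations) {
      poly <- referenceConstitutive(th, hydration)
      sdN <- if (is.null(noiseSd))
        noiseSdForTargetR2(poly, poly@rSquared, strainRange, nPoints)
      else noiseSd
      mu <- evaluateConstitutive(poly, eps)
      for (r in seq_len(replicates)) {
        y <- mu + if (sdN > 0) rnorm(nPoints, 0, sdN) else 0
        out[[length(out) + 1L]] <- stressStrainCurve(
          eps, y, metadata = list(
            orientation = th, hydration = hydration, replicate = r,
            seed = seed, noiseSd = sdN,
            truthCoefficients = poly@coefficients,
            truthR2 = poly@rSquared))
      }
    }
    out
  })
}

#' Generate a synthetic modulus grid
#'
#' Draws `E(theta) = slope * theta + intercept + N(0, sd^2)` per cell
#' (and replicate) around the linear modulus-orientation laws.  With the
#' default coefficients the un-hydrated intercepts exceed the hydrated
#' ones, reproducing the stiffening effect of water loss.
#'
#' @param lines data.frame with surface, hydration, slope, intercept
#'   (defaults to [referenceOrientationLines()])
#' @param orientations orientation angles (degrees)
#' @param noiseSd noise SD in GPa (0.15 reflects the scatter of the
#'   reference grid about its lines)
#' @param replicates observations per cell; the grid stores cell means
#' @param seed RNG seed
#' @return a [ModulusGrid-class]; `@observations` holds the replicate-level
#'   draws with their condition labels
#' @export
generateModulusGrid <- function(lines = referenceOrientationLines(),
                                orientations = REF_ORIENTATIONS,
                                noiseSd = 0.15, replicates = 1L, seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  withSeed(seed, {
    obs <- list()
    for (r in seq_len(nrow(lines))) {
      mu <- lines$slope[r] * orientations + lines$intercept[r]
      for (rep in seq_len(replicates)) {
        e <- mu + if (noiseSd > 0) rnorm(length(mu), 0, noiseSd) else 0
        obs[[length(obs) + 1L]] <- data.frame(
          orientation = orientations, hydration = lines$hydration[r],
          surface = lines$surface[r], E = pmax(e, 1e-6), replicate = rep,
          stringsAsFactors = FALSE)
      }
    }
    obs <- do.call(rbind, obs)
    cellMean <- stats::aggregate(E ~ orientation + hydration + surface,
                                 data = obs, FUN = mean)
    new("ModulusGrid", data = cellMean, observations = obs)
  })
}

#' Generate a miniature composite model for dynamics smoke tests
#'
#' A one-repeat triple helix over a small mineral slab: a valid
#' [CompositeModel-class] of a few hundred atoms, small enough for
#' sub-minute steered-MD runs.
#'
#' @param nRepeats tandem repeats per chain
#' @param replication slab replication counts
#' @param orientation fibril orientation (degrees)
#' @param hydrated add a thin hydration shell?
#' @param surface mineral termination ("Ca" or "OH")
#' @param shellThickness hydration shell (Angstrom)
#' @param gap helix-slab gap (Angstrom)
#' @param seed seed for water placement
#' @return a [CompositeModel-class]
#' @export
generateToyComposite <- function(nRepeats = 1L, replication = c(2, 1, 1),
                                 orientation = 0, hydrated = FALSE,
                                 surface = "Ca", shellThickness = 3,
                                 gap = 3, seed = 42L) {
  helix <- buildCollagenHelix(nRepeats = nRepeats)
  slab <- replicateCrystal(haUnitCell(), replication[1], replication[2],
                           replication[3])
  slab <- selectSurface(slab, surface)
  model <- assembleComposite(helix, slab, orientation, gap = gap)
  if (hydrated) model <- hydrate(model, shellThickness, seed = seed)
  model
}
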