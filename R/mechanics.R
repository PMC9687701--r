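# Reduction of stress-strain curves to mechanical properties and fitted
# constitutive models.  Units: stress MPa, modulus GPa, strain
# dimensionless, orientation degrees.

#' Construct a stress-strain curve from samples
#'
#' @param strain non-decreasing engineering strain samples
#' @param stress stress samples (MPa), same length
#' @param smoothingWindow window already applied to `stress` (1 = raw)
#' @param metadata named list of condition labels
#' @return a [StressStrainCurve-class]
#' @export
stressStrainCurve <- function(strain, stress, smoothingWindow = 1L,
                              metadata = list()) {
  new("StressStrainCurve", strain = as.numeric(strain),
      stress = as.numeric(stress), rawStress = as.numeric(stress),
      smoothingWindow = as.integer(smoothingWindow), metadata = metadata)
}

#' Ultimate tensile strength of a curve
#'
#' The maximum sampled stress; ties are broken towards the smallest strain.
#'
#' @param curve a [StressStrainCurve-class]
#' @return list with `uts` (MPa) and `strain` (location of the maximum)
#' @export
ultimateTensileStrength <- function(curve) {
  stopifnot(is(curve, "StressStrainCurve"))
  if (!length(curve@stress)) stop("empty stress-strain curve")
  i <- which.max(curve@stress)   # first index attaining the maximum
  list(uts = curve@stress[i], strain = curve@strain[i])
}

#' Toughness (area under the stress-strain curve)
#'
#' Trapezoidal integral of stress over strain from the first to the last
#' sample; for stress per unit volume this is an energy density (MPa).
#'
#' @param curve a [StressStrainCurve-class]
#' @return toughness in MPa
#' @export
toughness <- function(curve) {
  stopifnot(is(curve, "StressStrainCurve"))
  if (length(curve@strain) < 2) stop("need at least two samples")
  if (any(diff(curve@strain) < 0)) stop("strain must be non-decreasing")
  pracma::trapz(curve@strain, curve@stress)
}

#' Elastic modulus from the initial linear region
#'
#' Ordinary-least-squares slope of stress (MPa) against strain over
#' `fitRegion`, converted to GPa.
#'
#' @param curve a [StressStrainCurve-class]
#' @param fitRegion strain interval used for the linear fit
#' @return modulus in GPa
#' @export
elasticModulus <- function(curve, fitRegion = c(0, 0.05)) {
  stopifnot(is(curve, "StressStrainCurve"))
  sel <- curve@strain >= fitRegion[1] & curve@strain <= fitRegion[2]
  x <- curve@strain[sel]; y <- curve@stress[sel]
  if (length(x) < 2 || diff(range(x)) == 0)
    stop("degenerate fit region: need >= 2 distinct strain samples")
  unname(coef(lm(y ~ x))[2]) / 1000
}

#' Evaluate a polynomial with descending-degree coefficients (Horner)
#'
#' @param poly a [ConstitutivePolynomial-class] or a bare coefficient
#'   vector in descending degree
#' @param eps strain value(s)
#' @return stress (MPa)
#' @export
evaluateConstitutive <- function(poly, eps) {
  coefs <- if (is(poly, "ConstitutivePolynomial")) poly@coefficients
           else as.numeric(poly)
  out <- rep(0, length(eps))
  for (c in coefs) out <- out * eps + c
  out
}

#' Fit a polynomial constitutive model to a curve
#'
#' Least-squares polynomial of the requested degree with
#' R^2 = 1 - SS_res/SS_tot.
#'
#' @param curve a [StressStrainCurve-class]
#' @param degree polynomial degree (the published per-condition degrees
#'   range from 4 to 6)
#' @param orientation,hydration condition labels stored on the result
#'   (taken from the curve metadata when omitted)
#' @return a [ConstitutivePolynomial-class]
#' @export
fitConstitutivePolynomial <- function(curve, degree,
                                      orientation = NULL, hydration = NULL) {
  stopifnot(is(curve, "StressStrainCurve"))
  x <- curve@strain; y <- curve@stress
  if (length(x) <= degree + 1)
    stop("need more than degree + 1 = ", degree + 1, " samples, got ",
         length(x))
  X <- outer(x, degree:0, `^`)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("rank-deficient design: strain samples cannot support degree ",
         degree)
  ssRes <- sum(fit$residuals^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  md <- curve@metadata
  new("ConstitutivePolynomial",
      orientation = as.numeric(orientation %||% md$orientation %||% NA_real_),
      hydration = as.character(hydration %||% md$hydration %||% "unhydrated"),
      coefficients = unname(fit$coefficients), rSquared = r2)
}

#' Linear modulus-orientation law for one condition
#'
#' Least-squares line E(theta) for the requested hydration x surface cell
#' of a modulus grid.
#'
#' @param grid a [ModulusGrid-class]
#' @param hydration "hydrated" or "unhydrated"
#' @param surface "Ca" or "OH"
#' @return list with `slope` (GPa/degree), `intercept` (GPa), `residuals`
#'   and `rSquared`
#' @export
fitOrientationLine <- function(grid, hydration, surface) {
  stopifnot(is(grid, "ModulusGrid"))
  d <- grid@data
  sel <- d$hydration == hydration & d$surface == surface
  if (!any(sel))
    stop("no grid entries for hydration '", hydration, "', surface '",
         surface, "'")
  d <- d[sel, ]
  if (length(unique(d$orientation)) < 2)
    stop("need >= 2 distinct orientations to fit a line")
  fit <- lm(E ~ orientation, data = d)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits warn
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residuals = unname(fit$residuals), rSquared = r2,
       hydration = hydration, surface = surface)
}

#' Fit the bivariate stress regression surface
#'
#' Least squares over the same 20-monomial basis as the reference surface,
#' from observations of stress at (orientation, strain) pairs.
#'
#' @param data data.frame with columns theta (degrees), eps (strain) and
#'   stress (MPa); at least 20 observations spanning >= 3 orientations
#' @return a "RegressionSurface" with fitted `terms` and `metrics`
#'   (SSE, R^2, adjusted R^2 and RMSE, both on n - p denominators with
#'   p = 20 coefficients)
#' @export
fitRegressionSurface <- function(data) {
  need <- c("theta", "eps", "stress")
  if (!all(need %in% names(data)))
    stop("data must have columns theta, eps, stress")
  nobs <- nrow(data)
  tt <- utsSurfaceTerms()
  p <- nrow(tt)
  if (nobs < p)
    stop("need at least ", p, " observations, got ", nobs)
  if (length(unique(data$theta)) < 3)
    stop("need observations spanning >= 3 orientations")
  X <- vapply(seq_len(p), function(r) data$theta^tt$i[r] * data$eps^tt$j[r],
              numeric(nobs))
  fit <- lm.fit(X, data$stress)
  if (fit$rank < p) {
    bad <- which(is.na(fit$coefficients))
    stop("rank-deficient surface design; collinear terms: ",
         paste(sprintf("theta^%d*eps^%d", tt$i[bad], tt$j[bad]),
               collapse = ", "))
  }
  sse <- sum(fit$residuals^2)
  sst <- sum((data$stress - mean(data$stress))^2)
  r2 <- 1 - sse / sst
  adj <- 1 - (1 - r2) * (nobs - 1) / (nobs - p)
  rmse <- sqrt(sse / (nobs - p))
  out <- list(terms = data.frame(i = tt$i, j = tt$j,
                                 coef = unname(fit$coefficients)),
              metrics = list(sse = sse, rSquared = r2, adjRSquared = adj,
                             rmse = rmse, n = nobs))
  structure(out, class = "RegressionSurface")
}

#' Per-orientation maximum stress (sensitivity grid)
#'
#' Evaluates a constitutive set (list of [ConstitutivePolynomial-class])
#' or a "RegressionSurface" over a strain grid and reports the maximum
#' stress for each orientation, plus a monotonicity diagnostic.
#'
#' @param object list of constitutive polynomials, or a "RegressionSurface"
#' @param thetaGrid orientations (degrees); for a constitutive set these
#'   must match the set's orientations
#' @param epsGrid strain grid (defaults to [0, 0.40] in steps of 1e-4)
#' @return data.frame with theta, maxStress, argmaxStrain; attribute
#'   "monotoneDecreasing" carries the diagnostic
#' @export
sensitivityGrid <- function(object, thetaGrid = REF_ORIENTATIONS,
                            epsGrid = seq(0, 0.40, by = 1e-4)) {
  if (!length(thetaGrid) || !length(epsGrid))
    stop("theta and strain grids must be non-empty")
  maxOne <- function(th) {
    sig <- if (inherits(object, "RegressionSurface")) {
      evaluateRegressionSurface(object, th, epsGrid)
    } else {
      ors <- vapply(object, function(p) p@orientation, numeric(1))
      k <- which(ors == th)
      if (!length(k))
        stop("no constitutive polynomial for orientation ", th)
      evaluateConstitutive(object[[k[1]]], epsGrid)
    }
    i <- which.max(sig)
    c(sig[i], epsGrid[i])
  }
  res <- vapply(thetaGrid, maxOne, numeric(2))
  out <- data.frame(theta = thetaGrid, maxStress = res[1, ],
                    argmaxStrain = res[2, ])
  attr(out, "monotoneDecreasing") <- all(diff(out$maxStress) < 0)
  out
}
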