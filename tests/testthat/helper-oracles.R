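# Shared fixtures and independent oracles.
# Oracles here deliberately avoid the package's own computational paths:
# finite differences for forces, explicit normal equations for least
# squares, brute-force sums for ANOVA and geometry scans.

# ---- lazily built shared systems (expensive fixtures, built once) ------

.fixtures <- new.env(parent = emptyenv())

toyComposite <- function() {
  if (is.null(.fixtures$toy)) .fixtures$toy <- generateToyComposite()
  .fixtures$toy
}

toySystem <- function() {
  if (is.null(.fixtures$toySys))
    .fixtures$toySys <- buildSystem(toyComposite())
  .fixtures$toySys
}

# a short truncated triple helix (18 residues, ~130 atoms) for fast MD
tinyHelix <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- buildCollagenHelix(targetLength = 1.5)
  .fixtures$tiny
}

tinySystem <- function() {
  if (is.null(.fixtures$tinySys))
    .fixtures$tinySys <- buildSystem(tinyHelix())
  .fixtures$tinySys
}

helixSelections <- function(sys, frac = 0.1) {
  protein <- which(sys$atoms$chain %in% c("A", "B", "C"))
  xs <- sys$pos[protein, 1]
  list(fixed = protein[xs <= quantile(xs, frac)],
       pulled = protein[xs >= quantile(xs, 1 - frac)])
}

# ---- oracles -----------------------------------------------------------

# central finite-difference force oracle
fdForces <- function(sys, pos, atoms, h = 1e-5, cutoff = 12) {
  out <- matrix(NA_real_, length(atoms), 3)
  for (a in seq_along(atoms)) for (k in 1:3) {
    pp <- pos; pp[atoms[a], k] <- pp[atoms[a], k] + h
    pm <- pos; pm[atoms[a], k] <- pm[atoms[a], k] - h
    ep <- totalEnergyAndForces(sys, pp, cutoff = cutoff)$energy$total
    em <- totalEnergyAndForces(sys, pm, cutoff = cutoff)$energy$total
    out[a, k] <- -(ep - em) / (2 * h)
  }
  out
}

# explicit normal-equations least squares (descending-degree polynomial)
normalEquationsPoly <- function(x, y, degree) {
  X <- outer(x, degree:0, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# random micro-system exercising every energy term type
randomMicroSystem <- function(seed) {
  set.seed(seed)
  n <- 6L
  # chain 1-2-3-4-5 plus a dangling atom 6 interacting only nonbonded;
  # resample until no pair is closer than 1.3 A (keeps the steep r^-12
  # wall out of the finite-difference noise floor)
  bonds <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L))
  repeat {
    pos <- matrix(rnorm(3 * n, sd = 1.2), n, 3)
    for (r in seq_len(nrow(bonds)))
      pos[bonds[r, 2], ] <- pos[bonds[r, 1], ] +
        normalizeVec(rnorm(3)) * runif(1, 1.3, 1.8)
    pos[6, ] <- pos[3, ] + normalizeVec(rnorm(3)) * runif(1, 2.5, 4)
    if (min(dist(pos)) > 1.3) break
  }
  angles <- rbind(c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L, 5L))
  kub <- c(runif(1, 5, 30), 0, runif(1, 5, 30))
  ubSel <- which(kub > 0)
  structure(list(
    atoms = data.frame(chain = rep("A", n)), n = n, pos = pos,
    mass = runif(n, 5, 30),
    charge = runif(n, -0.6, 0.6),
    epsilon = runif(n, 0.05, 0.4),
    rminHalf = runif(n, 1.2, 2.2),
    bonds = bonds,
    bondPar = list(kb = runif(4, 100, 500), r0 = runif(4, 1.2, 1.8)),
    angles = angles,
    anglePar = list(ktheta = runif(3, 30, 90),
                    theta0 = runif(3, 1.5, 2.2), kub = kub,
                    rub0 = runif(3, 2.2, 2.8)),
    ub = angles[ubSel, c(1, 3), drop = FALSE],
    ubPar = list(kub = kub[ubSel], rub0 = runif(length(ubSel), 2.2, 2.8)),
    dihedrals = rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L)),
    dihPar = list(kphi = runif(2, 0.5, 3), n = sample(1:4, 2, TRUE)),
    impropers = rbind(c(2L, 1L, 3L, 6L)),
    impPar = list(komega = runif(1, 20, 120), omega0 = 0),
    exclKeys = sort(unique(c(
      pairKeyOracle(bonds[, 1], bonds[, 2], n),
      pairKeyOracle(angles[, 1], angles[, 3], n)))),
    coulombConstant = 332.0637), class = "MDSystem")
}

normalizeVec <- function(v) v / sqrt(sum(v * v))

pairKeyOracle <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (as.numeric(lo) - 1) * n + hi
}

# brute-force one-way ANOVA sums
bruteAnova <- function(values, group) {
  group <- factor(group)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (l in levels(group)) {
    v <- values[group == l]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- nlevels(group); n <- length(values)
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  list(ssb = ssb, ssw = ssw, sst = sum((values - gm)^2),
       F = msb / msw, p = pf(msb / msw, k - 1, n - k, lower.tail = FALSE))
}

# dense-grid evaluation of a descending-coefficient polynomial
hornerOracle <- function(coefs, x) {
  # evaluated term by term (not Horner) to stay independent
  deg <- length(coefs) - 1
  rowSums(vapply(seq_along(coefs), function(i) coefs[i] * x^(deg - i + 1),
                 numeric(length(x))))
}
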