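# Hydroxyapatite crystal construction: unit cell, slab replication and
# surface re-termination.

# Wyckoff orbits of the P6_3/m hydroxyapatite structure.  Positional
# parameters follow the classic single-crystal refinements; the hydroxyl
# column is ordered (both OH groups pointing +c) so the cell carries exactly
# 2 OH units and 44 atoms.
haWyckoff6h <- function(x, y) {
  rbind(c(x, y, 1/4), c(-y, x - y, 1/4), c(-x + y, -x, 1/4),
        c(-x, -y, 3/4), c(y, -x + y, 3/4), c(x - y, x, 3/4))
}

haWyckoff4f <- function(z) {
  rbind(c(1/3, 2/3, z), c(2/3, 1/3, 1/2 + z),
        c(2/3, 1/3, -z), c(1/3, 2/3, 1/2 - z))
}

haWyckoff12i <- function(x, y, z) {
  rbind(c(x, y, z), c(-y, x - y, z), c(-x + y, -x, z),
        c(-x, -y, 1/2 + z), c(y, -x + y, 1/2 + z), c(x - y, x, 1/2 + z),
        c(-x, -y, -z), c(y, -x + y, -z), c(x - y, x, -z),
        c(x, y, 1/2 - z), c(-y, x - y, 1/2 - z), c(-x + y, -x, 1/2 - z))
}

# formal charges: Ca +2, phosphate P +1 / O -1 (net -3 per PO4),
# hydroxide O -1.4 / H +0.4 (net -1); the 44-atom cell is neutral.
HA_CHARGES <- c(CAL = 2, PHO = 1, OPH = -1, OHM = -1.4, HOM = 0.4)

haBasisAtoms <- function() {
  orbit <- function(frac, element, type, site) {
    frac <- frac %% 1
    frac[abs(frac - 1) < 1e-9] <- 0
    data.frame(element = element, fx = frac[, 1], fy = frac[, 2],
               fz = frac[, 3], charge = unname(HA_CHARGES[type]),
               site = site, type = type, stringsAsFactors = FALSE)
  }
  rbind(
    orbit(haWyckoff4f(0.0010), "Ca", "CAL", "Ca1"),
    orbit(haWyckoff6h(0.2466, 0.9931), "Ca", "CAL", "Ca2"),
    orbit(haWyckoff6h(0.3982, 0.3682), "P", "PHO", "P"),
    orbit(haWyckoff6h(0.3283, 0.4846), "O", "OPH", "O1"),
    orbit(haWyckoff6h(0.5876, 0.4652), "O", "OPH", "O2"),
    orbit(haWyckoff12i(0.3433, 0.2579, 0.0705), "O", "OPH", "O3"),
    orbit(rbind(c(0, 0, 0.195), c(0, 0, 0.695)), "O", "OHM", "O4"),
    orbit(rbind(c(0, 0, 0.062), c(0, 0, 0.562)), "H", "HOM", "H4"))
}

#' Build a hydroxyapatite unit cell
#'
#' Populates the stated cell with the standard hexagonal (P6_3/m)
#' hydroxyapatite basis: 44 atoms realising Ca10(PO4)6(OH)2.  The default
#' lattice constants are a = 9.4214 A, b = 2a, c = 6.8814 A, gamma = 120
#' degrees; the b = 2a cell is taken at face value, i.e. the hexagonal basis
#' is scaled onto the stated b axis.
#'
#' @param a,b,c lattice constants in Angstrom (b defaults to 2a)
#' @param gamma a-b lattice angle in degrees
#' @return a [UnitCell-class] with 44 basis atoms
#' @examples
#' cell <- haUnitCell()
#' table(cell@basisAtoms$element)  # Ca:P:O:H = 10:6:26:2
#' @export
haUnitCell <- function(a = 9.4214, b = 2 * a, c = 6.8814, gamma = 120) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0 ||
      !is.numeric(b) || length(b) != 1 || !is.finite(b) || b <= 0 ||
      !is.numeric(c) || length(c) != 1 || !is.finite(c) || c <= 0)
    stop("invalid lattice parameter: a, b, c must be positive finite lengths")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0 || gamma >= 180)
    stop("invalid lattice parameter: gamma must lie in (0, 180) degrees")
  new("UnitCell", a = a, b = b, c = c, gamma = gamma,
      basisAtoms = haBasisAtoms())
}

# lattice vectors as rows of a 3x3 matrix; a along +X, c along +Z
latticeVectors <- function(cell) {
  g <- degToRad(cell@gamma)
  rbind(c(cell@a, 0, 0),
        c(cell@b * cos(g), cell@b * sin(g), 0),
        c(0, 0, cell@c))
}

#' Replicate a unit cell into a crystal slab
#'
#' Applies oblique lattice translations (gamma-angled a/b basis) to the cell
#' basis.  The atom count is exactly `44 * nx * ny * nz`.
#'
#' @param cell a [UnitCell-class]
#' @param nx,ny,nz positive integer replication counts along X, Y, Z
#' @return a [CrystalSlab-class] (chain "M")
#' @examples
#' slab <- replicateCrystal(haUnitCell(), 2, 1, 1)
#' nAtoms(slab)  # 88
#' @export
replicateCrystal <- function(cell, nx, ny, nz) {
  stopifnot(is(cell, "UnitCell"))
  reps <- c(nx, ny, nz)
  if (any(!is.finite(reps)) || any(reps != as.integer(reps)) || any(reps < 1))
    stop("replication counts must be integers >= 1")
  reps <- as.integer(reps)
  lat <- latticeVectors(cell)
  ba <- cell@basisAtoms
  frac <- as.matrix(ba[, c("fx", "fy", "fz")])
  shifts <- as.matrix(expand.grid(ix = 0:(reps[1] - 1L),
                                  iy = 0:(reps[2] - 1L),
                                  iz = 0:(reps[3] - 1L)))
  ncell <- nrow(shifts)
  fracAll <- frac[rep(seq_len(nrow(frac)), times = ncell), , drop = FALSE] +
    shifts[rep(seq_len(ncell), each = nrow(frac)), , drop = FALSE]
  cart <- fracAll %*% lat
  n <- nrow(cart)
  atomsDf <- data.frame(
    element = rep(ba$element, times = ncell),
    name = rep(ba$site, times = ncell),
    resname = "HAP",
    resid = rep(seq_len(ncell), each = nrow(frac)),
    chain = "M",
    type = rep(ba$type, times = ncell),
    charge = rep(ba$charge, times = ncell),
    x = cart[, 1], y = cart[, 2], z = cart[, 3],
    stringsAsFactors = FALSE)
  slab <- new("CrystalSlab", cell = cell, replication = reps,
              atoms = atomsDf, exposedSurface = "Ca",
              surfaceLog = list())
  slab@exposedSurface <- topLayerSurface(slab)
  slab
}

# does the topmost band satisfy a termination criterion?
# Ca: calcium is the majority species of the band; OH: hydroxide atoms are
meetsSurface <- function(slab, surface, band = 0.4) {
  a <- slab@atoms
  top <- a[a$z > max(a$z) - band, , drop = FALSE]
  if (surface == "Ca") mean(top$type == "CAL") > 0.5
  else mean(top$type %in% c("OHM", "HOM")) > 0.5
}

# classify the +Z face ("Ca"/"OH"; majority fallback for mixed bands)
topLayerSurface <- function(slab, band = 0.4) {
  if (meetsSurface(slab, "Ca", band)) return("Ca")
  if (meetsSurface(slab, "OH", band)) return("OH")
  a <- slab@atoms
  top <- a[a$z > max(a$z) - band, , drop = FALSE]
  if (sum(top$type == "CAL") >= sum(top$type %in% c("OHM", "HOM"))) "Ca"
  else "OH"
}

#' Re-terminate the +Z surface of a crystal slab
#'
#' Peels atomic layers off the top face until the requested species
#' dominates the topmost layer: "Ca" leaves a calcium-terminated face, "OH"
#' a hydroxide-terminated face (the O-H column atoms).  Removed atoms and
#' their total charge are recorded in `surfaceLog`.  Requesting the
#' termination the slab already has is a no-op.
#'
#' @param slab a [CrystalSlab-class]
#' @param surface "Ca" or "OH"
#' @param band thickness (Angstrom) of the surface layer used to classify
#'   the termination
#' @return the re-terminated [CrystalSlab-class]
#' @export
selectSurface <- function(slab, surface = c("Ca", "OH"), band = 0.4) {
  stopifnot(is(slab, "CrystalSlab"))
  surface <- match.arg(surface)
  zs <- sort(unique(round(slab@atoms$z, 3)))
  if (length(zs) < 2) stop("slab too thin to re-terminate: fewer than 2 layers")
  removed <- emptyAtomTable()
  guard <- 0L
  while (!meetsSurface(slab, surface, band)) {
    a <- slab@atoms
    zmax <- max(a$z)
    peel <- a$z > zmax - 0.3           # one crystallographic level
    if (all(peel) || guard > 200L)
      stop("slab too thin to re-terminate as '", surface, "'")
    removed <- rbind(removed, a[peel, , drop = FALSE])
    slab@atoms <- a[!peel, , drop = FALSE]
    guard <- guard + 1L
    if (length(unique(round(slab@atoms$z, 3))) < 2)
      stop("slab too thin to re-terminate as '", surface, "'")
  }
  slab@exposedSurface <- surface
  slab@surfaceLog <- list(
    requested = surface,
    removedAtoms = nrow(removed),
    removedCharge = sum(removed$charge),
    retainedCharge = sum(slab@atoms$charge))
  slab
}
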