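# Central S4 containers. All coordinates are Cartesian Angstrom; the tensile
# load axis is +X and the mineral surface normal is +Z throughout.

ATOM_COLUMNS <- c("element", "name", "resname", "resid", "chain",
                  "type", "charge", "x", "y", "z")

emptyAtomTable <- function() {
  data.frame(element = character(), name = character(),
             resname = character(), resid = integer(), chain = character(),
             type = character(), charge = numeric(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

checkAtomTable <- function(atoms, what = "atoms") {
  if (!is.data.frame(atoms))
    return(sprintf("'%s' must be a data.frame", what))
  missing <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing))
    return(sprintf("'%s' lacks columns: %s", what,
                   paste(missing, collapse = ", ")))
  if (nrow(atoms) && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    return(sprintf("'%s' has non-finite coordinates", what))
  TRUE
}

#' Hydroxyapatite unit cell
#'
#' Lattice parameters plus the 44-atom basis realising the
#' Ca10(PO4)6(OH)2 stoichiometry (10 Ca, 6 P, 26 O, 2 H per cell).
#' `gamma` is the angle between the a and b lattice vectors in degrees;
#' basis atoms are stored as fractional coordinates in [0, 1).
#'
#' @slot a,b,c lattice constants (Angstrom)
#' @slot gamma a-b lattice angle (degrees)
#' @slot basisAtoms data.frame with element, fx, fy, fz, charge, site
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 gamma = "numeric", basisAtoms = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@a) != 1 || !is.finite(object@a) || object@a <= 0)
      msg <- c(msg, "lattice constant 'a' must be a single positive number")
    if (length(object@b) != 1 || !is.finite(object@b) || object@b <= 0)
      msg <- c(msg, "lattice constant 'b' must be a single positive number")
    if (length(object@c) != 1 || !is.finite(object@c) || object@c <= 0)
      msg <- c(msg, "lattice constant 'c' must be a single positive number")
    if (length(object@gamma) != 1 || !is.finite(object@gamma) ||
        object@gamma <= 0 || object@gamma >= 180)
      msg <- c(msg, "'gamma' must lie strictly between 0 and 180 degrees")
    ba <- object@basisAtoms
    need <- c("element", "fx", "fy", "fz", "charge", "site")
    if (!all(need %in% names(ba))) {
      msg <- c(msg, "basisAtoms must have element/fx/fy/fz/charge/site")
    } else if (nrow(ba)) {
      if (nrow(ba) != 44L)
        msg <- c(msg, sprintf("hydroxyapatite basis must have 44 atoms, got %d",
                              nrow(ba)))
      cnt <- table(ba$element)
      want <- c(Ca = 10L, P = 6L, O = 26L, H = 2L)
      for (el in names(want))
        if (is.na(cnt[el]) || cnt[el] != want[el])
          msg <- c(msg, sprintf("basis must contain %d %s atoms", want[el], el))
      fr <- as.matrix(ba[, c("fx", "fy", "fz")])
      if (any(fr < 0 | fr >= 1))
        msg <- c(msg, "fractional coordinates must lie in [0, 1)")
    }
    if (length(msg)) msg else TRUE
  })

#' Replicated hydroxyapatite crystal slab
#'
#' @slot cell the generating [UnitCell-class]
#' @slot replication integer replication counts along X, Y, Z
#' @slot atoms Cartesian atom table (chain "M")
#' @slot exposedSurface "Ca" or "OH": which species terminates the +Z face
#' @slot surfaceLog list recording atoms removed by re-termination
#' @exportClass CrystalSlab
setClass("CrystalSlab",
  representation(cell = "UnitCell", replication = "integer",
                 atoms = "data.frame", exposedSurface = "character",
                 surfaceLog = "list"),
  validity = function(object) {
    msg <- character()
    ok <- checkAtomTable(object@atoms, "atoms")
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (length(object@replication) != 3 || any(object@replication < 1))
      msg <- c(msg, "replication must be three integers >= 1")
    if (!object@exposedSurface %in% c("Ca", "OH"))
      msg <- c(msg, "exposedSurface must be 'Ca' or 'OH'")
    if (length(msg)) msg else TRUE
  })

#' Collagen chain sequence
#'
#' One repeat of the alpha1 sequence has 30 residues and one repeat of the
#' alpha2 sequence 29 residues (Gly-X-Y triplets of PRO/HYP/GLY with one
#' GLU-LYS-GLY triplet).
#'
#' @slot chainType "alpha1" or "alpha2"
#' @slot residues three-letter residue codes of a single repeat
#' @slot nRepeats number of tandem repeats
#' @exportClass ChainSequence
setClass("ChainSequence",
  representation(chainType = "character", residues = "character",
                 nRepeats = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@chainType %in% c("alpha1", "alpha2"))
      msg <- c(msg, "chainType must be 'alpha1' or 'alpha2'")
    if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
    expected <- if (identical(object@chainType, "alpha1")) 30L else 29L
    if (length(object@residues) != expected)
      msg <- c(msg, sprintf("a single %s repeat must have %d residues, got %d",
                            object@chainType, expected,
                            length(object@residues)))
    if (length(msg)) msg else TRUE
  })

#' Collagen triple helix model
#'
#' Two alpha1 chains (chain IDs A, B) and one alpha2 chain (chain ID C)
#' on a right-handed triple-helical scaffold.
#'
#' @slot chains list of the three [ChainSequence-class] objects used
#' @slot atoms Cartesian atom table
#' @slot residueCount total residues over the three chains
#' @slot length helix length (nm, computed along the axis)
#' @slot diameter helix diameter (nm, computed from radial extent)
#' @exportClass TripleHelixModel
setClass("TripleHelixModel",
  representation(chains = "list", atoms = "data.frame",
                 residueCount = "integer", length = "numeric",
                 diameter = "numeric"),
  validity = function(object) {
    msg <- character()
    ok <- checkAtomTable(object@atoms, "atoms")
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (length(object@chains) != 3)
      msg <- c(msg, "a triple helix needs exactly three chains")
    else {
      types <- vapply(object@chains, function(ch) ch@chainType, character(1))
      if (sum(types == "alpha1") != 2 || sum(types == "alpha2") != 1)
        msg <- c(msg, "chain composition must be 2 x alpha1 + 1 x alpha2")
    }
    if (nrow(object@atoms)) {
      nres <- length(unique(paste(object@atoms$chain, object@atoms$resid)))
      if (nres != object@residueCount)
        msg <- c(msg, sprintf("residueCount (%d) != residues in atom table (%d)",
                              object@residueCount, nres))
    }
    if (length(msg)) msg else TRUE
  })

#' Crack geometry
#'
#' Ellipsoidal or slit-shaped void to carve out of a composite model.
#' Zero dimensions make the crack a no-op.
#'
#' @slot shape "ellipsoid" or "slit"
#' @slot center Cartesian centre (Angstrom)
#' @slot dimensions semi-axes (ellipsoid) or length/height/opening (slit), Angstrom
#' @slot orientation axis unit vector of the crack
#' @exportClass CrackGeometry
setClass("CrackGeometry",
  representation(shape = "character", center = "numeric",
                 dimensions = "numeric", orientation = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@shape %in% c("ellipsoid", "slit"))
      msg <- c(msg, "shape must be 'ellipsoid' or 'slit'")
    if (length(object@center) != 3) msg <- c(msg, "center must be length 3")
    if (length(object@dimensions) != 3 || any(object@dimensions < 0))
      msg <- c(msg, "dimensions must be three non-negative lengths")
    if (length(object@orientation) != 3)
      msg <- c(msg, "orientation must be length 3")
    if (length(msg)) msg else TRUE
  })

#' Collagen-hydroxyapatite composite model
#'
#' A triple helix placed above a mineral slab with a prescribed angle
#' between the helix axis and the +X load axis (rotation in the XZ plane),
#' optionally solvated by a shell of rigid three-site waters (chain "W").
#'
#' @slot helix [TripleHelixModel-class]
#' @slot slab [CrystalSlab-class]
#' @slot orientationDeg angle between helix axis and load axis, degrees, [0, 90]
#' @slot hydrated logical
#' @slot waters atom table of water atoms (empty when un-hydrated)
#' @slot provenance construction log (inputs, seeds, removed atoms, ...)
#' @exportClass CompositeModel
setClass("CompositeModel",
  representation(helix = "TripleHelixModel", slab = "CrystalSlab",
                 orientationDeg = "numeric", hydrated = "logical",
                 waters = "data.frame", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (object@orientationDeg < 0 || object@orientationDeg > 90)
      msg <- c(msg, "orientationDeg must lie in [0, 90]")
    ok <- checkAtomTable(object@waters, "waters")
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (!object@hydrated && nrow(object@waters) > 0)
      msg <- c(msg, "an un-hydrated model must have an empty water table")
    if (length(msg)) msg else TRUE
  })

#' CHARMM-style forcefield parameter set
#'
#' Harmonic bond, valence-angle (with optional Urey-Bradley 1-3 term),
#' cosine dihedral and harmonic improper parameters, plus per-type mass,
#' default charge and Lennard-Jones well depth/position.  Angle and torsion
#' lookups support CHARMM-style "X" wildcards.
#'
#' @slot atoms data.frame: type, mass, charge, epsilon, rminHalf
#' @slot bonds data.frame: typeI, typeJ, kb, r0
#' @slot angles data.frame: typeI, typeJ, typeK, ktheta, theta0 (deg), kub, rub0
#' @slot dihedrals data.frame: typeI..typeL, kphi, n
#' @slot impropers data.frame: typeI..typeL, komega, omega0 (deg)
#' @slot coulombConstant Coulomb prefactor, kcal A / (mol e^2)
#' @exportClass ForceFieldParameters
setClass("ForceFieldParameters",
  representation(atoms = "data.frame", bonds = "data.frame",
                 angles = "data.frame", dihedrals = "data.frame",
                 impropers = "data.frame", coulombConstant = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@bonds$kb < 0) || any(object@angles$ktheta < 0) ||
        any(object@angles$kub < 0, na.rm = TRUE) ||
        any(object@impropers$komega < 0))
      msg <- c(msg, "force constants must be non-negative")
    if (any(object@atoms$rminHalf <= 0))
      msg <- c(msg, "Lennard-Jones Rmin/2 must be positive")
    if (any(object@atoms$epsilon < 0))
      msg <- c(msg, "Lennard-Jones well depths must be non-negative")
    if (any(object@dihedrals$n < 1))
      msg <- c(msg, "dihedral multiplicities must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Tensile pulling protocol
#'
#' Constant-velocity steered MD: one atom selection is held fixed, the other
#' is tethered by stiff springs to anchors advancing along the pull axis.
#'
#' @slot pullAxis unit vector of the load axis
#' @slot pullSpeed anchor speed (Angstrom/ps)
#' @slot fixedSelection,pulledSelection atom indices (disjoint)
#' @slot springConstant steering spring (kcal/mol/A^2)
#' @slot timestep integration step (fs)
#' @slot temperature Langevin target temperature (K); 0 or friction 0 => NVE
#' @slot friction Langevin friction (1/ps)
#' @slot nSteps,saveInterval integration length and frame stride
#' @slot cutoff nonbonded cutoff (Angstrom)
#' @slot seed RNG seed controlling thermostat noise and initial velocities
#' @exportClass TensileProtocol
setClass("TensileProtocol",
  representation(pullAxis = "numeric", pullSpeed = "numeric",
                 fixedSelection = "integer", pulledSelection = "integer",
                 springConstant = "numeric", timestep = "numeric",
                 temperature = "numeric", friction = "numeric",
                 nSteps = "integer", saveInterval = "integer",
                 cutoff = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@pullAxis) != 3 ||
        abs(sqrt(sum(object@pullAxis^2)) - 1) > 1e-8)
      msg <- c(msg, "pullAxis must be a 3D unit vector")
    if (object@pullSpeed < 0) msg <- c(msg, "pullSpeed must be >= 0")
    if (object@timestep <= 0) msg <- c(msg, "timestep must be positive")
    if (length(intersect(object@fixedSelection, object@pulledSelection)))
      msg <- c(msg, "fixed and pulled selections must be disjoint")
    if (object@nSteps < 1 || object@saveInterval < 1)
      msg <- c(msg, "nSteps and saveInterval must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Molecular dynamics trajectory
#'
#' @slot times frame times (fs), strictly increasing
#' @slot positions list of N x 3 coordinate matrices
#' @slot velocities list of N x 3 velocity matrices (Angstrom/fs)
#' @slot energies data.frame of per-frame energy breakdowns (kcal/mol)
#' @slot stress list of per-frame 3 x 3 virial stress tensors (MPa)
#' @slot appliedStrain per-frame strain imposed by the steering anchors
#' @slot protocol the [TensileProtocol-class] that produced the run
#' @slot metadata list (model provenance, volumes, selections)
#' @exportClass Trajectory
setClass("Trajectory",
  representation(times = "numeric", positions = "list", velocities = "list",
                 energies = "data.frame", stress = "list",
                 appliedStrain = "numeric", protocol = "TensileProtocol",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) && any(diff(object@times) <= 0))
      msg <- c(msg, "frame times must be strictly increasing")
    if (length(object@positions) != length(object@times))
      msg <- c(msg, "one coordinate frame per time point required")
    if (length(msg)) msg else TRUE
  })

#' Stress-strain curve
#'
#' Paired engineering strain / stress samples with smoothing provenance.
#'
#' @slot strain dimensionless engineering strain, non-decreasing
#' @slot stress stress (MPa) after smoothing
#' @slot rawStress unsmoothed stress (MPa), same length
#' @slot smoothingWindow centred moving-average window (frames), >= 1
#' @slot metadata condition labels (orientation, hydration, surface, seed, ...)
#' @exportClass StressStrainCurve
setClass("StressStrainCurve",
  representation(strain = "numeric", stress = "numeric",
                 rawStress = "numeric", smoothingWindow = "integer",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@strain) != length(object@stress))
      msg <- c(msg, "strain and stress must have equal length")
    if (length(object@strain) > 1 && any(diff(object@strain) < -1e-9))
      msg <- c(msg, "strain must be non-decreasing")
    if (object@smoothingWindow < 1L)
      msg <- c(msg, "smoothingWindow must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Polynomial constitutive model of a stress-strain curve
#'
#' @slot orientation fibril orientation (degrees)
#' @slot hydration "hydrated" or "unhydrated"
#' @slot coefficients polynomial coefficients in descending degree
#' @slot rSquared coefficient of determination of the fit
#' @exportClass ConstitutivePolynomial
setClass("ConstitutivePolynomial",
  representation(orientation = "numeric", hydration = "character",
                 coefficients = "numeric", rSquared = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!length(object@coefficients))
      msg <- c(msg, "coefficients must be non-empty")
    if (!object@hydration %in% c("hydrated", "unhydrated"))
      msg <- c(msg, "hydration must be 'hydrated' or 'unhydrated'")
    if (length(object@rSquared) == 1 && is.finite(object@rSquared) &&
        object@rSquared > 1 + 1e-12)
      msg <- c(msg, "rSquared cannot exceed 1")
    if (length(msg)) msg else TRUE
  })

#' Elastic modulus grid over orientation x hydration x surface
#'
#' The canonical complete grid has 6 orientations x 2 hydration states x
#' 2 mineral surfaces = 24 entries, all positive, in GPa.
#'
#' @slot data data.frame: orientation, hydration, surface, E
#' @slot observations optional data.frame of replicate observations
#' @exportClass ModulusGrid
setClass("ModulusGrid",
  representation(data = "data.frame", observations = "data.frame"),
  validity = function(object) {
    msg <- character()
    need <- c("orientation", "hydration", "surface", "E")
    if (!all(need %in% names(object@data)))
      msg <- c(msg, "grid needs columns orientation, hydration, surface, E")
    else {
      if (any(!object@data$hydration %in% c("hydrated", "unhydrated")))
        msg <- c(msg, "hydration levels must be 'hydrated'/'unhydrated'")
      if (any(!object@data$surface %in% c("Ca", "OH")))
        msg <- c(msg, "surface levels must be 'Ca'/'OH'")
      if (any(object@data$E <= 0))
        msg <- c(msg, "moduli must be positive")
    }
    if (length(msg)) msg else TRUE
  })
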