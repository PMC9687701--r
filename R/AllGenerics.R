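# Generics, accessors and show methods.

#' Atom table of a model object
#'
#' Returns the Cartesian atom table (element, name, resname, resid, chain,
#' type, charge, x, y, z).  For a [CompositeModel-class] the helix (chains
#' A/B/C), mineral (chain M) and water (chain W) tables are concatenated in
#' that order.
#'
#' @param x a model object
#' @return a data.frame, one row per atom
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Number of atoms in a model object
#' @param x a model object
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn atoms atoms of a crystal slab
#' @export
setMethod("atoms", "CrystalSlab", function(x) x@atoms)

#' @describeIn atoms atoms of a triple helix
#' @export
setMethod("atoms", "TripleHelixModel", function(x) x@atoms)

#' @describeIn atoms combined helix + mineral + water atoms
#' @export
setMethod("atoms", "CompositeModel", function(x) {
  rbind(x@helix@atoms, x@slab@atoms, x@waters)
})

#' @describeIn nAtoms atom count of a slab
#' @export
setMethod("nAtoms", "CrystalSlab", function(x) nrow(x@atoms))

#' @describeIn nAtoms atom count of a helix
#' @export
setMethod("nAtoms", "TripleHelixModel", function(x) nrow(x@atoms))

#' @describeIn nAtoms total atom count of a composite
#' @export
setMethod("nAtoms", "CompositeModel", function(x) nrow(atoms(x)))

#' Total residue count of a triple helix
#' @param x a [TripleHelixModel-class]
#' @return integer residue count summed over the three chains
#' @export
residueCount <- function(x) {
  stopifnot(is(x, "TripleHelixModel"))
  x@residueCount
}

#' Orientation angle of a composite model
#' @param x a [CompositeModel-class]
#' @return angle between helix axis and load axis, degrees
#' @export
orientation <- function(x) {
  stopifnot(is(x, "CompositeModel"))
  x@orientationDeg
}

#' Hydration state of a composite model
#' @param x a [CompositeModel-class]
#' @return logical
#' @export
isHydrated <- function(x) {
  stopifnot(is(x, "CompositeModel"))
  x@hydrated
}

#' Strain samples of a stress-strain curve
#' @param x a [StressStrainCurve-class]
#' @return numeric vector of engineering strains
#' @export
strainOf <- function(x) {
  stopifnot(is(x, "StressStrainCurve"))
  x@strain
}

#' Stress samples of a stress-strain curve
#' @param x a [StressStrainCurve-class]
#' @param raw return the unsmoothed series?
#' @return numeric vector of stresses (MPa)
#' @export
stressOf <- function(x, raw = FALSE) {
  stopifnot(is(x, "StressStrainCurve"))
  if (raw) x@rawStress else x@stress
}

#' Grid data of a modulus grid
#' @param x a [ModulusGrid-class]
#' @return data.frame with orientation, hydration, surface, E (GPa)
#' @export
gridData <- function(x) {
  stopifnot(is(x, "ModulusGrid"))
  x@data
}

#' Coefficients of a constitutive polynomial (descending degree)
#' @param object a [ConstitutivePolynomial-class]
#' @param ... ignored
#' @return numeric coefficient vector
#' @export
setMethod("coef", "ConstitutivePolynomial", function(object, ...) {
  object@coefficients
})

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.4f b=%.4f c=%.4f A, gamma=%.1f deg, %d basis atoms\n",
              object@a, object@b, object@c, object@gamma,
              nrow(object@basisAtoms)))
})

setMethod("show", "CrystalSlab", function(object) {
  cat(sprintf("CrystalSlab: %d atoms (%dx%dx%d replication), %s-terminated +Z face\n",
              nrow(object@atoms), object@replication[1], object@replication[2],
              object@replication[3], object@exposedSurface))
})

setMethod("show", "TripleHelixModel", function(object) {
  cat(sprintf("TripleHelixModel: %d residues, %d atoms, length %.1f nm, diameter %.2f nm\n",
              object@residueCount, nrow(object@atoms), object@length,
              object@diameter))
})

setMethod("show", "CompositeModel", function(object) {
  cat(sprintf(
    "CompositeModel: %d atoms (helix %d, mineral %d, water %d)\n  orientation %.1f deg, %s, %s mineral surface\n",
    nAtoms(object), nrow(object@helix@atoms), nrow(object@slab@atoms),
    nrow(object@waters), object@orientationDeg,
    if (object@hydrated) "hydrated" else "un-hydrated",
    object@slab@exposedSurface))
})

setMethod("show", "ForceFieldParameters", function(object) {
  cat(sprintf(
    "ForceFieldParameters: %d atom types, %d bond, %d angle, %d dihedral, %d improper entries\n",
    nrow(object@atoms), nrow(object@bonds), nrow(object@angles),
    nrow(object@dihedrals), nrow(object@impropers)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %.1f fs, %d atoms\n",
              length(object@times),
              if (length(object@times)) max(object@times) else 0,
              if (length(object@positions)) nrow(object@positions[[1]]) else 0))
})

setMethod("show", "StressStrainCurve", function(object) {
  cat(sprintf("StressStrainCurve: %d samples, strain [%.3f, %.3f], window %d\n",
              length(object@strain),
              if (length(object@strain)) min(object@strain) else NA,
              if (length(object@strain)) max(object@strain) else NA,
              object@smoothingWindow))
})

setMethod("show", "ConstitutivePolynomial", function(object) {
  cat(sprintf("ConstitutivePolynomial: degree %d, %s, %g deg, R^2 = %.4f\n",
              length(object@coefficients) - 1L, object@hydration,
              object@orientation, object@rSquared))
})

setMethod("show", "ModulusGrid", function(object) {
  cat(sprintf("ModulusGrid: %d entries (%d observations)\n",
              nrow(object@data), nrow(object@observations)))
})
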