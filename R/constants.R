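# Physical constants and unit conversions.  Internal MD units are
# kcal/mol (energy), Angstrom (length), fs (time), amu (mass), e (charge).

AVOGADRO <- 6.02214076e23            # 1/mol
KCAL_JOULE <- 4184                   # J per kcal (thermochemical)
BOLTZMANN_KCAL <- 0.001987204259     # kcal/mol/K
COULOMB_KCAL <- 332.0637             # kcal A/(mol e^2), absorbs 1/(4 pi eps0)

# acceleration unit: (kcal/mol/A) / amu expressed in A/fs^2
ACCEL_UNIT <- KCAL_JOULE * 1e-4      # = 0.4184; a[A/fs^2] = 1e-4*4184/... see below
# derivation: 1 kcal/mol/A = 4184 J/mol/1e-10 m; dividing by 1 amu = 1e-3 kg/mol
# gives 4.184e16 m/s^2 = 4.184e-4 A/fs^2.
ACCEL_UNIT <- 4.184e-4
KE_UNIT <- 1 / ACCEL_UNIT            # amu (A/fs)^2 in kcal/mol (= 2390.06)

#' Stress unit conversion factor
#'
#' Number of MPa in one kcal/mol/Angstrom^3, computed from the
#' thermochemical calorie and the Avogadro constant rather than stored as a
#' literal, so it can be cross-checked against an independent unit chain.
#'
#' @return a single number, about 6947.7 MPa per kcal/mol/A^3
#' @export
kcalPerMolA3ToMPa <- function() {
  # kcal/mol/A^3 -> J/A^3 (per molecule) -> Pa -> MPa
  KCAL_JOULE / AVOGADRO / 1e-30 / 1e6
}

degToRad <- function(x) x * pi / 180
radToDeg <- function(x) x * 180 / pi

rowNorms <- function(m) sqrt(rowSums(m * m))

normalize <- function(v) v / sqrt(sum(v * v))
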