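# CHARMM-PRM-like parameter file reader/writer and the packaged default
# parameter set.
#
# Grammar: `*` and `!` start comments; section headers ATOMS, BONDS,
# ANGLES, DIHEDRALS, IMPROPER, NONBONDED (all required), optional END.
#   ATOMS      type mass charge
#   BONDS      typeI typeJ kb r0
#   ANGLES     typeI typeJ typeK ktheta theta0 [kub rub0]
#   DIHEDRALS  typeI typeJ typeK typeL kphi n
#   IMPROPER   typeI typeJ typeK typeL komega omega0
#   NONBONDED  type epsilon rminHalf
# "X" is a wildcard type in ANGLES/DIHEDRALS/IMPROPER.  Units: kcal/mol,
# Angstrom, degrees, electron charges, amu.  Duplicate definitions:
# last one wins, with a warning.

FF_SECTIONS <- c("ATOMS", "BONDS", "ANGLES", "DIHEDRALS", "IMPROPER",
                 "NONBONDED")

#' Parse a forcefield parameter file
#'
#' @param path path to a parameter file in the documented dialect
#' @return a [ForceFieldParameters-class]
#' @export
readForceFieldParameters <- function(path) {
  lines <- readLines(path)
  section <- NA_character_
  seen <- character()
  rows <- setNames(vector("list", length(FF_SECTIONS)), FF_SECTIONS)
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    txt <- sub("!.*$", "", raw)
    txt <- trimws(txt)
    if (!nzchar(txt) || startsWith(txt, "*")) next
    up <- toupper(txt)
    if (up %in% c(FF_SECTIONS, "END")) {
      if (up == "END") break
      section <- up
      seen <- union(seen, up)
      next
    }
    if (is.na(section))
      stop("parse error at line ", ln, ": data before any section header")
    tok <- strsplit(txt, "\\s+")[[1]]
    nType <- switch(section, ATOMS = 1L, BONDS = 2L, ANGLES = 3L,
                    DIHEDRALS = 4L, IMPROPER = 4L, NONBONDED = 1L)
    nNumMin <- switch(section, ATOMS = 2L, BONDS = 2L, ANGLES = 2L,
                      DIHEDRALS = 2L, IMPROPER = 2L, NONBONDED = 2L)
    nums <- suppressWarnings(as.numeric(tok[-seq_len(nType)]))
    if (length(nums) < nNumMin || anyNA(nums))
      stop("parse error at line ", ln, " (section ", section, "): '",
           raw, "'")
    rows[[section]][[length(rows[[section]]) + 1L]] <-
      list(types = tok[seq_len(nType)], nums = nums, line = ln)
  }
  missing <- setdiff(FF_SECTIONS, seen)
  if (length(missing))
    stop("missing section(s): ", paste(missing, collapse = ", "))

  dedupe <- function(entries, keyFun, what) {
    keys <- vapply(entries, keyFun, character(1))
    if (anyDuplicated(keys)) {
      dup <- unique(keys[duplicated(keys)])
      warning("duplicate ", what, " definition(s) for ",
              paste(dup, collapse = ", "), "; last wins", call. = FALSE)
    }
    entries[!rev(duplicated(rev(keys)))]
  }

  atomRows <- dedupe(rows$ATOMS, function(e) e$types[1], "atom")
  nbRows <- dedupe(rows$NONBONDED, function(e) e$types[1], "nonbonded")
  atomsDf <- data.frame(
    type = vapply(atomRows, function(e) e$types[1], character(1)),
    mass = vapply(atomRows, function(e) e$nums[1], numeric(1)),
    charge = vapply(atomRows, function(e) e$nums[2], numeric(1)),
    stringsAsFactors = FALSE)
  nbDf <- data.frame(
    type = vapply(nbRows, function(e) e$types[1], character(1)),
    epsilon = vapply(nbRows, function(e) e$nums[1], numeric(1)),
    rminHalf = vapply(nbRows, function(e) e$nums[2], numeric(1)),
    stringsAsFactors = FALSE)
  miss <- setdiff(atomsDf$type, nbDf$type)
  if (length(miss))
    stop("no NONBONDED entry for atom type(s): ", paste(miss, collapse = ", "))
  atomsDf <- merge(atomsDf, nbDf, by = "type", sort = TRUE)

  bondRows <- dedupe(rows$BONDS,
                     function(e) paste(sort(e$types), collapse = " "), "bond")
  bondsDf <- data.frame(
    typeI = vapply(bondRows, function(e) e$types[1], character(1)),
    typeJ = vapply(bondRows, function(e) e$types[2], character(1)),
    kb = vapply(bondRows, function(e) e$nums[1], numeric(1)),
    r0 = vapply(bondRows, function(e) e$nums[2], numeric(1)),
    stringsAsFactors = FALSE)
  if (any(bondsDf$kb < 0))
    stop("negative bond force constant for ",
         paste(bondsDf$typeI[bondsDf$kb < 0], bondsDf$typeJ[bondsDf$kb < 0],
               collapse = ", "))

  angleKey <- function(e) {
    t <- e$types
    if (t[1] > t[3]) t <- rev(t)
    paste(t, collapse = " ")
  }
  angleRows <- dedupe(rows$ANGLES, angleKey, "angle")
  anglesDf <- data.frame(
    typeI = vapply(angleRows, function(e) e$types[1], character(1)),
    typeJ = vapply(angleRows, function(e) e$types[2], character(1)),
    typeK = vapply(angleRows, function(e) e$types[3], character(1)),
    ktheta = vapply(angleRows, function(e) e$nums[1], numeric(1)),
    theta0 = vapply(angleRows, function(e) e$nums[2], numeric(1)),
    kub = vapply(angleRows, function(e)
      if (length(e$nums) >= 4) e$nums[3] else 0, numeric(1)),
    rub0 = vapply(angleRows, function(e)
      if (length(e$nums) >= 4) e$nums[4] else 0, numeric(1)),
    stringsAsFactors = FALSE)
  if (any(anglesDf$ktheta < 0) || any(anglesDf$kub < 0))
    stop("negative angle force constant encountered")

  quadKey <- function(e) {
    t <- e$types
    if (t[2] > t[3] || (t[2] == t[3] && t[1] > t[4])) t <- rev(t)
    paste(t, collapse = " ")
  }
  dihRows <- dedupe(rows$DIHEDRALS, quadKey, "dihedral")
  dihDf <- data.frame(
    typeI = vapply(dihRows, function(e) e$types[1], character(1)),
    typeJ = vapply(dihRows, function(e) e$types[2], character(1)),
    typeK = vapply(dihRows, function(e) e$types[3], character(1)),
    typeL = vapply(dihRows, function(e) e$types[4], character(1)),
    kphi = vapply(dihRows, function(e) e$nums[1], numeric(1)),
    n = vapply(dihRows, function(e) as.integer(e$nums[2]), integer(1)),
    stringsAsFactors = FALSE)
  if (any(dihDf$kphi < 0)) stop("negative dihedral force constant encountered")

  impRows <- dedupe(rows$IMPROPER, quadKey, "improper")
  impDf <- data.frame(
    typeI = vapply(impRows, function(e) e$types[1], character(1)),
    typeJ = vapply(impRows, function(e) e$types[2], character(1)),
    typeK = vapply(impRows, function(e) e$types[3], character(1)),
    typeL = vapply(impRows, function(e) e$types[4], character(1)),
    komega = vapply(impRows, function(e) e$nums[1], numeric(1)),
    omega0 = vapply(impRows, function(e) e$nums[2], numeric(1)),
    stringsAsFactors = FALSE)
  if (any(impDf$komega < 0)) stop("negative improper force constant encountered")

  new("ForceFieldParameters", atoms = atomsDf, bonds = bondsDf,
      angles = anglesDf, dihedrals = dihDf, impropers = impDf,
      coulombConstant = COULOMB_KCAL)
}

#' Write a forcefield parameter file
#'
#' Serialises a [ForceFieldParameters-class] in the dialect that
#' [readForceFieldParameters()] parses; read-write round trips are exact.
#'
#' @param params a [ForceFieldParameters-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeForceFieldParameters <- function(params, path) {
  g <- function(x) sprintf("%.10g", x)
  out <- c("* forcefield parameters (kcal/mol, Angstrom, degrees, e, amu)",
           "", "ATOMS")
  a <- params@atoms
  out <- c(out, sprintf("%-5s %s %s", a$type, g(a$mass), g(a$charge)),
           "", "BONDS")
  b <- params@bonds
  out <- c(out, sprintf("%-4s %-4s %s %s", b$typeI, b$typeJ, g(b$kb), g(b$r0)),
           "", "ANGLES")
  an <- params@angles
  ub <- ifelse(an$kub > 0, sprintf(" %s %s", g(an$kub), g(an$rub0)), "")
  out <- c(out, sprintf("%-4s %-4s %-4s %s %s%s", an$typeI, an$typeJ,
                        an$typeK, g(an$ktheta), g(an$theta0), ub),
           "", "DIHEDRALS")
  d <- params@dihedrals
  out <- c(out, sprintf("%-4s %-4s %-4s %-4s %s %d", d$typeI, d$typeJ,
                        d$typeK, d$typeL, g(d$kphi), d$n),
           "", "IMPROPER")
  im <- params@impropers
  out <- c(out, sprintf("%-4s %-4s %-4s %-4s %s %s", im$typeI, im$typeJ,
                        im$typeK, im$typeL, g(im$komega), g(im$omega0)),
           "", "NONBONDED")
  out <- c(out, sprintf("%-5s %s %s", a$type, g(a$epsilon), g(a$rminHalf)),
           "", "END")
  writeLines(out, path)
  invisible(path)
}

ffCache <- new.env(parent = emptyenv())

#' The packaged default forcefield
#'
#' A compact CHARMM-style parameter set covering united-heavy-atom peptide
#' types (with polar hydroxyl hydrogens), the hydroxyapatite mineral types
#' and three-site water, read from the parameter file shipped in
#' `inst/extdata/nanobone.prm`.
#'
#' @return a [ForceFieldParameters-class]
#' @export
defaultForceField <- function() {
  if (is.null(ffCache$default)) {
    path <- system.file("extdata", "nanobone.prm", package = "nanobone",
                        mustWork = TRUE)
    ffCache$default <- readForceFieldParameters(path)
  }
  ffCache$default
}
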