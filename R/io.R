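# File interchange: PDB (via bio3d), extended XYZ and builder configs.

#' Write a model to a PDB file
#'
#' Protein chains (A/B alpha1, C alpha2) are written as ATOM records,
#' mineral (chain M) and water (chain W) atoms as HETATM.
#'
#' @param model a [CompositeModel-class], [TripleHelixModel-class] or
#'   [CrystalSlab-class]
#' @param file output path
#' @return the file path, invisibly
#' @export
writeModelPDB <- function(model, file) {
  at <- atoms(model)
  hetero <- at$chain %in% c("M", "W")
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = file, xyz = xyz,
                   type = ifelse(hetero, "HETATM", "ATOM"),
                   resno = at$resid, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   chain = at$chain, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)), elesy = at$element)
  invisible(file)
}

#' Read an atom table from a PDB file
#'
#' Inverse of [writeModelPDB()] at the level of the atom table: element,
#' atom name, residue name/number, chain and coordinates are recovered
#' (charges and forcefield types are not part of the PDB format and come
#' back empty).
#'
#' @param file PDB path
#' @return an atom table data.frame
#' @export
readModelPDB <- function(file) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  data.frame(element = a$elesy, name = a$elety, resname = a$resid,
             resid = as.integer(a$resno), chain = a$chain,
             type = "", charge = 0,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

#' Write coordinates as extended XYZ
#'
#' One frame per call: an atom-count line, a comment line carrying
#' `Properties=species:S:1:pos:R:3` plus any `metadata` as key=value pairs,
#' then element and Cartesian coordinates.
#'
#' @param model a model object or an atom table data.frame
#' @param file output path
#' @param metadata named list of scalar comment-line annotations
#' @param append append as an additional frame?
#' @return the file path, invisibly
#' @export
writeXYZ <- function(model, file, metadata = list(), append = FALSE) {
  at <- if (is.data.frame(model)) model else atoms(model)
  meta <- "Properties=species:S:1:pos:R:3"
  if (length(metadata))
    meta <- paste(meta, paste(sprintf("%s=%s", names(metadata),
                                      vapply(metadata, format, character(1))),
                              collapse = " "))
  lines <- c(sprintf("%d", nrow(at)), meta,
             sprintf("%-2s %16.8f %16.8f %16.8f", at$element,
                     at$x, at$y, at$z))
  if (append) cat(lines, file = file, sep = "\n", append = TRUE)
  else writeLines(lines, file)
  invisible(file)
}

#' Read an extended XYZ file
#'
#' @param file path
#' @param frame which frame to read (1-based) when the file holds several
#' @return data.frame with element, x, y, z
#' @export
readXYZ <- function(file, frame = 1L) {
  lines <- readLines(file)
  pos <- 1L
  for (f in seq_len(frame)) {
    if (pos > length(lines)) stop("frame ", frame, " not present in ", file)
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("malformed XYZ atom-count line at line ", pos)
    start <- pos + 2L
    pos <- start + n
  }
  block <- lines[start:(start + n - 1L)]
  parts <- strsplit(trimws(block), "\\s+")
  data.frame(element = vapply(parts, `[`, character(1), 1L),
             x = as.numeric(vapply(parts, `[`, character(1), 2L)),
             y = as.numeric(vapply(parts, `[`, character(1), 3L)),
             z = as.numeric(vapply(parts, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Build a composite model from a configuration file
#'
#' The configuration (YAML or JSON) may contain: `nRepeats` or
#' `totalResidues`, `replication` (3 integers), `orientation` (degrees),
#' `surface` ("Ca"/"OH"), `hydrated` (logical), `shellThickness`,
#' `gap`, `seed`, and a `crack` block (shape, center, dimensions,
#' orientation).  Omitted fields fall back to the package defaults.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list
#' @return a [CompositeModel-class]
#' @export
buildFromConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- modifyList(list(nRepeats = NULL, totalResidues = 1014,
                         replication = c(20, 2, 4), orientation = 0,
                         surface = "Ca", hydrated = FALSE,
                         shellThickness = 3, gap = 3, seed = 42),
                    config)
  helix <- buildCollagenHelix(nRepeats = cfg$nRepeats,
                              totalResidues = cfg$totalResidues)
  slab <- replicateCrystal(haUnitCell(), cfg$replication[1],
                           cfg$replication[2], cfg$replication[3])
  slab <- selectSurface(slab, cfg$surface)
  model <- assembleComposite(helix, slab, cfg$orientation, gap = cfg$gap)
  if (isTRUE(cfg$hydrated))
    model <- hydrate(model, cfg$shellThickness, seed = cfg$seed)
  if (!is.null(cfg$crack)) {
    ck <- cfg$crack
    model <- introduceCrack(model, crackGeometry(
      shape = ck$shape %||% "ellipsoid",
      center = ck$center %||% c(0, 0, 0),
      dimensions = ck$dimensions %||% c(0, 0, 0),
      orientation = ck$orientation %||% c(1, 0, 0)))
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
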