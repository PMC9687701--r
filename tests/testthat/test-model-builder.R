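# Atomistic model construction: hydroxyapatite cells and slabs, collagen
# helices, oriented composites, hydration, disease variants and cracks.

test_that("hydroxyapatite unit cell realises the Ca10(PO4)6(OH)2 basis", {
  cell <- haUnitCell()
  expect_equal(cell@a, 9.4214)
  expect_equal(cell@b, 2 * 9.4214)
  expect_equal(cell@c, 6.8814)
  expect_equal(cell@gamma, 120)
  expect_equal(nrow(cell@basisAtoms), 44L)
  counts <- table(cell@basisAtoms$element)
  expect_equal(unname(counts[c("Ca", "P", "O", "H")]),
               c(10L, 6L, 26L, 2L), ignore_attr = TRUE)
  fr <- as.matrix(cell@basisAtoms[, c("fx", "fy", "fz")])
  expect_true(all(fr >= 0 & fr < 1))
  # arbitrary valid parameters keep the stoichiometry
  c2 <- haUnitCell(a = 5, b = 7, c = 4, gamma = 100)
  expect_equal(unname(table(c2@basisAtoms$element)[c("Ca", "P", "O", "H")]),
               c(10L, 6L, 26L, 2L), ignore_attr = TRUE)
  expect_error(haUnitCell(a = 0), "invalid lattice parameter")
  expect_error(haUnitCell(gamma = 190), "invalid lattice parameter")
})

test_that("crystal replication conserves the 44 atoms/cell count", {
  cell <- haUnitCell()
  slab <- replicateCrystal(cell, 2, 1, 1)
  expect_equal(nAtoms(slab), 44L * 2L)
  # identity replication reproduces the basis in Cartesian form
  one <- replicateCrystal(cell, 1, 1, 1)
  expect_equal(nAtoms(one), 44L)
  lat <- rbind(c(cell@a, 0, 0),
               c(cell@b * cos(2 * pi / 3), cell@b * sin(2 * pi / 3), 0),
               c(0, 0, cell@c))
  cart <- as.matrix(cell@basisAtoms[, c("fx", "fy", "fz")]) %*% lat
  expect_equal(as.matrix(one@atoms[, c("x", "y", "z")]), cart,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(replicateCrystal(cell, 0, 1, 1), "integers >= 1")
  expect_error(replicateCrystal(cell, 1.5, 1, 1), "integers >= 1")
})

test_that("surface selection terminates the +Z face as requested", {
  slab <- replicateCrystal(haUnitCell(), 2, 1, 2)
  expect_equal(slab@exposedSurface, "Ca")
  topBand <- function(s, band = 0.4) {
    a <- s@atoms
    a[a$z > max(a$z) - band, ]
  }
  tb <- topBand(slab)
  expect_gt(mean(tb$type == "CAL"), 0.5)

  oh <- selectSurface(slab, "OH")
  expect_equal(oh@exposedSurface, "OH")
  tb <- topBand(oh)
  expect_gt(sum(tb$type %in% c("OHM", "HOM")), 0)
  expect_equal(sum(tb$type == "CAL"), 0L)
  # geometric check: hydroxyl columns have O over H along the cell axis
  a <- oh@atoms
  topO <- a[a$type == "OHM" & a$z > max(a$z) - 0.4, ]
  expect_gt(nrow(topO), 0)
  for (r in seq_len(nrow(topO))) {
    mates <- a[a$type == "HOM" &
               abs(a$x - topO$x[r]) < 0.1 & abs(a$y - topO$y[r]) < 0.1, ]
    expect_true(any(abs(mates$z - topO$z[r]) < 1.1))
  }
  # charge bookkeeping of the removed layers is logged
  expect_equal(oh@surfaceLog$requested, "OH")
  expect_true(is.finite(oh@surfaceLog$removedCharge))

  # idempotence: re-requesting the current termination changes nothing
  oh2 <- selectSurface(oh, "OH")
  expect_identical(oh2@atoms, oh@atoms)
  ca2 <- selectSurface(slab, "Ca")
  expect_identical(ca2@atoms, slab@atoms)
})

test_that("collagen helix honours sequence content and residue counts", {
  h1 <- buildCollagenHelix(nRepeats = 1)
  expect_equal(residueCount(h1), 89L)   # 30 + 30 + 29
  caA <- h1@atoms[h1@atoms$chain == "A" & h1@atoms$name == "CA", ]
  expect_equal(nrow(caA), 30L)
  expect_equal(sum(caA$resname == "GLY"), 10L)
  caC <- h1@atoms[h1@atoms$chain == "C" & h1@atoms$name == "CA", ]
  expect_equal(nrow(caC), 29L)

  # default configuration pads the repeats to 1014 residues in total
  h <- buildCollagenHelix()
  expect_equal(residueCount(h), 1014L)
  expect_true(all(is.finite(as.matrix(h@atoms[, c("x", "y", "z")]))))
  expect_gt(h@length, 0)
  expect_gt(h@diameter, 0)

  # peptide bonds connect consecutive residues within each chain
  bonds <- modelBonds(h1)
  at <- h1@atoms
  pept <- bonds[at$name[bonds[, 1]] == "C" & at$name[bonds[, 2]] == "N", ,
                drop = FALSE]
  expect_equal(nrow(pept), (30L - 1L) * 2L + (29L - 1L))
  expect_true(all(at$resid[pept[, 2]] - at$resid[pept[, 1]] == 1L))

  bad <- collagenChainSequence("alpha1")
  bad@residues[5] <- "XXX"
  expect_error(buildCollagenHelix(alpha1 = bad), "XXX")
  expect_error(buildCollagenHelix(nRepeats = 0), "nRepeats")
})

test_that("composite assembly places the helix at the requested angle and gap", {
  h <- tinyHelix()
  slab <- replicateCrystal(haUnitCell(), 2, 1, 1)
  for (th in c(0, 45, 90)) {
    m <- assembleComposite(h, slab, th, gap = 3)
    ax <- helixAxis(m)
    expect_equal(acos(pmin(1, abs(sum(ax * c(1, 0, 0))))) * 180 / pi, th,
                 tolerance = 1e-6)
    expect_equal(m@provenance$minHelixSlabDistance, 3, tolerance = 1e-6)
  }
  m0 <- assembleComposite(h, slab, 0)
  expect_equal(abs(sum(helixAxis(m0) * c(1, 0, 0))), 1, tolerance = 1e-9)
  m90 <- assembleComposite(h, slab, 90)
  expect_equal(sum(helixAxis(m90) * c(1, 0, 0)), 0, tolerance = 1e-9)
  expect_error(assembleComposite(h, slab, 120), "orientationDeg")
  expect_error(assembleComposite(h, slab, 0, gap = 0), "clash")
})

test_that("assembly is rigid: internal distances are preserved", {
  h <- tinyHelix()
  slab <- replicateCrystal(haUnitCell(), 2, 1, 1)
  m <- assembleComposite(h, slab, 30)
  set.seed(4)
  pick <- sample(nrow(h@atoms), 12)
  d0 <- dist(h@atoms[pick, c("x", "y", "z")])
  d1 <- dist(m@helix@atoms[pick, c("x", "y", "z")])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-8)
  ds0 <- dist(slab@atoms[1:10, c("x", "y", "z")])
  ds1 <- dist(m@slab@atoms[1:10, c("x", "y", "z")])
  expect_equal(as.numeric(ds1), as.numeric(ds0), tolerance = 1e-8)
  # atom-count conservation
  expect_equal(nAtoms(m), nrow(h@atoms) + nAtoms(slab))
})

test_that("hydration fills the shell at bulk density, deterministically", {
  m <- assembleComposite(tinyHelix(), replicateCrystal(haUnitCell(), 2, 1, 1),
                         0)
  expect_identical(hydrate(m, 0), m)
  expect_error(hydrate(m, -1), "shellThickness")

  h1 <- hydrate(m, 3, seed = 7)
  h2 <- hydrate(m, 3, seed = 7)
  expect_identical(h1@waters, h2@waters)
  expect_true(h1@hydrated)
  h3 <- hydrate(m, 3, seed = 8)
  expect_false(identical(h1@waters, h3@waters))
  # identical solute under different water seeds
  expect_identical(h1@helix@atoms, h3@helix@atoms)

  # water count within 10% of 0.0334 molecules/A^3 of the accessible
  # shell volume, estimated by an independent Monte-Carlo integration
  solute0 <- rbind(m@helix@atoms, m@slab@atoms)
  S0 <- as.matrix(solute0[, c("x", "y", "z")])
  lo <- apply(S0, 2, min) - 3; hi <- apply(S0, 2, max) + 3
  set.seed(99)
  mc <- cbind(runif(4e4, lo[1], hi[1]), runif(4e4, lo[2], hi[2]),
              runif(4e4, lo[3], hi[3]))
  d2 <- outer(rowSums(mc^2), rowSums(S0^2), "+") - 2 * mc %*% t(S0)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  vAcc <- prod(hi - lo) * mean(dmin <= 3 & dmin >= 2.4)
  nW <- max(h1@waters$resid)
  expect_equal(nW, 0.0334 * vAcc, tolerance = 0.1)

  # no water oxygen within the exclusion radius of the solute
  solute <- rbind(h1@helix@atoms, h1@slab@atoms)
  ow <- h1@waters[h1@waters$name == "OW", ]
  S <- as.matrix(solute[, c("x", "y", "z")])
  W <- as.matrix(ow[, c("x", "y", "z")])
  d2 <- outer(rowSums(W^2), rowSums(S^2), "+") - 2 * W %*% t(S)
  expect_gt(sqrt(min(d2)), 2.4 - 1e-9)
})

test_that("glycine substitution targets only GLY and leaves the rest intact", {
  h <- buildCollagenHelix(nRepeats = 1)
  nGly <- sum(h@atoms$resname == "GLY" & h@atoms$name == "CA" &
              h@atoms$chain == "A")
  expect_equal(nGly, 10L)

  sub <- applyGlySubstitution(h, "VAL", positions = "all")
  expect_equal(sum(sub@atoms$resname == "GLY"), 0L)
  expect_equal(sum(sub@atoms$chain == "A" & sub@atoms$resname == "VAL" &
                   sub@atoms$name == "CA"), 10L)

  # non-targeted residues bitwise unchanged
  keyOf <- function(a) paste(a$chain, a$resid, a$name)
  old <- h@atoms[h@atoms$resname != "GLY", ]
  new <- sub@atoms[match(keyOf(old), keyOf(sub@atoms)), ]
  expect_identical(old$x, new$x)
  expect_identical(old$y, new$y)
  expect_identical(old$z, new$z)
  expect_identical(old$charge, new$charge)
  # backbone of substituted residues preserved too
  oldG <- h@atoms[h@atoms$resname == "GLY", ]
  newG <- sub@atoms[match(keyOf(oldG), keyOf(sub@atoms)), ]
  expect_identical(oldG$x, newG$x)

  expect_error(
    applyGlySubstitution(h, "CYS",
                         positions = data.frame(chain = "A", resid = 1)),
    "not GLY")
  expect_error(applyGlySubstitution(h, "GLY"), "arg")
})

test_that("cracks remove exactly the atoms inside the void", {
  m <- toyComposite()
  noop <- introduceCrack(m, crackGeometry("ellipsoid", c(0, 0, 0),
                                          c(0, 0, 0)))
  expect_equal(nAtoms(noop), nAtoms(m))

  at <- atoms(m)
  ctr <- as.numeric(at[50, c("x", "y", "z")])
  ck <- crackGeometry("ellipsoid", ctr, c(2.5, 2.5, 2.5))
  cracked <- introduceCrack(m, ck)
  # brute-force point-in-ellipsoid scan
  P <- sweep(as.matrix(at[, c("x", "y", "z")]), 2, ctr)
  inside <- rowSums((P / 2.5)^2) < 1
  expect_equal(nAtoms(m) - nAtoms(cracked), sum(inside))
  # the centre atom itself is gone
  a2 <- atoms(cracked)
  expect_false(any(a2$x == ctr[1] & a2$y == ctr[2] & a2$z == ctr[3]))

  big <- crackGeometry("ellipsoid", colMeans(at[, c("x", "y", "z")]),
                       c(500, 500, 500))
  expect_error(introduceCrack(m, big), "50%")
})

test_that("PDB and XYZ round trips preserve content at format precision", {
  m <- toyComposite()
  pdb <- tempfile(fileext = ".pdb")
  writeModelPDB(m, pdb)
  back <- readModelPDB(pdb)
  at <- atoms(m)
  expect_equal(nrow(back), nrow(at))
  expect_equal(back$element, at$element)
  expect_equal(back$resname, at$resname)
  expect_equal(back$chain, at$chain)
  expect_equal(back$x, at$x, tolerance = 1e-3)
  expect_equal(back$y, at$y, tolerance = 1e-3)
  expect_equal(back$z, at$z, tolerance = 1e-3)

  xyz <- tempfile(fileext = ".xyz")
  writeXYZ(m, xyz, metadata = list(orientation = 0))
  bx <- readXYZ(xyz)
  expect_equal(bx$element, at$element)
  expect_equal(bx$x, at$x, tolerance = 1e-8)
  expect_equal(bx$z, at$z, tolerance = 1e-8)
})

test_that("configuration-driven builds honour the config fields", {
  cfg <- list(nRepeats = 1, replication = c(2, 1, 1), orientation = 30,
              surface = "Ca", hydrated = FALSE)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  m <- buildFromConfig(yml)
  expect_s4_class(m, "CompositeModel")
  expect_equal(orientation(m), 30)
  expect_equal(residueCount(m@helix), 89L)
  expect_false(isHydrated(m))
})
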