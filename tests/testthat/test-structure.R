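test_that("PositionScan tables round-trip through the label dialect", {
  tab <- data.frame(
    chain = "A", residue = 451:460,
    aa_ref = c("E", "G", "C", "D", "E", "K", "L", "M", "N", "P"),
    aa_alt = c("K", "R", "Y", "N", "Q", "E", "F", "T", "S", "L"),
    ddg = round(rnorm(10, 1, 2), 4), stringsAsFactors = FALSE)
  ddg <- new("DdgTable", table = tab, sourceStructure = "synthetic")
  f <- withr::local_tempfile(fileext = ".txt")
  writeFoldxPositionScan(ddg, f)
  back <- readFoldxPositionScan(f, sourceStructure = "synthetic")
  expect_equal(back@table, tab)

  # empty file -> empty table
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_equal(nrow(readFoldxPositionScan(empty)@table), 0L)

  # identity offset keeps residue numbers; offset shifts them
  one <- withr::local_tempfile(fileext = ".txt")
  writeLines("GLUA455K\t1.5", one)
  expect_equal(readFoldxPositionScan(one)@table$residue, 455L)
  expect_equal(readFoldxPositionScan(one, residueOffset = 10)@table$residue,
               465L)
  # 1-letter refs are accepted too
  writeLines("EA455K\t1.5", one)
  expect_equal(readFoldxPositionScan(one)@table$aa_ref, "E")
})

test_that("PositionScan parse errors carry line numbers, duplicates warn", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("GLUA455K\t1.5", "not a record at all"), f)
  expect_error(readFoldxPositionScan(f), "line 2")
  writeLines(c("GLUA455K\t1.5", "GLUA455K\t2.5"), f)
  expect_warning(tab <- readFoldxPositionScan(f), "duplicate")
  expect_equal(tab@table$ddg, 2.5)  # last wins

  # the package's 5-column TSV dialect is auto-detected
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresidue\taa_ref\taa_alt\tddg", "A\t455\tE\tK\t3.49"), g)
  expect_equal(readFoldxPositionScan(g)@table$ddg, 3.49)
})

test_that("destabilising calls use a strict threshold and are monotone", {
  expect_false(classifyDestabilising(2.0))
  expect_true(classifyDestabilising(3.49))
  expect_true(is.na(classifyDestabilising(NA_real_)))
  x <- seq(-2, 6, by = 0.5)
  calls <- classifyDestabilising(x)
  expect_true(all(diff(as.integer(calls)) >= 0))  # monotone in ddg
  # monotone (antitone) in threshold
  expect_true(classifyDestabilising(3, threshold = 1))
  expect_false(classifyDestabilising(3, threshold = 4))
})

test_that("bundled residue sets match their published definitions", {
  sets <- notchResidueSets()
  expect_true(inResidueSet(455, sets$notch1_calcium))
  expect_true(inResidueSet(444, sets$notch1_interface))
  expect_false(inResidueSet(444, residueSet("empty", integer())))
  expect_length(sets$notch1_interface@residues, 29L)
  expect_identical(sets$notch1_calcium@residues,
                   c(412L, 413L, 415L, 431L, 432L, 435L, 452L, 453L, 455L,
                     469L, 470L))
  expect_length(sets$notch2_interface@residues, 16L)
  expect_length(sets$notch2_calcium@residues, 11L)
  # checksum guard on the shipped fixture
  f <- system.file("extdata", "residue_sets_notch.yaml",
                   package = "SomaticSelect")
  expect_identical(unname(tools::md5sum(f)), RESIDUE_SET_FIXTURE_MD5)
})

test_that("minimum distance to target is the brute-force pair minimum", {
  mk <- function(coords, targets) {
    new("StructureModel",
        atoms = data.frame(
          chain = c(rep("A", nrow(coords)), rep("L", nrow(targets))),
          resno = c(seq_len(nrow(coords)), seq_len(nrow(targets))),
          resid = "ALA", elety = "CA",
          x = c(coords[, 1], targets[, 1]),
          y = c(coords[, 2], targets[, 2]),
          z = c(coords[, 3], targets[, 3]),
          isTarget = c(rep(FALSE, nrow(coords)), rep(TRUE, nrow(targets))),
          stringsAsFactors = FALSE),
        targetSelection = "chain L")
  }
  # 3-4-5 triangle and coincident atoms
  s <- mk(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))
  expect_equal(minDistanceToTarget(s, 1), 5)
  expect_equal(minDistanceToTarget(mk(rbind(c(1, 2, 3)), rbind(c(1, 2, 3))),
                                   1), 0)
  expect_error(minDistanceToTarget(s, 99), "absent")

  # toy structure vs exhaustive pairwise oracle
  set.seed(21)
  s5 <- simulateStructure(5, seed = 21, targetDistance = 4)
  a <- s5@atoms
  tgt <- a[a$isTarget, ]
  for (r in 1:5) {
    res <- a[!a$isTarget & a$resno == r, ]
    oracle <- min(sqrt(outer(res$x, tgt$x, "-")^2 +
                         outer(res$y, tgt$y, "-")^2 +
                         outer(res$z, tgt$z, "-")^2))
    expect_equal(minDistanceToTarget(s5, r), oracle)
  }
})

test_that("distances are invariant under rigid-body transformation", {
  s <- simulateStructure(8, seed = 3, targetDistance = 6)
  d0 <- vapply(1:8, function(r) minDistanceToTarget(s, r), numeric(1))
  ang <- c(0.3, 1.2, 2.5)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  xyz <- as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
  s@atoms$x <- xyz[, 1] + 11.3
  s@atoms$y <- xyz[, 2] - 4.2
  s@atoms$z <- xyz[, 3] + 0.7
  d1 <- vapply(1:8, function(r) minDistanceToTarget(s, r), numeric(1))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("withinDistance is inclusive at the cutoff", {
  mk1 <- function(d) new("StructureModel",
    atoms = data.frame(chain = c("A", "L"), resno = c(1L, 1L),
                       resid = "ALA", elety = "CA",
                       x = c(0, d), y = 0, z = 0,
                       isTarget = c(FALSE, TRUE), stringsAsFactors = FALSE),
    targetSelection = "chain L")
  expect_true(withinDistance(mk1(7.3), 1))
  expect_true(withinDistance(mk1(8.0), 1))
  expect_false(withinDistance(mk1(18.7), 1))
})

test_that("attachFeatures scores entries and flags missing coverage", {
  tx <- simulateTranscript(12, seed = 4)
  cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
  ddg <- simulateDdg(cat, seed = 5)
  cat2 <- attachFeatures(cat, ddg = ddg,
                         residueSets = list(site = residueSet("s", 3:5)))
  e <- catalogueEntries(cat2)
  expect_true(all(!is.na(e$ddg[e$included])))  # full coverage -> no unscored
  expect_true(all(e$site == (e$residue %in% 3:5)))

  # remove one residue from the ddG table -> its entries become unscored
  ddg2 <- new("DdgTable", table = ddg@table[ddg@table$residue != 6, ],
              sourceStructure = "synthetic")
  expect_message(cat3 <- attachFeatures(cat, ddg = ddg2), "unscored")
  e3 <- catalogueEntries(cat3)
  expect_true(all(is.na(e3$ddg[e3$residue == 6])))
  expect_true(all(!is.na(e3$ddg[e3$included & e3$residue != 6])))

  # a structure missing one residue leaves its entries distance-unscored
  s <- simulateStructure(12, seed = 6)
  s@atoms <- s@atoms[!(s@atoms$resno == 7 & !s@atoms$isTarget), ]
  expect_message(cat4 <- attachFeatures(cat, structure = s), "unscored")
  e4 <- catalogueEntries(cat4)
  expect_true(all(is.na(e4$dist_target[e4$residue == 7])))
  expect_equal(sum(is.na(e4$dist_target[e4$included])),
               sum(e4$included & e4$residue == 7))
})

test_that("feature columns survive catalogue export and import", {
  cat <- maskingCatalogue(20, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCatalogue(cat, f)
  back <- readCatalogue(f, regionId = regionId(cat))
  e0 <- catalogueEntries(cat)
  e1 <- catalogueEntries(back)
  expect_equal(e1$prob, e0$prob, tolerance = 1e-12)
  expect_identical(e1$strong, e0$strong)
  expect_equal(e1$ddg, e0$ddg, tolerance = 1e-9)
})

test_that("toy structures survive a PDB round trip at format precision", {
  s <- simulateStructure(6, seed = 8, targetDistance = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePdb(s, f)
  back <- readStructurePdb(f, targetChain = "L")
  expect_equal(nrow(back@atoms), nrow(s@atoms))
  expect_equal(back@atoms$x, s@atoms$x, tolerance = 1e-3)
  expect_equal(back@atoms$y, s@atoms$y, tolerance = 1e-3)
  expect_equal(back@atoms$z, s@atoms$z, tolerance = 1e-3)
  expect_equal(minDistanceToTarget(back, 1), 5, tolerance = 1e-2)
})
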