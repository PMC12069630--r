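test_that("triangle surfaces round-trip bit-compatibly", {
  mesh <- generateIcosphere(1)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeSurface(mesh, p1)
  back <- readSurface(p1)
  expect_equal(meshVertices(back), unname(meshVertices(mesh)), tolerance = 1e-7)
  expect_identical(meshFaces(back), meshFaces(mesh))
  # second read of a re-written file is bit-identical (determinism)
  writeSurface(back, p2)
  writeSurface(back, p1)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  again <- readSurface(p2)
  expect_identical(meshVertices(again), meshVertices(back))
})

test_that("a handcrafted surface file parses per the published byte layout", {
  # 3 vertices / 1 face, assembled field by field: int24 magic 0xFFFFFE,
  # comment terminated by two newlines, big-endian counts, float32 xyz,
  # int32 0-based faces.  Layout cross-checked against an independent
  # reference reader of the format.
  p <- withr::local_tempfile()
  con <- file(p, "wb")
  writeBE(con, raws = c(0xff, 0xff, 0xfe))
  writeBin(charToRaw("test\n\n"), con)
  writeBE(con, ints = c(3L, 1L))
  writeBE(con, floats = c(0, 0, 0, 1, 0, 0, 0, 1, 0))
  writeBE(con, ints = c(0L, 1L, 2L))
  close(con)
  mesh <- readSurface(p)
  expect_equal(nVertices(mesh), 3L)
  expect_equal(nFaces(mesh), 1L)
  expect_equal(meshVertices(mesh), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_identical(meshFaces(mesh), rbind(c(1L, 2L, 3L)))
})

test_that("surface reader rejects wrong magic and truncated payloads", {
  p <- withr::local_tempfile()
  writeBin(as.raw(rep(0, 32)), p)
  expect_error(readSurface(p), "unrecognized surface format")
  # byte-swapped (little-endian) magic is foreign too
  con <- file(p, "wb"); writeBE(con, raws = c(0xfe, 0xff, 0xff)); close(con)
  expect_error(readSurface(p), "unrecognized surface format")
  # valid header, missing coordinates
  con <- file(p, "wb")
  writeBE(con, raws = c(0xff, 0xff, 0xfe))
  writeBin(charToRaw("x\n\n"), con)
  writeBE(con, ints = c(100L, 50L))
  writeBE(con, floats = c(1, 2, 3))
  close(con)
  expect_error(readSurface(p), "corrupt surface file")
})

test_that("a mesh violating its invariants cannot be written", {
  mesh <- triangleMesh()
  mesh@faces <- rbind(c(1L, 2L, 7L))    # index beyond N
  expect_error(writeSurface(mesh, withr::local_tempfile()), "out of range")
})

test_that("curv files round-trip to float32 precision", {
  p <- withr::local_tempfile()
  set.seed(4)
  v <- rnorm(100)
  writeCurv(v, p, nFaces = 196L)
  expect_equal(readCurv(p), v, tolerance = 1e-7)
  expect_equal(readCurv(p, expectedN = 100L), v, tolerance = 1e-7)
  expect_error(readCurv(p, expectedN = 99L), "length mismatch")
  writeCurv(rep(1.5, 10), p)
  expect_equal(mean(readCurv(p)), 1.5)
  expect_error(writeCurv(c(1, NA), p), "finite")
})

test_that("a handcrafted minimal curv file reproduces its two values", {
  # int24 magic 0xFFFFFF, big-endian vnum/fnum/vals_per_vertex, float32
  # payload; cross-checked against an independent reference reader.
  p <- withr::local_tempfile()
  con <- file(p, "wb")
  writeBE(con, raws = c(0xff, 0xff, 0xff), ints = c(2L, 0L, 1L),
          floats = c(-0.25, 3.5))
  close(con)
  expect_equal(readCurv(p), c(-0.25, 3.5))
})

test_that("curv reader rejects the old two-int dialect and byte-swapped files", {
  p <- withr::local_tempfile()
  con <- file(p, "wb")
  writeBE(con, raws = c(0x00, 0x00, 0x02), ints = 0L, floats = c(1, 2))
  close(con)
  expect_error(readCurv(p), "unrecognized curv format")
})

test_that("annot files round-trip labels, names and colours exactly", {
  set.seed(7)
  lab <- sample(0:2, 60, replace = TRUE)
  lab[c(3, 41)] <- -1L
  tab <- data.frame(class = 0:2, name = c("precentral", "postcentral", "insula"),
                    red = c(60, 20, 200), green = c(20, 220, 80),
                    blue = c(220, 20, 60), structureId = c(5L, 9L, 2L))
  parc <- Parcellation(lab, tab)
  p <- withr::local_tempfile()
  writeAnnot(parc, p)
  back <- readAnnot(p)
  expect_identical(parcLabels(back), as.integer(lab))
  expect_identical(labelTable(back)$name, tab$name)
  expect_identical(labelTable(back)$structureId, tab$structureId)
  # write -> read -> write -> read is idempotent on labels and names
  p2 <- withr::local_tempfile()
  writeAnnot(back, p2)
  again <- readAnnot(p2)
  expect_identical(parcLabels(again), parcLabels(back))
  expect_identical(labelTable(again)$name, labelTable(back)$name)
})

test_that("annotation values with no colortable entry map to the ignore index", {
  # patch one vertex's packed value to a colour absent from the table
  p <- withr::local_tempfile()
  writeAnnot(Parcellation(rep(c(0L, 1L), 5)), p)
  raw <- readBin(p, "raw", file.size(p))
  # vertex 0's annotation value is bytes 9..12 (after count and vertex id)
  raw[9:12] <- as.raw(c(0x00, 0xBA, 0xDB, 0xAD))
  writeBin(raw, p)
  back <- readAnnot(p)
  expect_identical(parcLabels(back)[1], -1L)
  expect_identical(parcLabels(back)[-1], rep(c(1L, 0L), length.out = 9))
})

test_that("a 31-region annot yields a 31-entry label table", {
  k <- 31L
  lab <- rep(seq_len(k) - 1L, length.out = 200)
  p <- withr::local_tempfile()
  writeAnnot(Parcellation(lab), p)
  back <- readAnnot(p)
  expect_identical(nClasses(back), k)
  expect_identical(parcLabels(back), lab)
})

test_that("annot reader rejects files without a colortable and byte-swapped input", {
  p <- withr::local_tempfile()
  con <- file(p, "wb")
  writeBE(con, ints = c(2L, 0L, 1L, 1L, 2L, 0L))   # 2 vertices, ctab flag 0
  close(con)
  expect_error(readAnnot(p), "colortable unsupported")
  # a byte-swapped vertex count is implausible for the file size
  con <- file(p, "wb")
  writeBin(as.integer(2L), con, size = 4L, endian = "little")
  writeBE(con, ints = c(0L, 1L, 1L, 2L))
  close(con)
  expect_error(readAnnot(p), "corrupt annot")
})

test_that("datasets export to FreeSurfer formats and import back", {
  spec <- syntheticSpec(level = 1L, nParcels = 3L, seed = 5L)
  subjects <- makeDataset(2, spec)
  dir <- withr::local_tempdir()
  manifest <- exportDataset(subjects, dir, force = TRUE)
  expect_equal(nrow(manifest), 2L)
  back <- importDataset(dir)
  expect_equal(length(back), 2L)
  expect_identical(back[[1]]@labels, subjects[[1]]@labels)
  expect_equal(back[[2]]@features, subjects[[2]]@features, tolerance = 1e-6)
  expect_equal(meshVertices(back[[1]]@mesh), unname(meshVertices(subjects[[1]]@mesh)),
               tolerance = 1e-7)
})
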