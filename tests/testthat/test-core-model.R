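test_that("PDB structures load with correct topology and C-alpha mask", {
  pdb <- system.file("extdata", "toy3.pdb", package = "unfoldscape")
  s <- loadStructure(pdb)
  expect_equal(nAtoms(s$topology), 12L)
  expect_equal(sum(calphaMask(s$topology)), 3L)
  expect_equal(nResidues(s$topology), 3L)
  expect_true(all(s$topology@masses > 0))
  expect_true(all(diff(s$topology@residueIndex) >= 0))
  expect_equal(dim(s$coords), c(12L, 3L))
  expect_error(loadStructure(tempfile("nope")), "not found")
})

test_that("a residue lacking CA is excluded from the mask, atoms kept", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       3.300   0.000   0.000  1.00  0.00           N",
    "ATOM      4  C   GLY A   2       4.700   0.000   0.000  1.00  0.00           C",
    "ATOM      5  N   SER A   3       6.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  SER A   3       7.400   0.000   0.000  1.00  0.00           C",
    "END"
  ), f)
  s <- loadStructure(f)
  expect_equal(nAtoms(s$topology), 6L)
  expect_equal(sum(calphaMask(s$topology)), 2L)
  expect_equal(s$topology@residueIndex[calphaMask(s$topology)], c(1L, 3L))
})

test_that("multi-model selection and trajectory round trips work", {
  toy <- makeToyNative(24)
  tr <- makeNativeTrajectory(toy, nFrames = 5, noiseSd = 0.2, seed = 4)
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(tr, f)
  # model selection
  s5 <- loadStructure(f, model = 5)
  expect_lt(max(abs(s5$coords - coords(tr, frame = 5))), 6e-4)
  expect_error(loadStructure(f, model = 6), "model")
  # round trip at format precision
  tr2 <- loadTrajectory(f, topology(tr), frameInterval = frameInterval(tr))
  expect_equal(nFrames(tr2), 5L)
  expect_lt(max(abs(coords(tr2) - coords(tr))), 6e-4)
})

test_that("stride subsamples frames, scales time, and composes", {
  toy <- makeToyNative(24)
  tr <- makeNativeTrajectory(toy, nFrames = 12, noiseSd = 0.2,
                             frameInterval = 0.5, seed = 9)
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(tr, f)
  t2 <- loadTrajectory(f, topology(tr), stride = 2, frameInterval = 0.5)
  expect_equal(nFrames(t2), 6L)
  expect_equal(frameInterval(t2), 1.0)
  expect_lt(max(abs(coords(t2) - coords(tr)[seq(1, 12, 2), , ])), 6e-4)
  # stride a then stride b equals stride a*b on frame indices
  t6 <- loadTrajectory(f, topology(tr), stride = 6, frameInterval = 0.5)
  f2 <- tempfile(fileext = ".pdb")
  writeTrajectory(t2, f2)
  t23 <- loadTrajectory(f2, topology(tr), stride = 3, frameInterval = 1.0)
  expect_equal(coords(t23), coords(t6), tolerance = 1e-6)
  # atom-count mismatch
  expect_error(loadTrajectory(f, makeToyNative(30)$topology), "mismatch")
})

test_that("tables round-trip losslessly in CSV and JSON", {
  df <- data.frame(
    t = c(0, 1.25), rmsd = c(0, pi * 1e5), label = c("a", "b"),
    stringsAsFactors = FALSE
  )
  for (fmt in c("csv", "json")) {
    f <- tempfile(fileext = paste0(".", fmt))
    writeTable(df, f, format = fmt)
    back <- readTable(f, format = fmt)
    expect_equal(back$rmsd, df$rmsd, tolerance = 1e-12)
    expect_equal(back$t, df$t, tolerance = 1e-12)
    expect_equal(back$label, df$label)
  }
  # empty record list: header-only file
  f <- tempfile(fileext = ".csv")
  writeTable(df[0, ], f)
  expect_equal(nrow(readTable(f)), 0L)
  expect_equal(names(readTable(f)), names(df))
  # NaN/NA serialized as explicit null token, re-read as missing
  f2 <- tempfile(fileext = ".csv")
  writeTable(data.frame(x = c(1, NaN)), f2)
  expect_true(is.na(readTable(f2)$x[2]))
  f3 <- tempfile(fileext = ".json")
  writeTable(data.frame(x = c(1, NaN)), f3, format = "json")
  expect_true(is.na(readTable(f3, format = "json")$x[2]))
})
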