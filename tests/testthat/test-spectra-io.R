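test_that("spectrum tables are parsed with comments, blanks and commas handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "", "1204.48 2.0", "3001.0,1.5"), path)
  sp <- read_spectrum_table(path, "mol1")
  expect_s3_class(sp, "vib_spectrum")
  expect_equal(sp$modes$wavenumber, c(1204.48, 3001.0))
  expect_equal(sp$modes$intensity, c(2.0, 1.5))

  writeLines(character(0), path)
  expect_equal(nrow(read_spectrum_table(path, "empty")$modes), 0)
})

test_that("spectrum validation rejects bad modes and names the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1204.48 -1.0", path)
  expect_error(read_spectrum_table(path, "m"), "negative intensity")

  writeLines(c("100 1", "abc 2"), path)
  expect_error(read_spectrum_table(path, "m"), ":2:")

  writeLines("1204.48", path)
  expect_error(read_spectrum_table(path, "m"), "at least 2 fields")

  expect_error(vib_spectrum(100, NaN, "m"), "non-finite")
  expect_error(vib_spectrum(100, 1, ""), "non-empty")
})

test_that("imaginary frequencies fail by default and drop with a warning when permitted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("-15.2 0.5", "1204.48 2.0"), path)
  expect_error(read_spectrum_table(path, "m"), "imaginary")
  expect_warning(sp <- read_spectrum_table(path, "m", drop_imaginary = TRUE),
                 "dropped 1 imaginary")
  expect_equal(sp$modes$wavenumber, 1204.48)
})

test_that("write/read round trip reproduces all mode pairs bit-identically", {
  set.seed(41)
  for (rep in 1:10) {
    sp <- random_spectrum(30, sprintf("m%02d", rep))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_spectrum_table(sp, path)
    back <- read_spectrum_table(path, sp$molecule_id)
    expect_identical(back$modes$wavenumber, sp$modes$wavenumber)
    expect_identical(back$modes$intensity, sp$modes$intensity)
  }
})

gamess_fixture <- function(freq_lines, inten_lines) {
  c("          NORMAL COORDINATE ANALYSIS IN THE HARMONIC APPROXIMATION", "",
    "                          1           2           3",
    freq_lines, "       SYMMETRY:     A           A           A", inten_lines,
    "", " ...... END OF NORMAL MODES ......")
}

test_that("GAMESS logs yield one mode per listed frequency", {
  path <- withr::local_tempfile(fileext = ".log")
  writeLines(gamess_fixture(
    "     FREQUENCY:       100.00     1204.50     3001.00",
    "  IR INTENSITY:      0.10000     2.00000     1.50000"), path)
  sp <- read_gamess_log(path, "fix")
  expect_equal(sp$modes$wavenumber, c(100.0, 1204.5, 3001.0))
  expect_equal(sp$modes$intensity, c(0.1, 2.0, 1.5))
})

test_that("GAMESS parsing enforces block structure and strictness", {
  path <- withr::local_tempfile(fileext = ".log")
  # missing intensity line
  writeLines(gamess_fixture(
    "     FREQUENCY:       100.00     1204.50     3001.00", character(0)), path)
  expect_error(read_gamess_log(path, "fix"), "frequencies but 0")
  # no frequency block at all
  writeLines("nothing to see here", path)
  expect_error(read_gamess_log(path, "fix"), "no recognizable FREQUENCY")
  # imaginary marker becomes a negative wavenumber, rejected by default
  writeLines(gamess_fixture(
    "     FREQUENCY:        45.12 I      1204.50     3001.00",
    "  IR INTENSITY:      0.10000     2.00000     1.50000"), path)
  expect_error(read_gamess_log(path, "fix"), "imaginary")
  expect_warning(sp <- read_gamess_log(path, "fix", drop_imaginary = TRUE))
  expect_equal(sp$modes$wavenumber, c(1204.5, 3001.0))
})

test_that("manifests resolve relative paths and check their columns", {
  dir <- withr::local_tempdir()
  writeLines("100 1", file.path(dir, "a.tsv"))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("molecule_id,spectrum_path,label", "a,a.tsv,agonist"), manifest)
  mf <- read_manifest(manifest)
  expect_true(file.exists(mf$spectrum_path[1]))
  expect_equal(levels(mf$label), "agonist")

  writeLines(c("molecule_id,spectrum_path", "a,a.tsv"), manifest)
  expect_error(read_manifest(manifest), "missing column")
  writeLines(c("molecule_id,spectrum_path,label", "a,a.tsv,agonist",
               "a,a.tsv,agonist"), manifest)
  expect_error(read_manifest(manifest), "duplicate")
})
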