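test_that("TMS groups are counted from the structure", {
  expect_identical(count_tms_groups("CCO"), 0L)
  expect_identical(count_tms_groups("CO[Si](C)(C)C"), 1L)
  expect_identical(count_tms_groups("C(CO[Si](C)(C)C)O[Si](C)(C)C"), 2L)
  # tetramethylsilane has no heteroatom link, so it is not a TMS group
  expect_identical(count_tms_groups("C[Si](C)(C)C"), 0L)
  expect_error(count_tms_groups("not-a-smiles(("), "invalid SMILES")
})

test_that("monoisotopic masses come from the most abundant isotopes", {
  expect_equal(monoisotopic_mass("C"), 16.0313, tolerance = 1e-3)
  expect_equal(monoisotopic_mass("O"), 18.01056, tolerance = 1e-4)
  # additivity of the formula sum
  expect_equal(mass_from_formula("C2H6O") + mass_from_formula("CH4"),
               mass_from_formula("C3H10O"), tolerance = 1e-9)
  expect_error(mass_from_formula("C2U1"), "U")
})

test_that("mass is invariant under SMILES respelling of the same molecule", {
  spellings <- c("CCO", "OCC", "C(O)C")
  expect_equal(monoisotopic_mass(spellings),
               rep(monoisotopic_mass("CCO"), 3), tolerance = 1e-9)
})

test_that("masses agree with the OpenBabel exact-mass oracle", {
  lib <- fixture_gen()$library
  mols <- tmsri:::parse_molecules(lib$smiles[1:50])
  oracle <- ChemmineOB::exactMass_OB(mols)
  expect_equal(lib$monoisotopic_mass[1:50], oracle, tolerance = 5e-3,
               ignore_attr = TRUE)
})

test_that("library validation discards bad records and reports why", {
  recs <- tiny_records()
  recs$smiles[2] <- ""          # missing SMILES
  recs$ri[3] <- NA              # missing RI
  recs$n_tms[4] <- 2L           # conflicts with structure (1 TMS)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(tf, recs)
  lib <- read_library(tf, "csv")
  expect_s3_class(lib, "derivative_library")
  expect_equal(nrow(lib), 3)
  d <- attr(lib, "discards")
  expect_setequal(d$record_id, c("eth1", "gly0", "gly1"))
  expect_match(d$reason[d$record_id == "eth1"], "missing SMILES")
  expect_match(d$reason[d$record_id == "gly0"], "RI")
  expect_match(d$reason[d$record_id == "gly1"], "conflicts")
})

test_that("an all-invalid or empty table is an empty-library error", {
  tf <- withr::local_tempfile(fileext = ".csv")
  recs <- tiny_records()[0, ]
  write_tiny_csv(tf, recs)
  expect_error(read_library(tf, "csv"), "empty library")
  recs <- tiny_records()[1:2, ]
  recs$smiles <- NA
  write_tiny_csv(tf, recs)
  expect_error(read_library(tf, "csv"), "empty library")
  expect_error(read_library("no/such/file.csv"), "cannot read")
})

test_that("csv round trip preserves records, ids and RI values", {
  lib <- fixture_gen()$library
  tf <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, tf, "csv")
  back <- read_library(tf, "csv")
  expect_equal(nrow(back), nrow(lib))
  expect_identical(back$record_id, lib$record_id)
  expect_equal(back$ri, lib$ri, tolerance = 1e-6)
  expect_identical(back$n_tms, lib$n_tms)
  expect_equal(nrow(attr(back, "discards")), 0)
})

test_that("SDF input with RI and id tags is read", {
  sdf <- ChemmineOB::convertFormat("SMILES", "SDF", "CCO ethanol\nOCCO glycol")
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n")[[1]]
  tags <- c("> <RECORD_ID>\ns1\n\n> <BASE_ID>\nb1\n\n> <RI>\n450.5\n\n$$$$",
            "> <RECORD_ID>\ns2\n\n> <BASE_ID>\nb2\n\n> <RI>\n701.25\n\n$$$$")
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(paste0(blocks, tags), tf)
  lib <- read_library(tf, "sdf")
  expect_equal(nrow(lib), 2)
  expect_setequal(lib$record_id, c("s1", "s2"))
  expect_equal(sort(lib$ri), c(450.5, 701.25))
  expect_equal(lib$n_tms, c(0L, 0L))
})

test_that("MSP spectra parse, sort and round trip", {
  tf <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: rec1", "Num Peaks: 2", "147 500; 73 999", ""), tf)
  sp <- read_spectra(tf)
  expect_length(sp, 1)
  expect_equal(sp$rec1$mz, c(73, 147))        # sorted by m/z
  expect_equal(sp$rec1$intensity, c(999, 500))

  writeLines(character(0), tf)
  expect_length(read_spectra(tf), 0)

  writeLines(c("Name: a", "Num Peaks: 1", "73 1", "",
               "Name: a", "Num Peaks: 1", "74 1", ""), tf)
  expect_error(read_spectra(tf), "duplicate spectrum id.*a")

  writeLines(c("Name: b", "Num Peaks: 1", "73 banana"), tf)
  expect_error(read_spectra(tf), "malformed peak line 3")
})

test_that("generated spectra survive an MSP round trip keyed by record id", {
  gen <- fixture_gen()
  spectra <- fixture_spectra()
  tf <- withr::local_tempfile(fileext = ".msp")
  write_msp(spectra, tf)
  back <- read_spectra(tf)
  expect_setequal(names(back), gen$library$record_id)
  id <- gen$library$record_id[5]
  expect_equal(back[[id]]$mz, spectra[[id]]$mz)
  expect_equal(back[[id]]$intensity, spectra[[id]]$intensity,
               tolerance = 1e-6)
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(ms_spectrum(c(73, -1), c(1, 1)), "> 0")
  expect_error(ms_spectrum(73, -5), ">= 0")
  expect_error(ms_spectrum(c(73, 147), c(0, 0)), "no peak")
  sp <- ms_spectrum(c(100, 100, 50), c(1, 2, 3))  # duplicate bins merge
  expect_equal(sp$mz, c(50, 100))
  expect_equal(sp$intensity, c(3, 3))
})
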