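test_that("dataset constructor validates and sorts records", {
  ds <- isotherm_dataset("Nsp1", "NTF2", gamma_FG = 4.9,
                         c_NTR = c(1, 0.1, 10), gamma_NTR = c(2, 1, 3))
  expect_s3_class(ds, "isotherm_dataset")
  expect_equal(ds$records$c_NTR, c(0.1, 1, 10))
  expect_false(ds$full_range)  # only 3 points, does not reach 0.05
  expect_error(isotherm_dataset("Nsp1", "NTF2", 4.9, c(-1, 1), c(0, 1)),
               "row 1")
  expect_error(isotherm_dataset("Nsp1", "NTF2", 0, 1, 1), "gamma_FG")
  expect_error(isotherm_dataset("Nope", "NTF2", 1, 1, 1))
})

test_that("full-range flag is inferred from the concentration grid", {
  full <- noiseless_dataset()
  expect_true(full$full_range)
  part <- noiseless_dataset(conc = titration_grid()[titration_grid() >= 0.2])
  expect_false(part$full_range)
})

test_that("isotherm tables round-trip through the sectioned CSV", {
  fam <- generate_dataset_family(n_datasets = 4L, seed = 99)
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_tables(fam, path)
  back <- read_isotherm_tables(path)
  expect_length(back, 4L)
  for (i in seq_along(fam)) {
    expect_equal(back[[i]]$fg_domain, fam[[i]]$fg_domain)
    expect_equal(back[[i]]$ntr, fam[[i]]$ntr)
    expect_equal(back[[i]]$gamma_FG, fam[[i]]$gamma_FG)
    expect_equal(back[[i]]$full_range, fam[[i]]$full_range)
    expect_equal(back[[i]]$records$c_NTR, fam[[i]]$records$c_NTR)
    expect_equal(back[[i]]$records$gamma_NTR, fam[[i]]$records$gamma_NTR)
    expect_equal(back[[i]]$records$thickness, fam[[i]]$records$thickness)
  }
  # canonical formatting: write(read(file)) is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_tables(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("malformed tables raise informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dataset,fg_domain,gamma_FG_pmol_cm2,full_range",
               "1,Nsp1,4.9,TRUE",
               "c_NTR_uM,Gamma_NTR_pmol_cm2", "1,0.5", "2,0.8", "3,1.0"),
             path)
  expect_error(read_isotherm_tables(path), "ntr")
  writeLines(c("dataset,fg_domain,ntr,gamma_FG_pmol_cm2,full_range",
               "1,Nsp1,NTF2,4.9,TRUE",
               "c_NTR_uM,thickness_nm", "1,30"), path)
  expect_error(read_isotherm_tables(path), "Gamma_NTR_pmol_cm2")
  writeLines(c("dataset,fg_domain,ntr,gamma_FG_pmol_cm2,full_range",
               "1,Nsp1,NTF2,4.9,TRUE",
               "c_NTR_uM,Gamma_NTR_pmol_cm2", "-1,0.5", "1,0.6", "2,0.7"),
             path)
  expect_error(read_isotherm_tables(path), "row")
  expect_error(read_isotherm_tables("no/such/file.csv"), "not found")
})
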