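test_that("gas constant is consistent with kB * N_A and units convert exactly", {
  pc <- phys_constants()
  expect_equal(pc$R_J, pc$kB * pc$N_A, tolerance = 1e-10)
  expect_equal(convert_energy(1, "hartree", "kcal_per_mol"), 627.5095)
  expect_identical(convert_energy(0, "hartree", "kJ_per_mol"), 0)
  x <- c(-0.51, 2.25, 1e3)
  expect_equal(convert_energy(convert_energy(x, "hartree", "kcal_per_mol"),
                              "kcal_per_mol", "hartree"),
               x, tolerance = 1e-12)
  expect_error(convert_energy(1, "eV", "hartree"))
})

test_that("medium constructor enforces its invariants", {
  expect_error(medium("water", temperature = -1), "temperature")
  expect_error(medium("water", viscosity = 0), "viscosity")
  expect_error(medium("water", pH = 15), "pH")
  w <- default_media()$water
  expect_true(w$is_polar)
  expect_equal(w$pH, 7.4)
  expect_equal(default_media()$gas$temperature, 298.15)
})

test_that("species tables load with unit conversion and validate roles", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,compound,role,medium,charge,enthalpy,gibbs_energy",
               "proton,ref,proton,gas,1,-0.010000,-0.012"), f)
  sp <- read_species_table(f, units = "hartree")
  expect_equal(sp$enthalpy, -6.275095)

  writeLines("name,compound,role,medium,charge,enthalpy,gibbs_energy", f)
  expect_identical(nrow(read_species_table(f)), 0L)

  writeLines(c("name,compound,role,medium,charge,enthalpy,gibbs_energy",
               "a,X,anion,gas,0,-1.0,-1.0"), f)
  expect_error(read_species_table(f), "role/charge mismatch")

  writeLines(c("name,compound,role,medium,enthalpy,gibbs_energy",
               "a,X,neutral,gas,-1.0,-1.0"), f)
  expect_error(read_species_table(f), "charge")

  writeLines(c("name,compound,role,medium,charge,enthalpy,gibbs_energy",
               "a,X,neutral,gas,0,oops,-1.0"), f)
  expect_error(read_species_table(f), "line 1")
})

test_that("species table write/read round trip preserves every field", {
  sp <- make_species()
  f <- tempfile(fileext = ".csv")
  write_species_table(sp, f)
  back <- read_species_table(f)
  expect_identical(back$enthalpy, sp$enthalpy)
  expect_identical(back$gibbs_energy, sp$gibbs_energy)
  expect_identical(back$role, sp$role)
  expect_identical(back$charge, sp$charge)
})

test_that("TS table validation catches inconsistent records", {
  base <- data.frame(compound = "X", site = "O14-H", mechanism = "FHT",
                     medium = "gas", protonation_state = "HA",
                     activation_gibbs = 16.7, stringsAsFactors = FALSE)
  ok <- validate_ts(base)
  expect_true(all(c("tunneling_coefficient", "barrierless") %in% names(ok)))

  bad <- base; bad$activation_gibbs <- -2
  expect_error(validate_ts(bad), "barrierless")
  bad$barrierless <- TRUE
  expect_silent(validate_ts(bad))

  bad <- base; bad$tunneling_coefficient <- 0.5
  expect_error(validate_ts(bad), "tunneling_coefficient")

  bad <- base; bad$mechanism <- "HAT"
  expect_error(validate_ts(bad), "mechanism")
})
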