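test_that("BDE/PA/IE compose species enthalpies with the right signs", {
  sp <- make_species(bde = 84.2, pa = 334.6, ie = 179.1)
  parent <- sp[sp$role == "neutral", ]
  rad <- sp[sp$role == "radical", ]
  an <- sp[sp$role == "anion", ]
  cat_ <- sp[sp$role == "cation_radical", ]
  h <- sp[sp$role == "hydrogen_atom", ]
  p <- sp[sp$role == "proton", ]
  e <- sp[sp$role == "electron", ]

  expect_equal(bond_dissociation_enthalpy(parent, rad, h), 84.2)
  expect_equal(proton_affinity(parent, an, p), 334.6)
  expect_equal(ionization_energy(parent, cat_, e), 179.1)

  # degenerate equality: parent enthalpy equals fragment sum
  rad0 <- rad; rad0$enthalpy <- parent$enthalpy - h$enthalpy
  expect_equal(bond_dissociation_enthalpy(parent, rad0, h), 0)

  # role and medium guards
  expect_error(bond_dissociation_enthalpy(rad, parent, h), "roles")
  h2 <- h; h2$medium <- "water"
  expect_error(bond_dissociation_enthalpy(parent, rad, h2), "media")

  # PA is invariant under a common shift of parent and anion
  parent2 <- parent; parent2$enthalpy <- parent$enthalpy + 11.3
  an2 <- an; an2$enthalpy <- an$enthalpy + 11.3
  expect_equal(proton_affinity(parent2, an2, p),
               proton_affinity(parent, an, p))
})

test_that("mechanism free energies follow products-minus-reactants", {
  sp <- make_species(dg_fht = -1.5, dg_pt = 183.1, dg_set = 155.9)
  pick <- function(role) as.list(sp[sp$role == role, ])
  react <- list(pick("neutral"), pick("hoo_radical"))

  expect_equal(mechanism_free_energy("FHT", react,
                                     list(pick("radical"), pick("hooh"))),
               -1.5)
  expect_equal(mechanism_free_energy("PT", react,
                                     list(pick("anion"),
                                          pick("hooh_cation_radical"))),
               183.1)
  expect_equal(mechanism_free_energy("SET", react,
                                     list(pick("cation_radical"),
                                          pick("hoo_anion"))),
               155.9)
  # degenerate case: products summing to the reactant total give zero
  rad0 <- pick("radical")
  rad0$gibbs_energy <- pick("neutral")$gibbs_energy +
    pick("hoo_radical")$gibbs_energy - pick("hooh")$gibbs_energy
  expect_equal(mechanism_free_energy("FHT", react,
                                     list(rad0, pick("hooh"))), 0)
  expect_error(mechanism_free_energy("SET", react,
                                     list(pick("anion"), pick("hooh"))),
               "roles")
})

test_that("balanced reaction energies are gauge invariant under uniform shifts", {
  sp <- make_species()
  d1 <- thermo_descriptors(sp)
  sp2 <- sp
  sp2$enthalpy <- sp2$enthalpy + 123.456
  sp2$gibbs_energy <- sp2$gibbs_energy + 123.456
  d2 <- thermo_descriptors(sp2)
  # 2-in/2-out mechanism steps cannot see a common energy origin
  for (col in c("dg_fht", "dg_pt", "dg_set"))
    expect_equal(d2[[col]], d1[[col]], tolerance = 1e-9)
  # dissociative descriptors (1 reactant, 2 products) shift by exactly +c
  for (col in c("bde", "pa", "ie"))
    expect_equal(d2[[col]], d1[[col]] + 123.456, tolerance = 1e-9)
})

test_that("gas-phase screening retains exactly the hydrogen-transfer channels", {
  thermo <- cleomiscosin_data()$thermo
  gas <- thermo[thermo$medium == "gas", ]
  scr <- screen_mechanisms(gas, retention_threshold = 10)
  kept <- scr[scr$retained, ]
  expect_true(all(kept$mechanism == "FHT"))
  expect_setequal(paste(kept$compound, kept$site),
                  c("CMA O14-H", "CMA C18-H", "CMB O14-H", "CMB C17-H",
                    "CMC O14-H", "CMC C18-H"))
  # O19-H hydrogen transfer and all PT/SET channels are dropped
  expect_false(any(kept$site == "O19-H"))
  expect_true(all(scr$dg[scr$mechanism == "PT"] >= 183.1))
  expect_true(all(scr$dg[scr$mechanism == "SET"] >= 155.9))
})

test_that("screening is monotone in the threshold with trivial limits", {
  d <- thermo_descriptors(make_species())
  none <- screen_mechanisms(d, -Inf)
  all_ <- screen_mechanisms(d, Inf)
  expect_false(any(none$retained))
  expect_true(all(all_$retained))
  for (thr in c(-10, 0, 50, 200)) {
    lo <- screen_mechanisms(d, thr)
    hi <- screen_mechanisms(d, thr + 25)
    expect_true(all(hi$retained[lo$retained]))
  }
  expect_identical(nrow(screen_mechanisms(d[0, ], 10)), 0L)
})
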