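# brute-force dense-trapezoid evaluation of the thermally averaged Eckart
# transmission; independent of the adaptive quadrature in eckart_kappa()
eckart_oracle <- function(vf, vr, nu, temperature = 298.15, n = 200001L) {
  pc <- phys_constants()
  rt <- pc$R_kcal * temperature
  freq_kcal <- pc$h * pc$c_cm * pc$N_A / 4184 * nu
  e0 <- max(0, vf - vr)
  emax <- vf + 40 * rt
  E <- seq(e0, emax, length.out = n)
  y <- radscav:::.eckart_transmission(E, vf, vr, freq_kcal) *
    exp((vf - E) / rt)
  sum(y[-1] + y[-n]) / 2 * (E[2] - E[1]) / rt
}

# closed-form sequential-deprotonation fractions, written independently of
# speciation_ladder()
ladder_oracle <- function(pkas, pH) {
  w <- vapply(0:length(pkas), function(k)
    prod(10^(pH - pkas[seq_len(k)])), 0)
  w / sum(w)
}

# minimal species table covering every role, with adjustable energies
make_species <- function(med = "gas",
                         h_parent = -1000, g_parent = -1030,
                         bde = 84.2, pa = 334.6, ie = 179.3,
                         dg_fht = -1.5, dg_pt = 183.1, dg_set = 155.9) {
  h_H <- 14.4; g_H <- 11
  h_p <- 34.6; g_p <- 28
  h_e <- 0; g_e <- 0
  g_hoo <- -100; g_hooh <- -180; g_hoocat <- 60; g_hooan <- -120
  df <- data.frame(
    name = c("parent", "radical", "anion", "cation", "h", "p", "e",
             "hoo", "hooan", "hooh", "hoocat"),
    compound = c(rep("X", 4), rep("ref", 7)),
    role = c("neutral", "radical", "anion", "cation_radical",
             "hydrogen_atom", "proton", "electron", "hoo_radical",
             "hoo_anion", "hooh", "hooh_cation_radical"),
    medium = med,
    charge = c(0L, 0L, -1L, 1L, 0L, 1L, -1L, 0L, -1L, 0L, 1L),
    enthalpy = c(h_parent, bde + h_parent - h_H, pa + h_parent - h_p,
                 ie + h_parent - h_e, h_H, h_p, h_e,
                 -105, -125, -185, 55),
    gibbs_energy = c(g_parent,
                     dg_fht + g_parent + g_hoo - g_hooh,
                     dg_pt + g_parent + g_hoo - g_hoocat,
                     dg_set + g_parent + g_hoo - g_hooan,
                     g_H, g_p, g_e, g_hoo, g_hooan, g_hooh, g_hoocat),
    site = c(NA, "O14-H", "O14-H", NA, rep(NA, 7)),
    stringsAsFactors = FALSE)
  validate_species(df)
}
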