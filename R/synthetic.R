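#' @name synthetic_data
#' @title Synthetic thermochemistry and barrier generators
#'
#' @description
#' Internally consistent synthetic inputs for every pipeline stage.
#' Generation works backwards: target descriptors (BDE, PA, IE, reaction
#' free energies) are sampled inside configurable physically plausible
#' ranges, then species energies are solved so that composing the thermo
#' operations over the synthetic table recovers the targets exactly.
#' One free gauge (the parent energies and the reference-species
#' energies) is fixed at conventional origins, so range compliance needs
#' no rejection sampling.
NULL

#' Generator configuration
#'
#' Default ranges follow the spans observed for coumarinolignan-type
#' phenols: BDE 84-107 kcal/mol, PA 306-364, IE 144-183, FHT reaction
#' free energies -5 to +6 for kinetically relevant channels, activation
#' Gibbs energies 14.2-22.6, imaginary frequencies 800-2500 cm-1,
#' Marcus reorganization energies 4.9-8.1, pKa 9.3-9.6.
#'
#' @param seed integer RNG seed.
#' @param n_compounds,sites_per_compound synthetic ensemble size.
#' @param media character vector of medium names to emit.
#' @param bde_range,pa_range,ie_range,dg_fht_range,dg_pt_range,dg_set_range
#'   descriptor target intervals, kcal/mol.
#' @param ddg_activation_range activation Gibbs interval, kcal/mol.
#' @param imaginary_frequency_range saddle-point wavenumber interval,
#'   cm-1.
#' @param lambda_range Marcus reorganization-energy interval, kcal/mol.
#' @param pka_range pKa interval for speciation targets.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_compounds = 3L,
                             sites_per_compound = 3L,
                             media = c("gas", "pentyl_ethanoate", "water"),
                             bde_range = c(84, 107),
                             pa_range = c(306, 364),
                             ie_range = c(144, 183),
                             dg_fht_range = c(-5, 6),
                             dg_pt_range = c(100, 212),
                             dg_set_range = c(73, 160),
                             ddg_activation_range = c(14.2, 22.6),
                             imaginary_frequency_range = c(800, 2500),
                             lambda_range = c(4.9, 8.1),
                             pka_range = c(9.3, 9.6)) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              sites_per_compound = as.integer(sites_per_compound),
              media = media, bde_range = bde_range, pa_range = pa_range,
              ie_range = ie_range, dg_fht_range = dg_fht_range,
              dg_pt_range = dg_pt_range, dg_set_range = dg_set_range,
              ddg_activation_range = ddg_activation_range,
              imaginary_frequency_range = imaginary_frequency_range,
              lambda_range = lambda_range, pka_range = pka_range)
  ranges <- cfg[grepl("_range$", names(cfg))]
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[2] < r[1])
      stop("invalid interval for ", nm)
  }
  if (cfg$bde_range[1] < 40 || cfg$bde_range[2] > 150)
    stop("bde_range outside physically plausible bounds [40, 150]")
  if (cfg$n_compounds < 1L || cfg$sites_per_compound < 1L)
    stop("need at least one compound and one site")
  class(cfg) <- "generator_config"
  cfg
}

.site_labels <- function(n) {
  # alternate phenolic O-H and benzylic C-H labels, O14-H style
  vapply(seq_len(n), function(i)
    sprintf("%s%d-H", if (i %% 2L == 1L) "O" else "C", 13L + i), "")
}

.runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a synthetic species table
#'
#' Samples target descriptors per (compound, site, medium) and solves
#' for the species energies, so that [thermo_descriptors()] over the
#' output reproduces the targets to machine precision. Reference
#' species (H., H+, e-, HOO., HOO-, HOOH, HOOH+.) are emitted per
#' medium. Deterministic under a fixed seed.
#'
#' @param config a [generator_config()].
#' @return list with `species` (validated species table) and `targets`
#'   (the sampled descriptor data.frame, for parameter-recovery tests).
#' @export
generate_species_set <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  compounds <- sprintf("SYN%02d", seq_len(config$n_compounds))
  sites <- .site_labels(config$sites_per_compound)
  rows <- list(); targets <- list()
  add <- function(name, compound, role, medium, H, G, site = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, compound = compound, role = role, medium = medium,
      charge = .role_charge[[role]], enthalpy = H, gibbs_energy = G,
      site = site, stringsAsFactors = FALSE)
  for (med in config$media) {
    # reference species: conventional origins with per-medium jitter
    h_H <- -312 + stats::runif(1, -2, 2);  g_H <- h_H - 3
    h_p <- 34 + stats::runif(1, -30, 2);   g_p <- h_p - 6
    h_e <- stats::runif(1, -20, 0);        g_e <- h_e - 1
    h_hoo <- -105 + stats::runif(1, -2, 2); g_hoo <- h_hoo + 12
    h_hooh <- h_hoo - 80 + stats::runif(1, -2, 2); g_hooh <- h_hooh + 14
    h_hoocat <- h_hooh + 240 + stats::runif(1, -2, 2); g_hoocat <- h_hoocat + 14
    h_hooan <- h_hoo - 20 + stats::runif(1, -2, 2); g_hooan <- h_hooan + 12
    add("h_atom", "ref", "hydrogen_atom", med, h_H, g_H)
    add("proton", "ref", "proton", med, h_p, g_p)
    add("electron", "ref", "electron", med, h_e, g_e)
    add("hoo_radical", "ref", "hoo_radical", med, h_hoo, g_hoo)
    add("hoo_anion", "ref", "hoo_anion", med, h_hooan, g_hooan)
    add("hooh", "ref", "hooh", med, h_hooh, g_hooh)
    add("hooh_cation_radical", "ref", "hooh_cation_radical", med,
        h_hoocat, g_hoocat)
    for (ci in seq_along(compounds)) {
      cmp <- compounds[ci]
      h_parent <- -1000 - 50 * ci + stats::runif(1, -5, 5)
      g_parent <- h_parent - 30 + stats::runif(1, -3, 3)
      add(paste(cmp, "parent", med, sep = "_"), cmp, "neutral", med,
          h_parent, g_parent)
      ie <- .runif1(config$ie_range)
      dg_set <- .runif1(config$dg_set_range)
      h_cat <- ie + h_parent - h_e
      g_cat <- dg_set + g_parent + g_hoo - g_hooan
      add(paste(cmp, "cation", med, sep = "_"), cmp, "cation_radical", med,
          h_cat, g_cat)
      for (site in sites) {
        bde <- .runif1(config$bde_range)
        pa <- .runif1(config$pa_range)
        dg_fht <- .runif1(config$dg_fht_range)
        dg_pt <- .runif1(config$dg_pt_range)
        add(paste(cmp, site, "radical", med, sep = "_"), cmp, "radical", med,
            bde + h_parent - h_H,
            dg_fht + g_parent + g_hoo - g_hooh, site = site)
        add(paste(cmp, site, "anion", med, sep = "_"), cmp, "anion", med,
            pa + h_parent - h_p,
            dg_pt + g_parent + g_hoo - g_hoocat, site = site)
        targets[[length(targets) + 1L]] <- data.frame(
          compound = cmp, site = site, medium = med, bde = bde, pa = pa,
          ie = ie, dg_fht = dg_fht, dg_pt = dg_pt, dg_set = dg_set,
          stringsAsFactors = FALSE)
      }
    }
  }
  species <- validate_species(do.call(rbind, rows))
  list(species = species, targets = do.call(rbind, targets))
}

#' Generate a synthetic transition-state ensemble
#'
#' FHT channels for the first two sites of each compound per medium
#' (matching the usual kinetically relevant O-H plus one C-H), with the
#' tunneling inputs varied across the three resolution routes
#' (explicit kappa / Eckart barriers / Wigner frequency only); SET
#' channels with sampled Marcus reorganization energies for aqueous
#' media. Deterministic under a fixed seed.
#'
#' @param config a [generator_config()].
#' @return validated TS table.
#' @export
generate_ts_ensemble <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 7654321L)
  compounds <- sprintf("SYN%02d", seq_len(config$n_compounds))
  sites <- .site_labels(min(2L, config$sites_per_compound))
  rows <- list()
  route <- 0L
  for (med in config$media) {
    for (cmp in compounds) {
      for (site in sites) {
        dg <- .runif1(config$ddg_activation_range)
        nu <- .runif1(config$imaginary_frequency_range)
        route <- route + 1L
        row <- data.frame(compound = cmp, site = site, mechanism = "FHT",
                          medium = med, protonation_state = "HA",
                          activation_gibbs = dg,
                          imaginary_frequency = NA_real_,
                          forward_barrier = NA_real_,
                          reverse_barrier = NA_real_,
                          tunneling_coefficient = NA_real_,
                          reorganization_energy = NA_real_,
                          barrierless = FALSE, stringsAsFactors = FALSE)
        switch(route %% 3L + 1L,
               { row$tunneling_coefficient <- stats::runif(1, 100, 3000) },
               { row$forward_barrier <- stats::runif(1, 4, 12)
                 row$reverse_barrier <- row$forward_barrier +
                   stats::runif(1, -2, 8)
                 row$imaginary_frequency <- nu },
               { row$imaginary_frequency <- nu })
        rows[[length(rows) + 1L]] <- row
      }
      if (med == "water") {
        lambda <- .runif1(config$lambda_range)
        dg_rxn <- stats::runif(1, -2, 2)
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cmp, site = sites[1], mechanism = "SET",
          medium = med, protonation_state = "A_minus",
          activation_gibbs = marcus_activation(dg_rxn, lambda),
          imaginary_frequency = NA_real_, forward_barrier = NA_real_,
          reverse_barrier = NA_real_, tunneling_coefficient = NA_real_,
          reorganization_energy = lambda, barrierless = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_ts(do.call(rbind, rows))
}

#' Synthetic pKa table matching a generator configuration
#'
#' @param config a [generator_config()].
#' @return data.frame with `compound` and `pka1` sampled in
#'   `config$pka_range`; deterministic under the seed.
#' @export
generate_pka_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 24681357L)
  data.frame(compound = sprintf("SYN%02d", seq_len(config$n_compounds)),
             pka1 = stats::runif(config$n_compounds, config$pka_range[1],
                                 config$pka_range[2]),
             stringsAsFactors = FALSE)
}
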