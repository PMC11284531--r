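#' @name pipeline
#' @title Stage drivers
#'
#' @description
#' One driver per pipeline stage, mirroring the table-per-stage layout
#' of the analysis: thermodynamic descriptors, speciation, channel
#' kinetics, overall assembly, synthetic-data simulation, and the
#' regression replay over the bundled cleomiscosin dataset. Each driver
#' accepts in-memory data.frames or CSV paths and can write its output
#' tables plus a run manifest (config echo, constants, package version,
#' seed) to an output directory. A thin command-line wrapper over these
#' drivers ships in `inst/scripts/radscav.R`.
NULL

.write_manifest <- function(out_dir, stage, config) {
  pc <- phys_constants()
  manifest <- list(stage = stage,
                   package = "radscav",
                   version = as.character(utils::packageVersion("radscav")),
                   constants = pc[c("R_kcal", "hartree_kcal", "T_ref")],
                   config = config)
  yaml::write_yaml(manifest, file.path(out_dir, paste0(stage, "_manifest.yaml")))
}

.as_df <- function(x, reader) if (is.character(x)) reader(x) else x

#' Thermodynamic-descriptor stage
#'
#' @param species species table (data.frame or CSV path).
#' @param units input energy units when `species` is a path.
#' @param retention_threshold screening cutoff, kcal/mol.
#' @param out_dir optional output directory for the descriptor and
#'   screening CSVs and the run manifest.
#' @return list with `descriptors` and `screening` data.frames.
#' @export
run_thermo <- function(species, units = "kcal_per_mol",
                       retention_threshold = 10, out_dir = NULL) {
  species <- .as_df(species, function(p) read_species_table(p, units))
  descriptors <- thermo_descriptors(species)
  screening <- screen_mechanisms(descriptors, retention_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(descriptors, file.path(out_dir, "descriptors.csv"),
                     row.names = FALSE)
    utils::write.csv(screening, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, "thermo",
                    list(units = units,
                         retention_threshold = retention_threshold))
  }
  list(descriptors = descriptors, screening = screening)
}

#' Speciation stage
#'
#' Either a ready pKa table or a linear pKa model plus deprotonation
#' free energies (as in the bundled synthetic calibration) may be
#' supplied.
#'
#' @param pka_table data.frame with `compound`, `pka1`, ... columns.
#' @param model list with `model$slope`, `model$intercept` and a named
#'   `deprotonation_free_energy` list (the [cleomiscosin_data()]
#'   `pka_model` layout); used when `pka_table` is `NULL`.
#' @param pH solution pH (required).
#' @param out_dir optional output directory.
#' @return speciation report data.frame (see [speciation_report()]).
#' @export
run_speciation <- function(pka_table = NULL, model = NULL, pH = 7.4,
                           out_dir = NULL) {
  if (is.null(pka_table)) {
    if (is.null(model)) stop("supply either pka_table or model")
    dg <- unlist(model$deprotonation_free_energy)
    pka_table <- data.frame(
      compound = names(dg),
      pka1 = pka_from_deprotonation_energy(as.numeric(dg),
                                           model$model$slope,
                                           model$model$intercept),
      stringsAsFactors = FALSE)
  }
  rep <- speciation_report(pka_table, pH)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rep, file.path(out_dir, "speciation.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, "speciation", list(pH = pH))
  }
  rep
}

#' Channel-kinetics stage
#'
#' @param ts TS table (data.frame or CSV path).
#' @param media named list of [medium()] objects.
#' @param ... passed to [channel_rates()] (radii, symmetry, caps).
#' @param out_dir optional output directory.
#' @return channel-rate data.frame.
#' @export
run_kinetics <- function(ts, media = default_media(), ..., out_dir = NULL) {
  ts <- .as_df(ts, read_ts_table)
  rates <- channel_rates(ts, media, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rates, file.path(out_dir, "channel_rates.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, "kinetics", list(...))
  }
  rates
}

#' Overall-assembly stage
#'
#' Splits a channel-rate table by (compound, medium), attaches the
#' protonation-state mole fractions and assembles overall rate
#' constants with branching ratios. Aqueous assemblies require a pH on
#' the water medium and a fractions table.
#'
#' @param channels data.frame with `compound`, `medium`, `site`,
#'   `mechanism`, `protonation_state`, `k_app`.
#' @param fractions optional data.frame `compound`, `state`
#'   (`HA`/`A_minus`), `fraction`; defaults to 1 for every channel in
#'   apolar media.
#' @param media named list of [medium()] objects.
#' @param scenario scenario label stored on the results.
#' @param out_dir optional output directory.
#' @return named list of `"overall_result"` objects
#'   (`<compound>.<medium>`).
#' @export
run_overall <- function(channels, fractions = NULL, media = default_media(),
                        scenario = "default", out_dir = NULL) {
  unknown <- setdiff(unique(channels$medium), names(media))
  if (length(unknown))
    stop("no medium definition for: ", paste(unknown, collapse = ", "))
  results <- list()
  for (med_name in unique(channels$medium)) {
    med <- media[[med_name]]
    if (med$is_polar) {
      if (is.na(med$pH))
        stop("aqueous assembly requires a pH on medium '", med_name, "'")
      if (is.null(fractions))
        stop("aqueous assembly requires a protonation-state fractions table")
    }
    sub <- channels[channels$medium == med_name, , drop = FALSE]
    for (cmp in unique(sub$compound)) {
      b <- sub[sub$compound == cmp, , drop = FALSE]
      if (med$is_polar) {
        key <- ifelse(b$protonation_state == "HA", "neutral", "anion")
        fr <- fractions[fractions$compound == cmp, , drop = FALSE]
        idx <- match(key, fr$state)
        if (anyNA(idx))
          stop("missing fraction for states of ", cmp, " in ", med_name)
        b$mole_fraction <- fr$fraction[idx]
      } else {
        b$mole_fraction <- 1
      }
      results[[paste(cmp, med_name, sep = ".")]] <-
        overall_rate(b, med, scenario = scenario)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rep <- activity_report(results)
    utils::write.csv(rep$overall, file.path(out_dir, "overall.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$branches, file.path(out_dir, "branches.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, "overall", list(scenario = scenario))
  }
  results
}

#' Synthetic-simulation stage
#'
#' @param config a [generator_config()] (or a bare seed, which selects
#'   all defaults).
#' @param out_dir optional output directory; species, TS and pKa tables
#'   are written as CSV and runs with the same config are byte-identical.
#' @return list with `species`, `targets`, `ts`, `pka`.
#' @export
run_simulate <- function(config = generator_config(), out_dir = NULL) {
  if (is.numeric(config)) config <- generator_config(seed = config)
  sp <- generate_species_set(config)
  ts <- generate_ts_ensemble(config)
  pka <- generate_pka_table(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_species_table(sp$species, file.path(out_dir, "species.csv"))
    write_ts_table(ts, file.path(out_dir, "ts.csv"))
    utils::write.csv(pka, file.path(out_dir, "pka.csv"), row.names = FALSE)
    .write_manifest(out_dir, "simulate", unclass(config))
  }
  list(species = sp$species, targets = sp$targets, ts = ts, pka = pka)
}

.check_row <- function(check, group, value, expected, tol, tol_type) {
  pass <- switch(tol_type,
                 rel = abs(value - expected) <= tol * abs(expected),
                 abs = abs(value - expected) <= tol)
  data.frame(check = check, group = group, value = value,
             expected = expected, tol = tol, tol_type = tol_type,
             pass = pass, stringsAsFactors = FALSE)
}

#' Replay the bundled cleomiscosin dataset through the pipeline
#'
#' Recomputes, from the published inputs only, every quantity the
#' downstream (post-electronic-structure) pipeline owns and compares it
#' with the published value at a per-row tolerance:
#' \itemize{
#'   \item TST: `k = kappa*(kB*T/h)*exp(-dG/RT)` from the activation
#'     Gibbs energies and tunneling coefficients, with the
#'     Collins-Kimball diffusion correction in condensed media
#'     (tolerance 10\%: the barriers are given to 0.1 kcal/mol).
#'   \item weighted rates `k_f = f * k_app`, using each row's annotated
#'     fraction convention (printed vs full precision from pKa).
#'   \item overall rate constants and branching ratios through the
#'     assembly module's channel-admission rule.
#'   \item scenario and cross-compound rate ratios, and fold
#'     differences against the reference antioxidants.
#'   \item speciation percentages from the pKa values at pH 7.4.
#' }
#' Diffusion-limited aqueous SET channels are not re-derived from
#' radii (the underlying solute radii are not published); their
#' apparent rates are exact-arithmetic inputs.
#'
#' @param data dataset in [cleomiscosin_data()] layout.
#' @param pH aqueous pH.
#' @return data.frame of checks (`check`, `group`, `value`, `expected`,
#'   `tol`, `tol_type`, `pass`) with attribute `"pass"` = `all(pass)`.
#' @export
run_reproduce <- function(data = cleomiscosin_data(), pH = 7.4) {
  ch <- data$channels
  ov <- data$overall
  sp <- data$speciation
  media <- default_media(pH = pH)
  checks <- list()
  add <- function(x) checks[[length(checks) + 1L]] <<- x

  ## --- TST recomputation from printed barriers and kappa -------------
  for (i in seq_len(nrow(ch))) {
    r <- ch[i, ]
    if (is.na(r$tol_tst)) next
    med <- media[[r$medium]]
    k_act <- tst_rate(r$dg_act, med$temperature, r$kappa)
    k_calc <- if (!is.na(med$viscosity))
      apparent_rate(k_act, diffusion_rate_constant(4e-10, 2e-10,
                                                   med$viscosity,
                                                   med$temperature))
    else k_act
    add(.check_row("tst_rate",
                   paste(r$compound, r$medium, r$scenario, r$mechanism,
                         r$protonation_state, r$site),
                   k_calc, r$k, r$tol_tst, "rel"))
  }

  ## --- fraction convention and weighted rates ------------------------
  f_used <- numeric(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    r <- ch[i, ]
    if (r$f_convention == "full" ||
        (r$medium == "water" && r$f_convention == "full_precision")) {
      pka <- sp$pka1[sp$compound == r$compound]
      fr <- mole_fractions(pka, pH)
      f_used[i] <- unname(fr[if (r$protonation_state == "HA") "neutral"
                             else "anion"])
    } else {
      f_used[i] <- r$f
    }
    add(.check_row("weighted_rate",
                   paste(r$compound, r$medium, r$scenario, r$mechanism,
                         r$protonation_state),
                   weighted_rate(f_used[i], r$k), r$k_f, r$tol_kf, "rel"))
  }

  ## --- assembly: k_overall and branching ratios ----------------------
  results <- list()
  for (i in seq_len(nrow(ov))) {
    o <- ov[i, ]
    sel <- ch$compound == o$compound & ch$medium == o$medium &
      ch$scenario == o$scenario
    b <- ch[sel, , drop = FALSE]
    b$k_app <- b$k
    b$mole_fraction <- f_used[sel]
    res <- overall_rate(b, media[[o$medium]], scenario = o$scenario)
    results[[paste(o$compound, o$medium, o$scenario, sep = ".")]] <- res
    add(.check_row("k_overall", paste(o$compound, o$medium, o$scenario),
                   res$k_overall, o$k_overall, o$tol_rel, "rel"))
    # branching ratios are published for the default assembly only
    rb <- res$branches
    if (o$scenario != "default") next
    for (j in which(rb$admitted))
      add(.check_row("branching_ratio",
                     paste(o$compound, o$medium, o$scenario,
                           rb$mechanism[j], rb$protonation_state[j],
                           rb$site[j]),
                     rb$gamma[j], b$gamma[j], 0.06, "abs"))
  }

  ## --- scenario and cross-compound ratios ----------------------------
  ko <- function(cmp, med, scen = "default")
    results[[paste(cmp, med, scen, sep = ".")]]$k_overall
  expl_ratio <- vapply(c("CMA", "CMB", "CMC"), function(cmp)
    compare_scenarios(results[[paste(cmp, "water", "default", sep = ".")]],
                      results[[paste(cmp, "water", "explicit_water",
                                     sep = ".")]], digits = NULL), 0)
  add(.check_row("explicit_water_slowdown_min", "range",
                 min(expl_ratio), 3.25, 0.005, "rel"))
  add(.check_row("explicit_water_slowdown_max", "range",
                 max(expl_ratio), 6.11, 0.005, "rel"))
  add(.check_row("methoxy_speedup", "pentyl_ethanoate CMC/CMA",
                 ko("CMC", "pentyl_ethanoate") / ko("CMA", "pentyl_ethanoate"),
                 61, 0.01, "rel"))
  add(.check_row("methoxy_speedup", "pentyl_ethanoate CMC/CMB",
                 ko("CMC", "pentyl_ethanoate") / ko("CMB", "pentyl_ethanoate"),
                 185, 0.01, "rel"))
  add(.check_row("methoxy_speedup", "gas CMC/CMA",
                 ko("CMC", "gas") / ko("CMA", "gas"), 84, 0.01, "rel"))
  trolox <- data$references$k[data$references$name == "trolox"]
  add(.check_row("fold_vs_trolox", "CMA water",
                 ko("CMA", "water") / trolox, 5.4e2, 0.01, "rel"))
  ascorbic <- data$references$k[data$references$name == "ascorbic_acid"]
  add(.check_row("fold_vs_ascorbic", "CMB water",
                 round(ko("CMB", "water") / ascorbic, 2), 0.87, 0.01, "abs"))

  ## --- speciation -----------------------------------------------------
  for (i in seq_len(nrow(sp))) {
    fr <- mole_fractions(sp$pka1[i], sp$pH[i])
    add(.check_row("speciation_pct_neutral", sp$compound[i],
                   round(100 * fr[["neutral"]], 1), sp$pct_neutral[i],
                   0.05, "abs"))
    add(.check_row("speciation_pct_anion", sp$compound[i],
                   round(100 * fr[["anion"]], 1), sp$pct_anion[i],
                   0.05, "abs"))
  }

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$pass)
  out
}
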