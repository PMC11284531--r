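#' @name kinetics
#' @title Channel rate constants: TST, tunneling, Marcus and diffusion
#'
#' @description
#' Rate constants are evaluated per reaction channel with conventional
#' transition state theory on a 1 M standard state,
#' `k = sigma * kappa * (kB*T/h) * exp(-dG_act/(R*T))`,
#' where `kappa` is a quantum tunneling transmission coefficient
#' (thermally averaged Eckart barrier, or the Wigner expansion as a
#' fallback) for hydrogen-transfer channels and 1 for electron transfer.
#' Electron-transfer barriers may be built from Marcus theory,
#' `dG_act = (lambda + dG)^2 / (4*lambda)`. In condensed media the
#' activation-controlled rate is combined with the Smoluchowski diffusion
#' limit through the Collins-Kimball expression to give the apparent rate
#' constant.
NULL

# energy of one wavenumber quantum, kcal/mol per cm-1
.kcal_per_wavenumber <- function() {
  pc <- phys_constants()
  pc$h * pc$c_cm * pc$N_A / 4184
}

#' Conventional TST rate constant with tunneling
#'
#' @param activation_gibbs Gibbs activation energy in kcal/mol (1 M
#'   standard state). A negative value triggers a warning and is
#'   evaluated as given; barrierless channels are capped downstream.
#' @param temperature temperature in K.
#' @param kappa tunneling transmission coefficient (>= 1).
#' @param symmetry_number reaction-path degeneracy (integer >= 1).
#' @return rate constant in M-1 s-1 (bimolecular, 1 M standard state).
#' @examples
#' tst_rate(16.7, kappa = 195.2)  # ~7e2 M-1 s-1
#' @export
tst_rate <- function(activation_gibbs, temperature = phys_constants()$T_ref,
                     kappa = 1, symmetry_number = 1L) {
  stopifnot(temperature > 0, all(kappa >= 1), all(symmetry_number >= 1))
  if (any(activation_gibbs < 0))
    warning("negative activation Gibbs energy; evaluating as given ",
            "(cap barrierless channels at the diffusion/collision limit)")
  pc <- phys_constants()
  symmetry_number * kappa * (pc$kB * temperature / pc$h) *
    exp(-activation_gibbs / (pc$R_kcal * temperature))
}

#' Wigner tunneling coefficient
#'
#' Leading-order correction `1 + (1/24) * (h*nu*c / (kB*T))^2` from the
#' magnitude of the imaginary frequency at the saddle point. Used as the
#' fallback when full Eckart inputs are unavailable.
#'
#' @param imaginary_frequency magnitude of the imaginary wavenumber, cm-1.
#' @param temperature temperature in K.
#' @return dimensionless kappa >= 1.
#' @export
wigner_kappa <- function(imaginary_frequency,
                         temperature = phys_constants()$T_ref) {
  stopifnot(all(imaginary_frequency >= 0), temperature > 0)
  pc <- phys_constants()
  u <- pc$h * pc$c_cm * imaginary_frequency / (pc$kB * temperature)
  1 + u^2 / 24
}

# log(cosh(x)) without overflow
.logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

# log(exp(a) - exp(b)), a >= b
.logspace_sub <- function(a, b) a + log1p(-exp(pmin(b - a, 0)))

# log(exp(a) + exp(b))
.logspace_add <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))

# transmission probability of the 1-D asymmetric Eckart barrier at
# energy E (kcal/mol, measured from the reactant asymptote), evaluated
# in log space so the cosh terms cannot overflow
.eckart_transmission <- function(E, vf, vr, freq_kcal) {
  a1 <- 2 * pi * vf / freq_kcal
  a2 <- 2 * pi * vr / freq_kcal
  cc <- 1 / sqrt(a1) + 1 / sqrt(a2)
  xi <- E / vf
  two_pi_a <- 2 * sqrt(pmax(a1 * xi, 0)) / cc
  arg_b <- (xi - 1) * a1 + a2
  two_pi_b <- 2 * sqrt(pmax(arg_b, 0)) / cc
  d_arg <- a1 * a2 - pi^2 / 4
  p <- numeric(length(E))
  open_ch <- arg_b >= 0 & E > 0
  if (!any(open_ch)) return(p)
  la <- two_pi_a[open_ch]; lb <- two_pi_b[open_ch]
  num <- .logspace_sub(.logcosh(la + lb), .logcosh(la - lb))
  if (d_arg >= 0) {
    ld <- .logcosh(2 * sqrt(d_arg))
    den <- .logspace_add(.logcosh(la + lb), ld)
  } else {
    # thin-barrier branch: cosh(i y) = cos(y)
    cd <- cos(2 * sqrt(-d_arg))
    den <- .logspace_add(.logcosh(la + lb), log(abs(cd) + 1e-300)) # cd > -1
    # exact when cd >= 0; for cd < 0 fall back to direct evaluation
    if (cd < 0) {
      den <- log(pmax(cosh(pmin(la + lb, 700)) + cd, 1e-300))
      num <- log(pmax(cosh(pmin(la + lb, 700)) - cosh(pmin(la - lb, 700)),
                      1e-300))
    }
  }
  p[open_ch] <- exp(num - den)
  pmin(p, 1)
}

#' Eckart tunneling coefficient
#'
#' Thermally averaged transmission through the one-dimensional
#' asymmetric Eckart barrier fitted to the forward and reverse barrier
#' heights and the imaginary frequency:
#' `kappa = exp(Vf/RT)/RT * integral P(E) exp(-E/RT) dE`,
#' integrated from the higher of the two asymptotes (so endoergic
#' channels never count energetically closed states) up to
#' `Vf + 40*RT`. Adaptive quadrature to the requested relative
#' tolerance.
#'
#' @param forward_barrier,reverse_barrier barrier heights from the
#'   reactant and product sides, kcal/mol (> 0).
#' @param imaginary_frequency magnitude of the imaginary wavenumber at
#'   the saddle point, cm-1 (> 0).
#' @param temperature temperature in K.
#' @param rel_tol relative tolerance of the quadrature.
#' @return dimensionless kappa (>= 1 over the physical domain).
#' @export
eckart_kappa <- function(forward_barrier, reverse_barrier,
                         imaginary_frequency,
                         temperature = phys_constants()$T_ref,
                         rel_tol = 1e-6) {
  stopifnot(forward_barrier > 0, reverse_barrier > 0,
            imaginary_frequency > 0, temperature > 0)
  pc <- phys_constants()
  rt <- pc$R_kcal * temperature
  freq_kcal <- .kcal_per_wavenumber() * imaginary_frequency
  e0 <- max(0, forward_barrier - reverse_barrier)
  emax <- forward_barrier + 40 * rt
  integrand <- function(E)
    .eckart_transmission(E, forward_barrier, reverse_barrier, freq_kcal) *
      exp((forward_barrier - E) / rt)
  q <- stats::integrate(integrand, e0, emax, rel.tol = rel_tol,
                        subdivisions = 1000L, stop.on.error = FALSE)
  if (q$message != "OK" && q$abs.error > rel_tol * abs(q$value))
    stop("Eckart quadrature did not converge: ", q$message,
         " (abs.error ", format(q$abs.error), ")")
  q$value / rt
}

#' Marcus-theory activation energy for electron transfer
#'
#' `dG_act = (lambda + dG)^2 / (4*lambda)`.
#'
#' @param dg_reaction reaction Gibbs energy of the electron-transfer
#'   step, kcal/mol.
#' @param reorganization_energy nuclear reorganization energy lambda,
#'   kcal/mol (> 0).
#' @return activation Gibbs energy, kcal/mol.
#' @examples
#' marcus_activation(1.78, 5.0)  # 2.30
#' @export
marcus_activation <- function(dg_reaction, reorganization_energy) {
  if (any(reorganization_energy <= 0))
    stop("reorganization energy must be > 0")
  (reorganization_energy + dg_reaction)^2 / (4 * reorganization_energy)
}

#' Nuclear reorganization energy from SET energetics
#'
#' `lambda = deltaE_SET - dG_SET`: the vertical (fixed-geometry) energy
#' change of the electron transfer minus its adiabatic reaction free
#' energy.
#'
#' @param delta_e_set vertical SET energy change, kcal/mol.
#' @param dg_set adiabatic SET reaction Gibbs energy, kcal/mol.
#' @return lambda, kcal/mol; an error if the difference is not positive.
#' @export
reorganization_energy <- function(delta_e_set, dg_set) {
  lambda <- delta_e_set - dg_set
  if (any(lambda <= 0))
    stop("lambda = deltaE_SET - dG_SET must be > 0 for this convention")
  lambda
}

#' Smoluchowski diffusion-limited rate constant
#'
#' Steady-state encounter rate `k_D = 4*pi*R_AB*D_AB*N_A` with
#' `R_AB = r_a + r_b` and Stokes-Einstein diffusion coefficients
#' `D = kB*T/(6*pi*eta*r)` for each partner.
#'
#' @param radius_a,radius_b solute radii in m.
#' @param viscosity dynamic viscosity in Pa s.
#' @param temperature temperature in K.
#' @return rate constant in M-1 s-1.
#' @export
diffusion_rate_constant <- function(radius_a, radius_b, viscosity,
                                    temperature = phys_constants()$T_ref) {
  stopifnot(radius_a > 0, radius_b > 0, viscosity > 0, temperature > 0)
  pc <- phys_constants()
  stokes <- function(r) pc$kB * temperature / (6 * pi * viscosity * r)
  k_si <- 4 * pi * (radius_a + radius_b) * (stokes(radius_a) + stokes(radius_b)) *
    pc$N_A                                   # m^3 mol-1 s-1
  k_si * 1000                               # L mol-1 s-1
}

#' Collins-Kimball apparent rate constant
#'
#' `k_app = k_D * k_act / (k_D + k_act)`; with no diffusion limit (gas
#' phase) the activation-controlled rate is returned unchanged.
#'
#' @param k_activation activation-controlled (TST) rate, M-1 s-1.
#' @param k_diffusion diffusion-limited rate, M-1 s-1, or `NA`/`NULL`
#'   for gas phase.
#' @return apparent rate constant, M-1 s-1; never exceeds either input.
#' @export
apparent_rate <- function(k_activation, k_diffusion = NULL) {
  stopifnot(all(k_activation >= 0))
  if (is.null(k_diffusion) || all(is.na(k_diffusion))) return(k_activation)
  stopifnot(all(k_diffusion >= 0))
  out <- ifelse(k_activation + k_diffusion == 0, 0,
                k_diffusion * k_activation / (k_diffusion + k_activation))
  unname(out)
}

#' Standard-state correction of a reaction/activation free energy
#'
#' Converting between the 1 atm ideal-gas and 1 M solution standard
#' states shifts each free energy by `RT*ln(V_m)` per unit change in
#' molecularity, where `V_m = RT/p0` is the molar volume in litres
#' (24.46 L at 298.15 K, i.e. about 1.89 kcal/mol per unit). The
#' correction is explicit and directional; nothing in the package
#' applies it silently.
#'
#' @param dg free energy, kcal/mol.
#' @param temperature temperature in K.
#' @param delta_molecularity change in moles between the two sides of
#'   the step (e.g. -1 for a bimolecular association), |.| <= 2.
#' @param direction `"atm_to_molar"` or `"molar_to_atm"`.
#' @return corrected free energy, kcal/mol.
#' @export
standard_state_correction <- function(dg,
                                      temperature = phys_constants()$T_ref,
                                      delta_molecularity = -1L,
                                      direction = c("atm_to_molar",
                                                    "molar_to_atm")) {
  direction <- match.arg(direction)
  stopifnot(abs(delta_molecularity) <= 2)
  pc <- phys_constants()
  vm_litre <- pc$R_J * temperature / 101325 * 1000
  shift <- delta_molecularity * pc$R_kcal * temperature * log(vm_litre)
  if (direction == "atm_to_molar") dg + shift else dg - shift
}

#' Resolve the tunneling coefficient for one channel record
#'
#' Preference order for hydrogen-transfer (FHT) channels: an explicitly
#' provided kappa; else Eckart from forward/reverse barriers and the
#' imaginary frequency; else Wigner from the imaginary frequency; else 1.
#' Electron- and proton-transfer channels always take kappa = 1.
#'
#' @param ts one validated TS-table row (data.frame or list).
#' @param temperature temperature in K.
#' @return list with `kappa` and `method` (one of `"provided"`,
#'   `"eckart"`, `"wigner"`, `"unity"`).
#' @export
resolve_kappa <- function(ts, temperature = phys_constants()$T_ref) {
  ts <- .one_ts(ts)
  if (ts$mechanism != "FHT")
    return(list(kappa = 1, method = "unity"))
  if (!is.na(ts$tunneling_coefficient))
    return(list(kappa = ts$tunneling_coefficient, method = "provided"))
  if (!is.na(ts$forward_barrier) && !is.na(ts$reverse_barrier) &&
      !is.na(ts$imaginary_frequency))
    return(list(kappa = eckart_kappa(ts$forward_barrier, ts$reverse_barrier,
                                     ts$imaginary_frequency, temperature),
                method = "eckart"))
  if (!is.na(ts$imaginary_frequency))
    return(list(kappa = wigner_kappa(ts$imaginary_frequency, temperature),
                method = "wigner"))
  list(kappa = 1, method = "unity")
}

.one_ts <- function(ts) {
  if (is.data.frame(ts)) {
    stopifnot(nrow(ts) == 1L)
    ts <- as.list(ts)
  }
  for (col in .ts_optional)
    if (is.null(ts[[col]])) ts[[col]] <- if (col == "barrierless") FALSE else NA_real_
  ts
}

#' Per-channel rate constants from a transition-state table
#'
#' Evaluates every channel of a validated TS table: resolves kappa,
#' applies TST, and in condensed media combines with the Smoluchowski
#' diffusion limit via Collins-Kimball. Channels flagged barrierless
#' (or with a negative barrier) are capped at the diffusion limit in
#' condensed media and at `gas_collision_cap` in the gas phase, with a
#' warning.
#'
#' @param ts validated TS table (see [read_ts_table()]).
#' @param media named list of [medium()] objects covering every medium
#'   named in `ts`.
#' @param radius_solute,radius_radical solute radii in m for the
#'   diffusion limit (defaults 4.0 and 2.0 Angstrom).
#' @param symmetry_number reaction-path degeneracy applied to every
#'   channel.
#' @param gas_collision_cap cap for barrierless gas-phase channels,
#'   M-1 s-1.
#' @return data.frame: one row per channel with `kappa`, `kappa_method`,
#'   `k_tst`, `k_diffusion`, `k_app`, plus the identifying columns and
#'   `reorganization_energy` passed through.
#' @export
channel_rates <- function(ts, media = default_media(),
                          radius_solute = 4.0e-10,
                          radius_radical = 2.0e-10,
                          symmetry_number = 1L,
                          gas_collision_cap = 1e10) {
  ts <- validate_ts(ts)
  if (nrow(ts) == 0L) stop("empty TS table")
  unknown <- setdiff(unique(ts$medium), names(media))
  if (length(unknown))
    stop("no medium definition for: ", paste(unknown, collapse = ", "))
  rows <- lapply(seq_len(nrow(ts)), function(i) {
    row <- as.list(ts[i, ])
    med <- media[[row$medium]]
    kres <- resolve_kappa(row, med$temperature)
    condensed <- !is.na(med$viscosity)
    k_diff <- if (condensed)
      diffusion_rate_constant(radius_solute, radius_radical,
                              med$viscosity, med$temperature)
    else NA_real_
    if (isTRUE(row$barrierless) ||
        (is.finite(row$activation_gibbs) && row$activation_gibbs < 0)) {
      cap <- if (condensed) k_diff else gas_collision_cap
      warning(sprintf("channel %s/%s/%s in %s is barrierless; capped at %s",
                      row$compound, row$site, row$mechanism, row$medium,
                      format(cap, digits = 3)))
      k_tst <- cap
      k_app <- cap
    } else {
      k_tst <- tst_rate(row$activation_gibbs, med$temperature,
                        kres$kappa, symmetry_number)
      k_app <- if (condensed) apparent_rate(k_tst, k_diff) else k_tst
    }
    data.frame(compound = row$compound, site = row$site,
               mechanism = row$mechanism, medium = row$medium,
               protonation_state = row$protonation_state,
               activation_gibbs = row$activation_gibbs,
               kappa = kres$kappa, kappa_method = kres$method,
               reorganization_energy = row$reorganization_energy,
               k_tst = k_tst, k_diffusion = k_diff, k_app = k_app,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
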