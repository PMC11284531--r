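#' @name thermo
#' @title Thermodynamic descriptors of the radical-scavenging mechanisms
#'
#' @description
#' Three one-electron/one-proton bookkeeping quantities decide which of the
#' classical antioxidant mechanisms is viable at a phenolic site:
#' \describe{
#'   \item{BDE}{bond dissociation enthalpy, H(CM-O.) + H(H.) - H(CM-OH);
#'     first step of formal hydrogen transfer (FHT).}
#'   \item{PA}{proton affinity (deprotonation enthalpy),
#'     H(CM-O-) + H(H+) - H(CM-OH); first step of SPLET.}
#'   \item{IE}{adiabatic ionization energy,
#'     H(CM-OH+.) + H(e-) - H(CM-OH); first step of SETPT.}
#' }
#' Reaction free energies against the hydroperoxyl radical follow the same
#' pattern on Gibbs energies: products minus reactants for the PT, FHT and
#' SET channels.
NULL

.one_record <- function(rec, what) {
  if (is.data.frame(rec)) {
    if (nrow(rec) != 1L) stop(what, ": expected a single record")
    rec <- as.list(rec)
  }
  if (is.null(rec$enthalpy) || is.null(rec$gibbs_energy) || is.null(rec$role))
    stop(what, ": record needs role, enthalpy and gibbs_energy fields")
  rec
}

.check_triplet <- function(parent, other, small, roles, what) {
  parent <- .one_record(parent, what)
  other <- .one_record(other, what)
  small <- .one_record(small, what)
  got <- c(parent$role, other$role, small$role)
  if (!identical(got, roles))
    stop(what, ": expected roles (", paste(roles, collapse = ", "),
         "), got (", paste(got, collapse = ", "), ")")
  med <- c(parent$medium, other$medium, small$medium)
  if (length(unique(med)) != 1L)
    stop(what, ": records span media ", paste(unique(med), collapse = ", "))
  list(parent = parent, other = other, small = small)
}

#' Bond dissociation enthalpy of an X-H bond
#'
#' `H(radical) + H(H.) - H(parent)`, all records in the same medium.
#'
#' @param parent neutral-parent species record (single row or list).
#' @param radical X-centred radical record after homolysis.
#' @param hydrogen_atom hydrogen-atom reference record for the medium.
#' @return BDE in kcal/mol.
#' @export
bond_dissociation_enthalpy <- function(parent, radical, hydrogen_atom) {
  r <- .check_triplet(parent, radical, hydrogen_atom,
                      c("neutral", "radical", "hydrogen_atom"), "BDE")
  r$other$enthalpy + r$small$enthalpy - r$parent$enthalpy
}

#' Proton affinity (deprotonation enthalpy) of an acidic O-H
#'
#' `H(anion) + H(H+) - H(parent)`.
#'
#' @param parent neutral-parent species record.
#' @param anion deprotonated (phenoxide) record.
#' @param proton proton reference record for the medium.
#' @return PA in kcal/mol.
#' @export
proton_affinity <- function(parent, anion, proton) {
  r <- .check_triplet(parent, anion, proton,
                      c("neutral", "anion", "proton"), "PA")
  r$other$enthalpy + r$small$enthalpy - r$parent$enthalpy
}

#' Adiabatic ionization energy of a compound
#'
#' `H(cation radical) + H(e-) - H(parent)`. The electron enthalpy is
#' whatever convention the species table carries (zero, or a solvated
#' electron value); IE is a per-compound quantity, independent of site.
#'
#' @param parent neutral-parent species record.
#' @param cation_radical one-electron-oxidised record.
#' @param electron electron reference record for the medium.
#' @return IE in kcal/mol.
#' @export
ionization_energy <- function(parent, cation_radical, electron) {
  r <- .check_triplet(parent, cation_radical, electron,
                      c("neutral", "cation_radical", "electron"), "IE")
  r$other$enthalpy + r$small$enthalpy - r$parent$enthalpy
}

# role stoichiometry of the first step of each mechanism against HOO.
.mech_stoich <- list(
  PT  = list(reactants = c("neutral", "hoo_radical"),
             products  = c("anion", "hooh_cation_radical")),
  FHT = list(reactants = c("neutral", "hoo_radical"),
             products  = c("radical", "hooh")),
  SET = list(reactants = c("neutral", "hoo_radical"),
             products  = c("cation_radical", "hoo_anion"))
)

#' Reaction Gibbs energy of a mechanism's first step against HOO radical
#'
#' `sum G(products) - sum G(reactants)` with the stoichiometry fixed per
#' mechanism: PT gives phenoxide + HOOH radical cation, FHT gives phenoxyl
#' radical + HOOH, SET gives the radical cation + hydroperoxide anion.
#' Microsolvated anion/radical roles are accepted in place of the bare
#' ones for the explicit-water scenario.
#'
#' @param mechanism `"FHT"`, `"PT"` or `"SET"`.
#' @param reactants two species records (parent phenol + HOO radical).
#' @param products two species records matching the mechanism.
#' @return reaction Gibbs energy in kcal/mol.
#' @export
mechanism_free_energy <- function(mechanism, reactants, products) {
  mechanism <- match.arg(mechanism, .mechanisms)
  as_list <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else x
  }
  reactants <- as_list(reactants)
  products <- as_list(products)
  st <- .mech_stoich[[mechanism]]
  desolv <- function(r) sub("^microsolvated_", "", r)
  check_side <- function(recs, want, side) {
    got <- sort(desolv(vapply(recs, `[[`, "", "role")))
    if (!identical(got, sort(want)))
      stop(mechanism, " ", side, " must have roles {",
           paste(want, collapse = ", "), "}, got {",
           paste(got, collapse = ", "), "}")
  }
  check_side(reactants, st$reactants, "reactants")
  check_side(products, st$products, "products")
  med <- unique(vapply(c(reactants, products), `[[`, "", "medium"))
  if (length(med) != 1L)
    stop("records span media ", paste(med, collapse = ", "))
  sum(vapply(products, `[[`, 0, "gibbs_energy")) -
    sum(vapply(reactants, `[[`, 0, "gibbs_energy"))
}

#' Compose per-site thermodynamic descriptors from a species table
#'
#' For every (compound, site, medium) with a radical record the BDE and
#' FHT reaction free energy are computed; sites with an anion record also
#' get PA and the PT free energy; compounds with a cation-radical record
#' get IE and the SET free energy (replicated across the compound's
#' sites, since ionization is site-independent).
#'
#' @param species validated species table (see [read_species_table()]).
#' @return data.frame with columns `compound`, `site`, `medium`,
#'   `bond_class`, `bde`, `dg_fht`, `pa`, `dg_pt`, `ie`, `dg_set`,
#'   ordered by (medium, compound, site).
#' @export
thermo_descriptors <- function(species) {
  species <- validate_species(species)
  ref_roles <- c("hydrogen_atom", "proton", "electron", "hoo_radical",
                 "hoo_anion", "hooh", "hooh_cation_radical")
  is_site_role <- species$role %in% c("radical", "anion")
  keys <- unique(species[is_site_role, c("compound", "site", "medium")])
  if (nrow(keys) == 0L)
    return(data.frame(compound = character(), site = character(),
                      medium = character(), bond_class = character(),
                      bde = numeric(), dg_fht = numeric(), pa = numeric(),
                      dg_pt = numeric(), ie = numeric(), dg_set = numeric()))
  keys <- keys[order(keys$medium, keys$compound, keys$site), ]
  ref <- function(role, med) {
    hit <- species[species$role == role & species$medium == med, , drop = FALSE]
    if (nrow(hit) != 1L)
      stop("need exactly one ", role, " reference record in medium ", med)
    as.list(hit)
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    cmp <- keys$compound[i]; site <- keys$site[i]; med <- keys$medium[i]
    parent <- .pick_species(species, cmp, "neutral", med)
    out <- list(compound = cmp, site = site, medium = med,
                bond_class = if (grepl("^O", site)) "OH" else "CH",
                bde = NA_real_, dg_fht = NA_real_, pa = NA_real_,
                dg_pt = NA_real_, ie = NA_real_, dg_set = NA_real_)
    has <- function(role) any(species$role == role & species$medium == med &
                                species$compound == cmp &
                                !is.na(species$site) & species$site == site)
    if (has("radical")) {
      rad <- .pick_species(species, cmp, "radical", med, site)
      out$bde <- bond_dissociation_enthalpy(parent, rad, ref("hydrogen_atom", med))
      out$dg_fht <- mechanism_free_energy(
        "FHT", list(as.list(parent), ref("hoo_radical", med)),
        list(as.list(rad), ref("hooh", med)))
    }
    if (has("anion")) {
      an <- .pick_species(species, cmp, "anion", med, site)
      out$pa <- proton_affinity(parent, an, ref("proton", med))
      out$dg_pt <- mechanism_free_energy(
        "PT", list(as.list(parent), ref("hoo_radical", med)),
        list(as.list(an), ref("hooh_cation_radical", med)))
    }
    cat_sel <- species$role == "cation_radical" & species$medium == med &
      species$compound == cmp
    if (any(cat_sel)) {
      cation <- species[cat_sel, , drop = FALSE][1, ]
      out$ie <- ionization_energy(parent, cation, ref("electron", med))
      out$dg_set <- mechanism_free_energy(
        "SET", list(as.list(parent), ref("hoo_radical", med)),
        list(as.list(cation), ref("hoo_anion", med)))
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Screen mechanisms for kinetic follow-up
#'
#' A (site, mechanism) channel is retained iff its first-step reaction
#' free energy is at or below `retention_threshold`. Channels whose free
#' energy is missing (descriptor not populated) are not retained. The
#' default +10 kcal/mol keeps every mildly endergonic hydrogen-transfer
#' channel while dropping the strongly endergonic proton- and
#' electron-transfer first steps.
#'
#' @param descriptors output of [thermo_descriptors()].
#' @param retention_threshold free-energy cutoff in kcal/mol.
#' @return data.frame with `compound`, `site`, `medium`, `mechanism`,
#'   `dg`, `retained`, `reason`, ordered by (compound, site, mechanism).
#' @export
screen_mechanisms <- function(descriptors, retention_threshold = 10) {
  if (nrow(descriptors) == 0L)
    return(data.frame(compound = character(), site = character(),
                      medium = character(), mechanism = character(),
                      dg = numeric(), retained = logical(),
                      reason = character()))
  mech_col <- c(FHT = "dg_fht", PT = "dg_pt", SET = "dg_set")
  rows <- lapply(names(mech_col), function(m) {
    dg <- descriptors[[mech_col[[m]]]]
    keep <- !is.na(dg)
    if (!any(keep)) return(NULL)
    d <- descriptors[keep, c("compound", "site", "medium")]
    d$mechanism <- m
    d$dg <- dg[keep]
    d$retained <- d$dg <= retention_threshold
    d$reason <- sprintf("dG = %.1f kcal/mol %s threshold %.1f", d$dg,
                        ifelse(d$retained, "<=", ">"), retention_threshold)
    d
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$compound, res$site, res$mechanism), ]
  rownames(res) <- NULL
  res
}
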