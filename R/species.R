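#' @name species_table
#' @title Species thermochemistry tables
#'
#' @description
#' A species table holds one row per chemical species per medium: the
#' parent phenol (CM-OH), its phenoxide anion (CM-O-), phenoxyl radical
#' (CM-O.), radical cation (CM-OH+.), and the reference species entering
#' the mechanism energetics (H., H+, e-, HOO., HOO-, HOOH, HOOH+.).
#' Enthalpy and Gibbs energy are stored internally in kcal/mol at the
#' table's level of theory; reference-species energies are ordinary rows
#' supplied per medium because continuum solvation shifts them.
#'
#' Required columns: `name`, `compound`, `role`, `medium`, `charge`,
#' `enthalpy`, `gibbs_energy`. An optional `site` column ties
#' site-specific species (radical/anion at one O-H or C-H bond) to their
#' bond label, e.g. `"O14-H"`.
NULL

.species_roles <- c("neutral", "anion", "radical", "cation_radical",
                    "hydrogen_atom", "proton", "electron", "hoo_radical",
                    "hoo_anion", "hooh", "hooh_cation_radical",
                    "microsolvated_anion", "microsolvated_radical")

# roles with a fixed formal charge
.role_charge <- c(neutral = 0L, anion = -1L, radical = 0L,
                  cation_radical = 1L, hydrogen_atom = 0L, proton = 1L,
                  electron = -1L, hoo_radical = 0L, hoo_anion = -1L,
                  hooh = 0L, hooh_cation_radical = 1L,
                  microsolvated_anion = -1L, microsolvated_radical = 0L)

.species_cols <- c("name", "compound", "role", "medium", "charge",
                   "enthalpy", "gibbs_energy")

#' Validate a species table
#'
#' Checks the schema and the per-record invariants: known role, finite
#' energies, and role/charge consistency (an anion must carry charge -1,
#' a radical cation +1, and so on).
#'
#' @param df data.frame of species records.
#' @return the validated data.frame, invisibly coerced (charge to integer,
#'   energies to double).
#' @export
validate_species <- function(df) {
  missing <- setdiff(.species_cols, names(df))
  if (length(missing))
    stop("species table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  df$charge <- as.integer(df$charge)
  df$enthalpy <- as.numeric(df$enthalpy)
  df$gibbs_energy <- as.numeric(df$gibbs_energy)
  bad_role <- !df$role %in% .species_roles
  if (any(bad_role))
    stop("unknown role(s): ", paste(unique(df$role[bad_role]), collapse = ", "))
  if (any(!is.finite(df$enthalpy)) || any(!is.finite(df$gibbs_energy)))
    stop("non-finite energy in record(s): ",
         paste(df$name[!is.finite(df$enthalpy) | !is.finite(df$gibbs_energy)],
               collapse = ", "))
  expected <- .role_charge[df$role]
  mism <- df$charge != expected
  if (any(mism))
    stop("role/charge mismatch in record(s): ",
         paste(sprintf("%s (role %s expects charge %+d, got %+d)",
                       df$name[mism], df$role[mism], expected[mism],
                       df$charge[mism]), collapse = "; "))
  if (!"site" %in% names(df)) df$site <- NA_character_
  df
}

#' Read a species thermochemistry table from CSV
#'
#' @param path CSV file with the columns documented in [species_table].
#' @param units units of the `enthalpy` and `gibbs_energy` columns;
#'   energies are converted to kcal/mol on load.
#' @return validated data.frame of species records in kcal/mol.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("name,compound,role,medium,charge,enthalpy,gibbs_energy",
#'              "h_atom,ref,hydrogen_atom,gas,0,-0.49742,-0.51")
#'            , f)
#' read_species_table(f, units = "hartree")
#' @export
read_species_table <- function(path, units = c("kcal_per_mol", "hartree")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  missing <- setdiff(.species_cols, names(df))
  if (length(missing))
    stop("species table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("charge", "enthalpy", "gibbs_energy")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & nzchar(df[[col]])
    if (any(bad))
      stop("unparseable ", col, " at data line ",
           paste(which(bad), collapse = ", "), " of ", path)
    df[[col]] <- v
  }
  if (units == "hartree") {
    df$enthalpy <- convert_energy(df$enthalpy, "hartree", "kcal_per_mol")
    df$gibbs_energy <- convert_energy(df$gibbs_energy, "hartree", "kcal_per_mol")
  }
  validate_species(df)
}

#' Write a species table to CSV (kcal/mol, full precision)
#'
#' @param df validated species data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(df, path) {
  df <- validate_species(df)
  cols <- c(.species_cols, if ("site" %in% names(df)) "site")
  out <- df[, cols, drop = FALSE]
  for (col in c("enthalpy", "gibbs_energy"))
    out[[col]] <- formatC(out[[col]], format = "g", digits = 17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fetch exactly one species row; used by the descriptor builders
.pick_species <- function(df, compound, role, medium, site = NULL) {
  sel <- df$compound == compound & df$role == role & df$medium == medium
  if (!is.null(site) && "site" %in% names(df))
    sel <- sel & !is.na(df$site) & df$site == site
  hit <- df[sel, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop(sprintf("expected exactly one %s record for %s%s in %s, found %d",
                 role, compound,
                 if (is.null(site)) "" else paste0(" at ", site),
                 medium, nrow(hit)))
  hit
}
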