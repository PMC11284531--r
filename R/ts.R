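#' @name ts_table
#' @title Transition-state (barrier) tables
#'
#' @description
#' One row per reaction channel: compound, bond site, mechanism (FHT, SET
#' or PT), medium and protonation state, with the activation Gibbs energy
#' and whatever tunneling inputs are available. For FHT channels the
#' tunneling coefficient is resolved in order of preference: an explicit
#' `tunneling_coefficient` (kappa), else an Eckart evaluation from
#' `forward_barrier`/`reverse_barrier`/`imaginary_frequency`, else a
#' Wigner estimate from the imaginary frequency alone, else 1. SET
#' channels take kappa = 1; their optional `reorganization_energy` column
#' is the Marcus lambda.
#'
#' Required columns: `compound`, `site`, `mechanism`, `medium`,
#' `protonation_state`, `activation_gibbs`. Optional:
#' `imaginary_frequency` (cm-1), `forward_barrier`, `reverse_barrier`,
#' `tunneling_coefficient`, `reorganization_energy` (kcal/mol),
#' `barrierless` (logical).
NULL

.ts_required <- c("compound", "site", "mechanism", "medium",
                  "protonation_state", "activation_gibbs")
.ts_optional <- c("imaginary_frequency", "forward_barrier",
                  "reverse_barrier", "tunneling_coefficient",
                  "reorganization_energy", "barrierless")
.mechanisms <- c("FHT", "SET", "PT")
.prot_states <- c("HA", "A_minus")

#' Validate a transition-state table
#'
#' @param df data.frame of channel records.
#' @return validated data.frame with all optional columns present
#'   (`NA`-filled where absent).
#' @export
validate_ts <- function(df) {
  missing <- setdiff(.ts_required, names(df))
  if (length(missing))
    stop("TS table is missing column(s): ", paste(missing, collapse = ", "))
  for (col in .ts_optional)
    if (!col %in% names(df))
      df[[col]] <- if (col == "barrierless") FALSE else NA_real_
  if (nrow(df) == 0L) return(df)
  df$barrierless <- as.logical(df$barrierless)
  df$barrierless[is.na(df$barrierless)] <- FALSE
  num_cols <- c("activation_gibbs", .ts_optional[.ts_optional != "barrierless"])
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if (any(!df$mechanism %in% .mechanisms))
    stop("unknown mechanism(s): ",
         paste(unique(setdiff(df$mechanism, .mechanisms)), collapse = ", "))
  if (any(!df$protonation_state %in% .prot_states))
    stop("unknown protonation state(s): ",
         paste(unique(setdiff(df$protonation_state, .prot_states)),
               collapse = ", "))
  neg <- is.finite(df$activation_gibbs) & df$activation_gibbs < 0 &
    !df$barrierless
  if (any(neg))
    stop("negative activation_gibbs without barrierless flag in row(s): ",
         paste(which(neg), collapse = ", "))
  kap <- df$tunneling_coefficient
  if (any(!is.na(kap) & kap < 1))
    stop("tunneling_coefficient < 1 in row(s): ",
         paste(which(!is.na(kap) & kap < 1), collapse = ", "))
  df
}

#' Read a transition-state table from CSV
#'
#' @param path CSV file with the columns documented in [ts_table]. Energies
#'   in kcal/mol, frequencies in cm-1.
#' @return validated data.frame of channel records.
#' @export
read_ts_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  validate_ts(df)
}

#' Write a transition-state table to CSV
#'
#' @param df validated channel data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ts_table <- function(df, path) {
  df <- validate_ts(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
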