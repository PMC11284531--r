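#' @name speciation
#' @title Acid-base speciation of phenolic antioxidants
#'
#' @description
#' In water at physiological pH a phenol partitions between its neutral
#' (HA) and phenoxide (A-) forms; the tiny anion population often carries
#' essentially all of the electron-transfer reactivity. pKa values come
#' from a parametrized linear free-energy relationship on the computed
#' deprotonation free energy (the fit parameters are inputs, not built
#' in), and mole fractions follow the Henderson-Hasselbalch form.
NULL

#' pKa from a deprotonation free energy via a linear model
#'
#' `pKa = slope * dG_deprotonation + intercept`. Slope has units
#' 1/(kcal/mol); the parameters are calibration constants for a given
#' level of theory and functional-group class (e.g. phenol O-H).
#'
#' @param dg_deprotonation deprotonation free energy, kcal/mol.
#' @param slope,intercept linear-model parameters.
#' @return pKa (dimensionless), vectorized over `dg_deprotonation`.
#' @export
pka_from_deprotonation_energy <- function(dg_deprotonation, slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  slope * dg_deprotonation + intercept
}

#' Neutral/anion mole fractions of a monoprotic acid
#'
#' @param pka acid dissociation constant (pKa scale).
#' @param pH solution pH.
#' @return named numeric vector `c(neutral = , anion = )` with
#'   `anion = 1/(1 + 10^(pka - pH))`.
#' @examples
#' mole_fractions(9.43, 7.4)  # 99.1% neutral, 0.9% anion
#' @export
mole_fractions <- function(pka, pH) {
  f_anion <- 1 / (1 + 10^(pka - pH))
  c(neutral = 1 - f_anion, anion = f_anion)
}

#' Sequential-deprotonation speciation ladder
#'
#' Mole fractions of the n+1 protonation states of an n-protic acid at a
#' given pH, from the standard sequential expression
#' `f_k = 10^sum_{i<=k}(pH - pKa_i) / sum_j 10^sum_{i<=j}(pH - pKa_i)`.
#' With a single pKa this reduces exactly to [mole_fractions()].
#'
#' @param pka_values ascending vector of pKa values (acidic O-H sites
#'   only).
#' @param pH solution pH.
#' @param compound optional compound label carried into the result.
#' @return object of class `"speciation_state"`: a list with `compound`,
#'   `pH`, `pka_values` and a data.frame `fractions` (columns `state`,
#'   `n_deprotonated`, `fraction`).
#' @export
speciation_ladder <- function(pka_values, pH, compound = NA_character_) {
  stopifnot(length(pka_values) >= 1L, all(is.finite(pka_values)))
  if (is.unsorted(pka_values, strictly = FALSE))
    stop("pka_values must be sorted ascending")
  # log10 of cumulative deprotonation weights, state 0..n
  lw <- c(0, cumsum(pH - pka_values))
  lw <- lw - max(lw)                     # overflow-safe
  w <- 10^lw
  fr <- w / sum(w)
  n <- length(pka_values)
  labels <- c("HA", if (n >= 1) paste0("A", strrep("-", seq_len(n))))
  labels[2] <- "A-"
  structure(list(
    compound = compound, pH = pH, pka_values = pka_values,
    fractions = data.frame(state = labels[seq_len(n + 1L)],
                           n_deprotonated = 0:n, fraction = fr)
  ), class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("<speciation> %s at pH %.2f (pKa: %s)\n",
              if (is.na(x$compound)) "compound" else x$compound, x$pH,
              paste(format(x$pka_values), collapse = ", ")))
  f <- x$fractions
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-4s %8.4f%%\n", f$state[i], 100 * f$fraction[i]))
  invisible(x)
}

#' Speciation report over several compounds
#'
#' @param pka_table data.frame with columns `compound` and `pka1`
#'   (optionally `pka2`, ... for deeper ladders).
#' @param pH solution pH.
#' @param digits percentage rounding for the `percent` column (full
#'   precision kept in `fraction`).
#' @return data.frame with compound, pH, state, fraction and percent.
#' @export
speciation_report <- function(pka_table, pH, digits = 1) {
  pka_cols <- grep("^pka[0-9]+$", names(pka_table), value = TRUE)
  rows <- lapply(seq_len(nrow(pka_table)), function(i) {
    pkas <- sort(as.numeric(pka_table[i, pka_cols]))
    pkas <- pkas[is.finite(pkas)]
    st <- speciation_ladder(pkas, pH, compound = pka_table$compound[i])
    data.frame(compound = pka_table$compound[i], pH = pH,
               state = st$fractions$state,
               fraction = st$fractions$fraction,
               percent = round(100 * st$fractions$fraction, digits))
  })
  do.call(rbind, rows)
}
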