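#' @name assembly
#' @title Overall rate constants and branching ratios
#'
#' @description
#' Channel rates are combined into a per-compound overall rate constant.
#' Each admitted channel is weighted by the mole fraction `f` of its
#' protonation state (`k_f = f * k_app`), the overall rate is the sum of
#' the weighted rates, and branching ratios report each channel's
#' percentage contribution (`Gamma = 100 * k_f / k_overall`). The
#' channel-admission rule depends on the medium: in apolar media only
#' neutral-state hydrogen-transfer channels enter; in polar (aqueous)
#' media neutral FHT, neutral SET and anion SET channels all enter.
NULL

#' Population-weighted channel rate
#'
#' @param mole_fraction mole fraction `f` of the reacting protonation
#'   state, in \[0, 1\].
#' @param k_apparent apparent channel rate constant, M-1 s-1.
#' @return `f * k_apparent`, exact.
#' @examples
#' weighted_rate(0.009, 7.80e9)  # 7.02e7
#' @export
weighted_rate <- function(mole_fraction, k_apparent) {
  if (any(mole_fraction < 0 | mole_fraction > 1))
    stop("mole fraction must lie in [0, 1]")
  mole_fraction * k_apparent
}

# the channel-admission rule: which (mechanism, state) pairs sum into
# k_overall in each kind of medium
.admit_channel <- function(mechanism, state, polar) {
  if (polar)
    (mechanism == "FHT" & state == "HA") |
      (mechanism == "SET" & state %in% c("HA", "A_minus"))
  else
    mechanism == "FHT" & state == "HA"
}

#' Overall rate constant over a compound's channels
#'
#' Applies the channel-admission rule for the medium, weights each
#' admitted channel by its protonation-state mole fraction, sums into
#' `k_overall` and computes branching ratios. Rejected channels are
#' retained in the result with `admitted = FALSE` and a reason.
#'
#' @param branches data.frame with columns `compound`, `site`,
#'   `mechanism`, `protonation_state`, `k_app` and optionally
#'   `mole_fraction` (defaults to 1, the single-state case).
#' @param medium a [medium()] object (its `is_polar` flag selects the
#'   admission rule).
#' @param scenario free-text scenario label (e.g. `"default"` or
#'   `"explicit_water"`).
#' @return object of class `"overall_result"`: list with `compound`,
#'   `medium`, `scenario`, `k_overall` and the annotated `branches`
#'   data.frame (columns `k_f`, `gamma`, `admitted`, `reason` added).
#' @export
overall_rate <- function(branches, medium, scenario = "default") {
  if (nrow(branches) == 0L) stop("empty branch set")
  cmp <- unique(branches$compound)
  if (length(cmp) != 1L)
    stop("branches span compounds: ", paste(cmp, collapse = ", "))
  if (!"mole_fraction" %in% names(branches)) branches$mole_fraction <- 1
  if (any(branches$mole_fraction < 0 | branches$mole_fraction > 1))
    stop("mole fractions must lie in [0, 1]")
  adm <- .admit_channel(branches$mechanism, branches$protonation_state,
                        medium$is_polar)
  branches$admitted <- adm
  branches$reason <- ifelse(adm, "admitted",
                            sprintf("%s-%s channel not admitted in %s medium",
                                    branches$mechanism,
                                    branches$protonation_state,
                                    if (medium$is_polar) "polar" else "apolar"))
  branches$k_f <- ifelse(adm,
                         weighted_rate(branches$mole_fraction, branches$k_app),
                         NA_real_)
  k_overall <- sum(branches$k_f[adm])
  res <- structure(list(compound = cmp, medium = medium$name,
                        scenario = scenario, k_overall = k_overall,
                        branches = branches),
                   class = "overall_result")
  branching_ratios(res)
}

#' Branching ratios of an overall result
#'
#' `Gamma_i = 100 * k_f_i / k_overall` over the admitted channels; the
#' unrounded ratios sum to exactly 100.
#'
#' @param result an `"overall_result"` object with `k_overall > 0`.
#' @return the result with a `gamma` column on its branches.
#' @export
branching_ratios <- function(result) {
  stopifnot(inherits(result, "overall_result"))
  if (result$k_overall <= 0) stop("k_overall must be > 0")
  b <- result$branches
  b$gamma <- ifelse(b$admitted, 100 * b$k_f / result$k_overall, NA_real_)
  result$branches <- b
  result
}

#' @export
print.overall_result <- function(x, ...) {
  cat(sprintf("<overall_result> %s in %s (%s): k_overall = %.3g M-1 s-1\n",
              x$compound, x$medium, x$scenario, x$k_overall))
  b <- x$branches[x$branches$admitted, ]
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-4s %-9s %-8s f=%-7.4g k_app=%-10.3g k_f=%-10.3g Gamma=%5.1f%%\n",
                b$mechanism[i], b$protonation_state[i], b$site[i],
                b$mole_fraction[i], b$k_app[i], b$k_f[i], b$gamma[i]))
  invisible(x)
}

#' Ratio of two overall rate constants
#'
#' Used to compare scenarios (e.g. with and without an explicit water
#' molecule on the phenoxide) or media/compounds.
#'
#' @param a,b `"overall_result"` objects for the same compound, or bare
#'   numeric k_overall values.
#' @param digits rounding applied to the reported ratio; `NULL` for
#'   full precision.
#' @return `k_overall(a) / k_overall(b)`.
#' @export
compare_scenarios <- function(a, b, digits = 2) {
  k <- function(x) if (inherits(x, "overall_result")) x$k_overall else x
  if (inherits(a, "overall_result") && inherits(b, "overall_result") &&
      a$compound != b$compound &&
      a$medium == b$medium && a$scenario == b$scenario)
    message("comparing different compounds (", a$compound, " vs ",
            b$compound, ")")
  kb <- k(b)
  if (kb == 0) stop("zero denominator")
  r <- k(a) / kb
  if (is.null(digits)) r else round(r, digits)
}

#' Activity report across compounds, media and reference antioxidants
#'
#' @param results list of `"overall_result"` objects.
#' @param references optional data.frame of reference antioxidant rates
#'   with columns `name`, `k`, and optionally `note`; fold-differences
#'   of every result against every reference are reported. Empty or
#'   `NULL` omits the comparison section.
#' @return list with `overall` (data.frame compound/medium/scenario/
#'   k_overall), `branches` (row-bound branch tables) and `comparison`
#'   (fold vs references, or `NULL`), each deterministically ordered.
#' @export
activity_report <- function(results, references = NULL) {
  stopifnot(length(results) > 0)
  ov <- do.call(rbind, lapply(results, function(r)
    data.frame(compound = r$compound, medium = r$medium,
               scenario = r$scenario, k_overall = r$k_overall,
               stringsAsFactors = FALSE)))
  ov <- ov[order(ov$compound, ov$medium, ov$scenario), ]
  rownames(ov) <- NULL
  br <- do.call(rbind, lapply(results, function(r) {
    b <- r$branches
    b$medium <- r$medium; b$scenario <- r$scenario
    b
  }))
  br <- br[order(br$compound, br$medium, br$scenario, br$mechanism,
                 br$protonation_state, br$site), ]
  rownames(br) <- NULL
  comparison <- NULL
  if (!is.null(references) && nrow(references) > 0) {
    comparison <- do.call(rbind, lapply(seq_len(nrow(ov)), function(i)
      data.frame(compound = ov$compound[i], medium = ov$medium[i],
                 scenario = ov$scenario[i], reference = references$name,
                 fold = ov$k_overall[i] / references$k,
                 stringsAsFactors = FALSE)))
    rownames(comparison) <- NULL
  }
  list(overall = ov, branches = br, comparison = comparison)
}
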