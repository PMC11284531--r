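#' Reaction medium descriptor
#'
#' A medium bundles the temperature, bulk viscosity (condensed phases only),
#' pH (aqueous only) and polarity flag used by the kinetics and assembly
#' stages. The three media of the study design are gas phase, pentyl
#' ethanoate (lipid mimic) and water at physiological pH.
#'
#' @param name medium identifier, e.g. `"gas"`, `"pentyl_ethanoate"`,
#'   `"water"`.
#' @param temperature absolute temperature in K.
#' @param viscosity dynamic viscosity in Pa s, or `NA` for the gas phase.
#' @param pH solution pH, or `NA` for non-aqueous media.
#' @param is_polar logical polarity flag (controls which overall-rate
#'   channel-admission rule applies).
#' @return An object of class `"medium"` (a named list).
#' @examples
#' medium("water", viscosity = 8.91e-4, pH = 7.4, is_polar = TRUE)
#' @export
medium <- function(name, temperature = phys_constants()$T_ref,
                   viscosity = NA_real_, pH = NA_real_, is_polar = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0 K")
  if (!is.na(viscosity) && viscosity <= 0)
    stop("viscosity must be > 0 Pa s when present")
  if (!is.na(pH) && (pH < 0 || pH > 14))
    stop("pH must lie in [0, 14] when present")
  structure(list(name = name, temperature = temperature,
                 viscosity = viscosity, pH = pH, is_polar = is_polar),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s: T = %.2f K", x$name, x$temperature))
  if (!is.na(x$viscosity)) cat(sprintf(", eta = %.3g Pa s", x$viscosity))
  if (!is.na(x$pH)) cat(sprintf(", pH = %.2f", x$pH))
  cat(if (x$is_polar) ", polar\n" else ", apolar\n")
  invisible(x)
}

#' Default media of the study design
#'
#' Gas phase, pentyl ethanoate (viscosity 8.62e-4 Pa s at 298.15 K) and
#' water (8.91e-4 Pa s, pH 7.4). All values overridable by constructing
#' media directly.
#'
#' @param pH aqueous pH, default 7.4 (physiological).
#' @return named list of [medium()] objects.
#' @export
default_media <- function(pH = 7.4) {
  list(
    gas = medium("gas"),
    pentyl_ethanoate = medium("pentyl_ethanoate", viscosity = 8.62e-4),
    water = medium("water", viscosity = 8.91e-4, pH = pH, is_polar = TRUE)
  )
}
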