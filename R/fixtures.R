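#' Bundled reference dataset for cleomiscosins A, B and C
#'
#' The package ships the published DFT-derived tables for the
#' coumarinolignans cleomiscosin A/B/C reacting with the hydroperoxyl
#' radical, keyed by (compound, site, mechanism, protonation state,
#' medium, scenario):
#' \describe{
#'   \item{thermo}{per-site BDE/PA/IE and reaction free energies of the
#'     FHT/PT/SET first steps in gas, pentyl ethanoate and water.}
#'   \item{channels}{per-channel activation Gibbs energies, tunneling
#'     coefficients (FHT) or Marcus reorganization energies (SET),
#'     apparent rate constants, protonation-state mole fractions `f`,
#'     weighted rates `k_f` and branching ratios. Rows carry the
#'     row-specific regression tolerances (`tol_tst`, `tol_kf`) and the
#'     `f_convention` flag saying whether the published weighted rate
#'     used the rounded printed fraction or the full-precision fraction
#'     from the pKa.}
#'   \item{overall}{per-compound overall rate constants per medium and
#'     scenario (`default` vs `explicit_water`, the latter with one
#'     water molecule hydrogen-bonded to the phenoxide/phenoxyl pair).}
#'   \item{speciation}{pKa1 values and neutral/anion percentages at
#'     pH 7.4.}
#'   \item{references}{reference antioxidant rate constants (Trolox,
#'     ascorbic acid, resveratrol) for fold-comparisons.}
#'   \item{pka_model}{synthetic linear pKa-model calibration (see the
#'     file header: reverse-engineered to reproduce the reported pKa1
#'     values, labelled synthetic).}
#' }
#'
#' @return named list of data.frames (and a list for `pka_model`).
#' @export
cleomiscosin_data <- function() {
  path <- function(f) system.file("extdata", f, package = "radscav",
                                  mustWork = TRUE)
  read <- function(f) utils::read.csv(path(f), stringsAsFactors = FALSE,
                                      strip.white = TRUE)
  list(
    thermo = read("cleomiscosin_thermo.csv"),
    channels = read("cleomiscosin_channels.csv"),
    overall = read("cleomiscosin_overall.csv"),
    speciation = read("cleomiscosin_speciation.csv"),
    references = read("reference_antioxidants.csv"),
    pka_model = yaml::read_yaml(path("pka_model_synthetic.yaml"))
  )
}
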