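#' Thermodynamic constants for the free-energy to pKi conversion
#'
#' Behind the binding efficiency index sits the relation
#' \eqn{\Delta G = -RT \ln K_i}, so that
#' \eqn{pK_i = -\Delta G / (\ln 10 \cdot R T)}.  At the default temperature
#' of 298.15 K the conversion factor \eqn{c = \ln 10 \cdot R T} is about
#' 1.364 kcal/mol.
#'
#' @param temperature_K absolute temperature in kelvin.
#' @param R gas constant in kcal mol^-1 K^-1.
#' @return list with `R`, `T` and the conversion factor `c` (kcal/mol per
#'   pKi unit).
#' @export
thermo_constants <- function(temperature_K = 298.15, R = 0.0019872) {
  stopifnot(temperature_K > 0, R > 0)
  list(R = R, T = temperature_K, c = log(10) * R * temperature_K)
}

#' Convert a binding free energy to pKi
#'
#' @param delta_g binding free energy in kcal/mol (negative = favorable).
#' @param constants from [thermo_constants()].
#' @return pKi (dimensionless); vectorised over `delta_g`.
#' @export
delta_g_to_pki <- function(delta_g, constants = thermo_constants()) {
  -delta_g / constants$c
}

#' Ligand efficiency
#'
#' \eqn{LE = -\Delta G_b / HAC}: binding free energy per heavy atom.
#'
#' @param delta_g binding free energy in kcal/mol.
#' @param hac heavy atom count (>= 1).
#' @return LE in kcal/mol per heavy atom; vectorised.
#' @export
ligand_efficiency <- function(delta_g, hac) {
  if (any(hac < 1L)) stop("heavy atom count must be >= 1")
  -delta_g / hac
}

#' Binding efficiency index
#'
#' \eqn{BEI = pK_i / MW(kDa)}: potency per kilodalton of molecular weight,
#' which weights heteroatoms from lower periodic rows more heavily than the
#' per-atom ligand efficiency does.
#'
#' @param pki pKi value(s).
#' @param mw molecular weight in daltons (> 0).
#' @return BEI; vectorised.
#' @export
binding_efficiency_index <- function(pki, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  pki / (mw / 1000)
}

#' Score a set of binding records
#'
#' Applies the energy-to-pKi conversion, ligand efficiency and binding
#' efficiency index to every record, pairing each with its descriptors.
#'
#' @param records data.frame with columns `id`, `delta_g` (kcal/mol) and
#'   optionally `ic50_nM`.
#' @param descriptors data.frame with columns `id`, `HAC`, `MW`.
#' @param constants from [thermo_constants()].
#' @return data.frame with columns `id`, `delta_g`, `pKi`, `LE`, `BEI`.
#' @export
score_fragments <- function(records, descriptors,
                            constants = thermo_constants()) {
  if (!nrow(records))
    return(data.frame(id = character(), delta_g = numeric(), pKi = numeric(),
                      LE = numeric(), BEI = numeric()))
  m <- match(records$id, descriptors$id)
  if (anyNA(m))
    stop("no descriptors for record id(s): ",
         paste(records$id[is.na(m)], collapse = ", "))
  pki <- delta_g_to_pki(records$delta_g, constants)
  data.frame(
    id = records$id,
    delta_g = records$delta_g,
    pKi = pki,
    LE = ligand_efficiency(records$delta_g, descriptors$HAC[m]),
    BEI = binding_efficiency_index(pki, descriptors$MW[m]),
    stringsAsFactors = FALSE)
}

#' Min-max normalisation of a score series
#'
#' Scales a series to the unit interval.  Binding energies are normalised on
#' their magnitude (`on_magnitude = TRUE`) so that stronger binding maps to
#' larger values, making the BE, LE and BEI curves directly comparable.
#'
#' @param values numeric vector, length >= 2.
#' @param on_magnitude take `abs(values)` first (use for binding energies).
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_series <- function(values, on_magnitude = FALSE) {
  if (length(values) < 2L)
    stop("normalisation needs at least two values")
  v <- if (on_magnitude) abs(values) else values
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate range: all values equal, cannot normalise")
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Difference between normalised BEI and LE series
#'
#' The per-fragment divergence \eqn{\Delta E = BEI_{norm} - LE_{norm}}.
#' Fragments whose per-atom mass is unusual (e.g. sulfur-rich) show the
#' largest magnitudes.
#'
#' @param norm_bei,norm_le equal-length normalised series, paired by
#'   position.
#' @return numeric vector.
#' @export
delta_e_series <- function(norm_bei, norm_le) {
  if (length(norm_bei) != length(norm_le))
    stop("series lengths differ: ", length(norm_bei), " vs ", length(norm_le))
  norm_bei - norm_le
}

#' Normalised score table
#'
#' Convenience wrapper producing the full plotted series: normalised BE
#' (on magnitude), LE, BEI and their difference.
#'
#' @param scores data.frame from [score_fragments()].
#' @return `scores` with added columns `BE_norm`, `LE_norm`, `BEI_norm`,
#'   `delta_E`.
#' @export
normalized_scores <- function(scores) {
  scores$BE_norm <- normalize_series(scores$delta_g, on_magnitude = TRUE)
  scores$LE_norm <- normalize_series(scores$LE)
  scores$BEI_norm <- normalize_series(scores$BEI)
  scores$delta_E <- delta_e_series(scores$BEI_norm, scores$LE_norm)
  scores
}

#' Plot normalised efficiency series
#'
#' Line plot of normalised binding energy, LE, BEI and the BEI-LE
#' difference against fragment index.
#'
#' @param scores output of [normalized_scores()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_efficiency_series <- function(scores, ...) {
  idx <- seq_len(nrow(scores))
  graphics::plot(idx, scores$BE_norm, type = "l", lty = 2, col = "blue",
                 ylim = range(c(scores$BE_norm, scores$LE_norm,
                                scores$BEI_norm, scores$delta_E)),
                 xlab = "fragment", ylab = "normalised score", ...)
  graphics::lines(idx, scores$LE_norm, col = "red")
  graphics::lines(idx, scores$BEI_norm, col = "darkgreen", lty = 3)
  graphics::lines(idx, scores$delta_E, col = "violet", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("BE (norm)", "LE (norm)", "BEI (norm)",
                              "dE = BEI - LE"),
                   col = c("blue", "red", "darkgreen", "violet"),
                   lty = c(2, 1, 3, 1), lwd = c(1, 1, 1, 2))
  invisible(scores)
}
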