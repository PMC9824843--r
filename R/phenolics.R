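#' Dilution scheme for UV quantification
#'
#' Describes how a lignosulphonate sample is carried from the balance to
#' the cuvette: a weighed mass dissolved in a primary volumetric flask, an
#' aliquot of that solution diluted to the cuvette volume, and the optical
#' path length. The default mirrors the standard LS-content procedure:
#' 0.5 g to 1000 mL, then 0.5 mL diluted to 3.0 mL in a 1 cm quartz
#' cuvette.
#'
#' @param sample_mass Sample mass weighed, g.
#' @param primary_volume Primary flask volume, L.
#' @param aliquot_volume Aliquot taken from the primary solution, L.
#' @param final_volume Volume the aliquot is diluted to in the cuvette, L.
#' @param path_length Optical path, cm.
#' @return An object of class `"dilution_scheme"`.
#' @export
dilution_scheme <- function(sample_mass = 0.5, primary_volume = 1.0,
                            aliquot_volume = 0.5e-3, final_volume = 3.0e-3,
                            path_length = 1) {
  v <- c(sample_mass = sample_mass, primary_volume = primary_volume,
         aliquot_volume = aliquot_volume, final_volume = final_volume,
         path_length = path_length)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all dilution-scheme quantities must be positive and finite",
         call. = FALSE)
  if (aliquot_volume > final_volume)
    stop("'aliquot_volume' cannot exceed 'final_volume'", call. = FALSE)
  structure(as.list(v), class = "dilution_scheme")
}

#' Lignosulphonate content from absorbance at 232.5 nm
#'
#' Inverts the Beer-Lambert law at the LS band: the cuvette concentration
#' is `A / (epsilon * path)`, which is propagated back through the
#' dilution scheme to a mass percentage of the weighed sample. The default
#' extinction coefficient is 24.5 L g^-1 cm^-1.
#'
#' @param A232 Absorbance at 232.5 nm (dimensionless, >= 0).
#' @param scheme A [dilution_scheme()].
#' @param epsilon Mass extinction coefficient, L g^-1 cm^-1.
#' @return LS content as a percentage of the sample mass.
#' @examples
#' ls_content_from_absorbance(0.684, dilution_scheme())  # 33.5
#' @export
ls_content_from_absorbance <- function(A232, scheme = dilution_scheme(),
                                       epsilon = 24.5) {
  stopifnot(inherits(scheme, "dilution_scheme"))
  if (any(!is.finite(A232)) || any(A232 < 0))
    stop("'A232' must be finite and non-negative", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be positive", call. = FALSE)
  conc_cuvette <- A232 / (epsilon * scheme$path_length)          # g/L
  conc_primary <- conc_cuvette * scheme$final_volume / scheme$aliquot_volume
  ls_mass <- conc_primary * scheme$primary_volume                # g
  100 * ls_mass / scheme$sample_mass
}

#' Forward Beer-Lambert: absorbance expected from a known LS content
#'
#' The exact inverse of [ls_content_from_absorbance()]; used to
#' synthesise instrument readings for round-trip checks.
#'
#' @param content_pct LS content, % of sample mass.
#' @inheritParams ls_content_from_absorbance
#' @return Absorbance at 232.5 nm.
#' @export
ls_absorbance_from_content <- function(content_pct,
                                       scheme = dilution_scheme(),
                                       epsilon = 24.5) {
  stopifnot(inherits(scheme, "dilution_scheme"))
  conc_primary <- content_pct / 100 * scheme$sample_mass / scheme$primary_volume
  conc_cuvette <- conc_primary * scheme$aliquot_volume / scheme$final_volume
  conc_cuvette * epsilon * scheme$path_length
}

#' Coefficients for differential-ionization phenolic OH quantification
#'
#' Phenolic hydroxyl groups are classified by ionization behaviour: types
#' I and II ionize at pH 12, types III and IV only in 0.2 M NaOH. The
#' content of each class is obtained as a linear combination of the two
#' ionization-difference absorptivity maxima (near 300 and 360 nm):
#' `content = a300 * d300 + a360 * d360`, with the pH 12 difference
#' spectrum giving types I+II and the NaOH difference spectrum the total.
#'
#' The numerical values shipped here are implementation defaults chosen so
#' the generator and the quantifier form a consistent closed loop; they
#' are a documented configuration object, not literature constants, and
#' should be replaced with calibrated values for real instruments.
#' `peak_ratio` is used only by the spectrum generator: the ratio of the
#' 360 nm to the 300 nm band height it synthesises.
#'
#' @param a300,a360 Weights, % per (L g^-1 cm^-1).
#' @param peak_ratio Generator-side 360/300 band-height ratio.
#' @return An object of class `"zakis_coefficients"`.
#' @export
zakis_coefficients <- function(a300 = 0.25, a360 = 0.15, peak_ratio = 0.6) {
  if (!is.finite(a300) || !is.finite(a360) || a300 + a360 <= 0)
    stop("coefficients must be finite with positive sum", call. = FALSE)
  if (!is.finite(peak_ratio) || peak_ratio < 0)
    stop("'peak_ratio' must be non-negative", call. = FALSE)
  structure(list(a300 = a300, a360 = a360, peak_ratio = peak_ratio),
            class = "zakis_coefficients")
}

# quadratic refinement of a local maximum on a regular grid; exact when
# the apex sits on a grid point of a symmetric peak
refine_peak <- function(wl, y, i) {
  if (i <= 1L || i >= length(y)) return(c(wl[i], y[i]))
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps) return(c(wl[i], y2))
  d <- 0.5 * (y1 - y3) / denom
  d <- max(min(d, 1), -1)
  h <- wl[i + 1] - wl[i]
  c(wl[i] + d * h, y2 - 0.25 * (y1 - y3) * d)
}

#' Differential ionization spectrum
#'
#' Computes the absorptivity difference between an alkaline measurement
#' (pH 12 buffer or 0.2 M NaOH) and the pH 6 reference of the same
#' solution: `(A_alk - A_ref) / (mass_conc * path)`, in L g^-1 cm^-1.
#' Locates the two ionization maxima expected near 300 and 360 nm by grid
#' argmax within +/- 20 nm of each nominal position, refined by local
#' quadratic interpolation. A maximum that falls on the window edge is
#' flagged as not found.
#'
#' @param alkaline,reference_pH6 Data frames with columns `wavelength_nm`
#'   and `absorbance` on identical strictly increasing grids.
#' @param mass_conc Lignosulphonate mass concentration in the cuvette, g/L.
#' @param path Optical path, cm.
#' @param peak_targets Nominal maxima positions, nm.
#' @param window Half-width of the search window, nm.
#' @return An object of class `"ionization_spectrum"`: list with
#'   `wavelengths`, `delta_absorptivity` and a data frame `maxima`
#'   (`target`, `wavelength_nm`, `height`, `found`).
#' @export
ionization_difference <- function(alkaline, reference_pH6, mass_conc,
                                  path = 1, peak_targets = c(300, 360),
                                  window = 20) {
  for (s in list(alkaline, reference_pH6))
    if (!all(c("wavelength_nm", "absorbance") %in% names(s)))
      stop("spectra need columns 'wavelength_nm' and 'absorbance'",
           call. = FALSE)
  wl <- alkaline$wavelength_nm
  if (!isTRUE(all.equal(wl, reference_pH6$wavelength_nm, tolerance = 0)))
    stop("alkaline and reference spectra are on different wavelength grids",
         call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (!is.finite(mass_conc) || mass_conc <= 0)
    stop("'mass_conc' must be positive", call. = FALSE)

  delta <- (alkaline$absorbance - reference_pH6$absorbance) / (mass_conc * path)
  flat <- diff(range(delta)) < .Machine$double.eps * 100

  maxima <- do.call(rbind, lapply(peak_targets, function(tgt) {
    in_win <- which(wl >= tgt - window & wl <= tgt + window)
    if (length(in_win) < 3L || flat)
      return(data.frame(target = tgt, wavelength_nm = NA_real_,
                        height = NA_real_, found = FALSE))
    i <- in_win[which.max(delta[in_win])]
    on_edge <- i == in_win[1] || i == in_win[length(in_win)]
    pk <- refine_peak(wl, delta, i)
    data.frame(target = tgt, wavelength_nm = pk[1], height = pk[2],
               found = !on_edge)
  }))

  structure(list(wavelengths = wl, delta_absorptivity = delta,
                 maxima = maxima),
            class = "ionization_spectrum")
}

#' @export
print.ionization_spectrum <- function(x, ...) {
  cat(sprintf("Ionization difference spectrum: %d points, %g-%g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  print(x$maxima, row.names = FALSE)
  invisible(x)
}

#' Phenolic hydroxyl content from ionization-difference maxima
#'
#' Types I+II come from the pH 12 difference maxima, the total from the
#' 0.2 M NaOH maxima; types III+IV are the difference, floored at zero
#' with a warning when the measurements are inconsistent.
#'
#' @param delta_eps_300_pH12,delta_eps_360_pH12 Heights of the 300/360 nm
#'   maxima of the pH 12 difference spectrum, L g^-1 cm^-1.
#' @param delta_eps_300_NaOH,delta_eps_360_NaOH Same for the NaOH
#'   difference spectrum.
#' @param coefficients A [zakis_coefficients()] set.
#' @return An object of class `"phenolic_oh_content"`: list with
#'   `oh_I_II`, `oh_III_IV`, `oh_total`, all % mass on a dry LS basis.
#' @export
phenolic_oh_content <- function(delta_eps_300_pH12, delta_eps_360_pH12,
                                delta_eps_300_NaOH, delta_eps_360_NaOH,
                                coefficients = zakis_coefficients()) {
  if (!inherits(coefficients, "zakis_coefficients"))
    stop("'coefficients' must be a zakis_coefficients() set", call. = FALSE)
  v <- c(delta_eps_300_pH12, delta_eps_360_pH12,
         delta_eps_300_NaOH, delta_eps_360_NaOH)
  if (any(!is.finite(v)))
    stop("all four difference-maxima heights must be finite", call. = FALSE)
  oh_I_II <- coefficients$a300 * delta_eps_300_pH12 +
    coefficients$a360 * delta_eps_360_pH12
  oh_total <- coefficients$a300 * delta_eps_300_NaOH +
    coefficients$a360 * delta_eps_360_NaOH
  oh_III_IV <- oh_total - oh_I_II
  if (oh_III_IV < 0) {
    warning("NaOH total below pH-12 content; flooring [OH]III+IV at 0")
    oh_III_IV <- 0
    oh_total <- oh_I_II
  }
  structure(list(oh_I_II = oh_I_II, oh_III_IV = oh_III_IV,
                 oh_total = oh_total),
            class = "phenolic_oh_content")
}

#' @export
print.phenolic_oh_content <- function(x, ...) {
  cat("Phenolic hydroxyl content (% mass, dry LS basis)\n")
  cat(sprintf("  [OH]I+II      = %.4f\n", x$oh_I_II))
  cat(sprintf("  [OH]III+IV    = %.4f\n", x$oh_III_IV))
  cat(sprintf("  [OH]I+II+III+IV = %.4f\n", x$oh_total))
  invisible(x)
}

#' Reaction-medium [POH] from an hourly off-line sample
#'
#' Converts a measured type I+II phenolic hydroxyl mass percentage (dry LS
#' basis) into the molar concentration of phenolic OH groups in the
#' reaction medium, using a per-hydroxyl formula mass of 17.007 g/mol.
#' The sampling dilution (mass of reaction medium into a volumetric
#' flask) cancels in the back-conversion but is validated for sanity.
#'
#' @param reaction_mass Mass of reaction medium sampled, g.
#' @param flask_volume Volumetric flask the sample is diluted in, L.
#' @param measured A [phenolic_oh_content()] result (or a list with an
#'   `oh_I_II` element).
#' @param ls_conc_in_medium Lignosulphonate concentration in the reaction
#'   medium, g/L (280 g/L in the standard procedure).
#' @return Type I+II phenolic hydroxyl concentration in the medium, mol/L.
#' @examples
#' m <- list(oh_I_II = 2.23)
#' offline_poh_sample(0.15, 0.05, m, 280)  # ~0.367
#' @export
offline_poh_sample <- function(reaction_mass = 0.15, flask_volume = 0.05,
                               measured, ls_conc_in_medium = 280) {
  if (!is.finite(reaction_mass) || reaction_mass <= 0 ||
      !is.finite(flask_volume) || flask_volume <= 0 ||
      !is.finite(ls_conc_in_medium) || ls_conc_in_medium <= 0)
    stop("masses, volumes and concentrations must be positive", call. = FALSE)
  oh <- measured$oh_I_II
  if (is.null(oh) || !is.finite(oh) || oh < 0)
    stop("'measured' must carry a non-negative 'oh_I_II' percentage",
         call. = FALSE)
  ls_conc_in_medium * (oh / 100) / 17.007
}
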