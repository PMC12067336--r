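#' Packaged mass-attenuation coefficients at 24 keV
#'
#' Mass attenuation coefficients (cm^2/g) at the working energy of 24 keV,
#' log-log interpolated from the NIST XCOM/Hubbell-Seltzer tables between
#' the tabulated 20 and 30 keV values.  These are packaged defaults for the
#' mineral calibration and dose bookkeeping; pass your own values to the
#' functions that take them if higher accuracy is needed.
#'
#' @param material one or more of `"water"`, `"alumina"`,
#'   `"hydroxyapatite"`, `"cortical_bone"`.
#' @return named numeric vector of mass attenuation coefficients, cm^2/g.
#' @examples
#' massAttenuation(c("water", "alumina"))
#' @export
massAttenuation <- function(material) {
  tab <- c(water = 0.5730, alumina = 1.374, hydroxyapatite = 2.195,
           cortical_bone = 2.438)
  bad <- setdiff(material, names(tab))
  if (length(bad))
    stop("unknown material(s): ", paste(bad, collapse = ", "))
  tab[material]
}

#' Tabulated densities of the reference materials
#'
#' @param material one or more of `"water"`, `"alumina"`.
#' @return named numeric vector of densities, g/cm^3.
#' @examples
#' referenceDensity("alumina")
#' @export
referenceDensity <- function(material) {
  tab <- c(water = 1.00, alumina = 3.95)
  bad <- setdiff(material, names(tab))
  if (length(bad))
    stop("no packaged density for: ", paste(bad, collapse = ", "))
  tab[material]
}
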