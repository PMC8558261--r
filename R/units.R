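# Internal unit system: micrometre, millisecond, millivolt, nanoampere.
# Derived electrical units are then MOhm (= mV/nA), microsiemens (1/MOhm) and
# nanofarad (nF = uS * ms), so tau = C/G falls out in ms with no extra factors.
# Specific membrane constants keep their conventional units (Rm in Ohm*cm^2,
# Cm in uF/cm^2, Ra in Ohm*cm); every conversion lives here.

# membrane leak conductance of an area in um^2 -> uS
leak_conductance_uS <- function(area_um2, Rm_ohm_cm2) {
  # area[cm^2] = area_um2 * 1e-8 ; G[S] = area/Rm ; uS = S * 1e6
  area_um2 * 1e-2 / Rm_ohm_cm2
}

# membrane capacitance of an area in um^2 -> nF
capacitance_nF <- function(area_um2, Cm_uF_cm2) {
  # C[uF] = Cm * area*1e-8 ; nF = uF * 1e3
  Cm_uF_cm2 * area_um2 * 1e-5
}

# axial resistance of a cylinder (length l, diameter d, both um) -> MOhm
axial_resistance_MOhm <- function(l_um, d_um, Ra_ohm_cm) {
  # Ra[Ohm*um] = Ra * 1e4 ; R[Ohm] = 4*Ra*l/(pi*d^2) ; MOhm = Ohm * 1e-6
  4 * Ra_ohm_cm * l_um / (pi * d_um^2) * 1e-2
}

#' Passive space constant of a cylindrical cable
#'
#' \eqn{\lambda = \sqrt{d \, R_m / (4 R_a)}}, the length over which steady
#' voltage decays by a factor e in a semi-infinite cable.  When dendritic
#' spines are folded into the membrane ("q-factor" correction) the specific
#' membrane resistance entering the formula is the corrected value
#' \eqn{R_m / q}.
#'
#' @param d_um cable diameter (micrometres).
#' @param Rm_ohm_cm2 specific membrane resistance (Ohm cm^2), already divided
#'   by the spine-correction factor q if spines are folded in.
#' @param Ra_ohm_cm axial resistivity of the cytosol (Ohm cm).
#' @return space constant in micrometres.
#' @examples
#' space_constant(1, 10000, 150) # 408.25 um
#' @export
space_constant <- function(d_um, Rm_ohm_cm2, Ra_ohm_cm) {
  if (any(d_um <= 0) || any(Rm_ohm_cm2 <= 0) || any(Ra_ohm_cm <= 0)) {
    abort("space_constant() needs strictly positive d, Rm and Ra.")
  }
  # d[cm] = d*1e-4 ; lambda[cm] = sqrt(d_cm*Rm/(4Ra)) ; um = cm * 1e4
  1e2 * sqrt(d_um * Rm_ohm_cm2 / (4 * Ra_ohm_cm))
}
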