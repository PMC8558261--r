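# Shared fixtures: tiny analytic morphologies and membrane presets.

# single-point soma morphology of radius r (isopotential sphere)
iso_soma <- function(r = 5) {
  as_morphology(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                           radius = r, parent_id = -1))
}

# canonical passive constants without spines (Rm 10 kOhm cm^2, Cm 1, Ra 150)
plain_params <- function(spine_density = 0, Rm = 10000, Cm = 1) {
  membrane_params(Rm = Rm, Cm = Cm, Ra = 150, E_leak = -75,
                  spine_density = spine_density, spine_area = 1.5)
}

# hand-built asymmetric branched tree: soma + two basal branches of
# different lengths plus one apical branch
small_tree <- function() {
  pts <- rbind(
    c(1, 1, 0, 0, 0, 4, -1),
    c(2, 3, 10, 0, 0, 0.6, 1),
    c(3, 3, 40, 0, 0, 0.6, 2),
    c(4, 3, 80, 0, 0, 0.5, 3),
    c(5, 3, 40, 25, 0, 0.4, 3),
    c(6, 3, 40, 60, 0, 0.4, 5),
    c(7, 4, 0, 12, 0, 0.9, 1),
    c(8, 4, 0, 60, 0, 0.8, 7),
    c(9, 4, 0, 120, 0, 0.7, 8))
  as_morphology(as.data.frame(pts))
}

# sealed-cable analytic input resistance R_inf * coth(L)
coth_rin <- function(d, l, Rm, Ra) {
  lam <- dendrisig::space_constant(d, Rm, Ra)
  Rinf <- (2 / pi) * sqrt(Rm * Ra) * (d * 1e-4)^(-1.5) / 1e6   # MOhm
  Rinf / tanh(l / lam)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
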