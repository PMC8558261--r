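test_that("steady solution matches RC and sealed-cable closed forms", {
  p <- plain_params()
  solo <- compartmentalize(iso_soma(5), p)
  A <- 4 * pi * 25
  v <- solve_steady(solo, 1, I = 0.01)
  expect_equal(v[1] / 0.01, p$Rm / (A * 1e-2), tolerance = 1e-12)  # Rin = Rm/A
  # Kirchhoff: total leak current equals injected current
  sys <- assemble_system(solo)
  expect_equal(sum(sys$G %*% v), 0.01, tolerance = 1e-9)

  # sealed finite cable without soma: R_inf * coth(L) within 0.5%
  cc <- compartmentalize(make_cylinder(1, 400, 201, soma = FALSE), p, max_len = 2)
  expect_rel(input_resistance(cc), coth_rin(1, 400, p$Rm, p$Ra), 0.005)

  # Rall 3/2 tree matches its equivalent cylinder within 1% at 5-um spacing
  rt <- compartmentalize(make_rall_tree(2, 3, 150), p, max_len = 5)
  lam <- space_constant(c(2, 2 / 2^(2 / 3), 2 / 2^(4 / 3)), p$Rm, p$Ra)
  L <- sum(150 / lam)
  Rinf <- (2 / pi) * sqrt(p$Rm * p$Ra) * (2e-4)^(-1.5) / 1e6
  expect_rel(input_resistance(rt), Rinf / tanh(L), 0.01)

  # passive attenuation: somatic injection decays monotonically outward
  cab <- compartmentalize(make_cylinder(1, 400, 81), p)
  v <- solve_steady(cab, 1, I = 0.01)
  expect_true(all(diff(v) <= 1e-15))
})

test_that("phasor solution has the right DC limit and RC magnitude", {
  p <- plain_params()
  solo <- compartmentalize(iso_soma(5), p)
  R <- input_resistance(solo); C <- solo$compartments$c_nF
  vph <- solve_phasor(solo, 1, f = 50, I = 0.01)
  expect_equal(Mod(vph), 0.01 * R / sqrt(1 + (2 * pi * 50 * 1e-3 * R * C)^2),
               tolerance = 1e-12)
  vdc <- solve_phasor(solo, 1, f = 1e-4, I = 0.01)
  expect_rel(Mod(vdc), solve_steady(solo, 1, 0.01), 1e-6)
  expect_error(solve_phasor(solo, 1, f = 0))
})

test_that("phasor and time-domain sinusoid amplitudes agree within 0.5%", {
  cm <- compartmentalize(small_tree(), plain_params(spine_density = 1.25))
  site <- nrow(cm$compartments)
  ph <- Mod(solve_phasor(cm, site, f = 50, I = 0.1))[cm$soma]
  tr <- simulate_traces(cm, stimulus("sinusoid_current", site, amplitude = 0.1,
                                     frequency = 50),
                        t_stop = 120, record = cm$soma)
  late <- tr$v[tr$times > 100, 1]   # > 5 tau settling
  expect_rel((max(late) - min(late)) / 2, ph, 0.005)
})

test_that("Crank-Nicolson reproduces the RC step response and 63% criterion", {
  p <- plain_params()            # tau = Rm*Cm = 10 ms
  solo <- compartmentalize(iso_soma(5), p)
  tr <- simulate_traces(solo, stimulus("current_step", 1, amplitude = 0.01,
                                       duration = 200), t_stop = 200)
  R <- input_resistance(solo)
  analytic <- 0.01 * R * (1 - exp(-tr$times / 10))
  expect_lt(max(abs(tr$v[, 1] - analytic)) / (0.01 * R), 1e-4)
  expect_equal(time_constant(solo), 10, tolerance = 0.025 / 10)  # within dt

  # no stimulus: identically zero deviation
  tr0 <- simulate_traces(solo, list(), t_stop = 5)
  expect_true(all(tr0$v == 0))
})

test_that("input resistance is amplitude-invariant and decreases with a dendrite", {
  p <- plain_params()
  solo <- compartmentalize(iso_soma(5), p)
  expect_equal(solve_steady(solo, 1, 0.01)[1] / 0.01,
               solve_steady(solo, 1, 1)[1] / 1, tolerance = 1e-12)
  with_dend <- compartmentalize(make_cylinder(10, 200, 21), p)
  expect_lt(input_resistance(with_dend), input_resistance(solo))
})

test_that("alpha-conductance EPSPs saturate with driving force", {
  cm <- compartmentalize(small_tree(), plain_params(spine_density = 1.25))
  site <- nrow(cm$compartments)
  peak <- function(g) {
    tr <- simulate_traces(cm, stimulus("alpha_conductance", site, g_max = g),
                          t_stop = 50, record = site)
    max(tr$v)
  }
  expect_lt(peak(25) / peak(0.25), 100 * 0.9)   # clearly sublinear
})

test_that("voltage transfer is reciprocal between any two sites", {
  p <- plain_params(spine_density = 1.25)
  for (seed in 1:3) {
    m <- sample_population(group_params(n_basal_stems = 2,
                                        apical_trunk_length = 120,
                                        max_total_extent = 300),
                           1, seed = seed)[[1]]
    cm <- compartmentalize(m, p)
    n <- nrow(cm$compartments)
    i <- 2L; j <- n
    vi <- solve_steady(cm, i, 0.01)
    vj <- solve_steady(cm, j, 0.01)
    expect_rel(vi[j], vj[i], 1e-10)
  }
})

test_that("charge is conserved in transient runs", {
  cm <- compartmentalize(small_tree(), plain_params(spine_density = 1.25))
  site <- nrow(cm$compartments)
  tr <- simulate_traces(cm, stimulus("alpha_current", site, amplitude = 0.25,
                                     t_peak = 0.5), t_stop = 300)
  sys <- assemble_system(cm)
  dt <- tr$dt
  trapz <- function(y) (sum(y) - (y[1] + y[length(y)]) / 2) * dt
  q_in <- trapz(tr$i_inj[, 1])
  q_cap <- sum(sys$C * tr$v[nrow(tr$v), ])
  q_leak <- sum(vapply(seq_len(ncol(tr$v)),
                       function(k) trapz(tr$v[, k]) * cm$compartments$g_leak_uS[k],
                       numeric(1)))
  expect_rel(q_cap + q_leak, q_in, 0.001)
})

test_that("halving dt changes the somatic EPSP peak by < 0.1%", {
  cm <- compartmentalize(small_tree(), plain_params(spine_density = 1.25))
  site <- nrow(cm$compartments)
  pk <- function(dt) {
    tr <- simulate_traces(cm, stimulus("alpha_conductance", site, g_max = 0.25),
                          t_stop = 60, dt = dt, record = cm$soma)
    max(tr$v)
  }
  expect_rel(pk(0.0125), pk(0.025), 0.001)
})
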