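# shared model fixtures for descriptor tests
desc_cable <- function() {
  compartmentalize(make_cylinder(1, 400, 81), plain_params(), max_len = 10)
}
desc_tree <- function(seed = 2) {
  m <- sample_population(group_params(n_basal_stems = 2, apical_trunk_length = 120,
                                      max_total_extent = 300), 1, seed = seed)[[1]]
  compartmentalize(m, plain_params(spine_density = 1.25))
}

test_that("voltage transfers attenuate and respect the low-pass property", {
  cm <- desc_cable()
  expect_equal(voltage_transfer_ss(cm, cm$soma), 1)
  sites <- which(cm$compartments$kind == "dendrite")
  vt <- vapply(sites, function(s) voltage_transfer_ss(cm, s), numeric(1))
  expect_true(all(diff(vt) < 0))           # monotone along the cable
  expect_true(all(vt > 0 & vt <= 1))

  tip <- sites[length(sites)]
  vt50 <- voltage_transfer_sin(cm, tip, f = 50)
  expect_lt(vt50, voltage_transfer_ss(cm, tip))
  fs <- c(1, 10, 50, 100)
  vts <- vapply(fs, function(f) voltage_transfer_sin(cm, tip, f), numeric(1))
  expect_true(all(diff(vts) < 0))          # non-increasing in frequency
  expect_rel(voltage_transfer_sin(cm, tip, f = 1e-4),
             voltage_transfer_ss(cm, tip), 1e-6)
})

test_that("steady tip-to-origin attenuation matches the cosh ratio", {
  p <- plain_params()
  cc <- compartmentalize(make_cylinder(1, 400, 201, soma = FALSE), p, max_len = 2)
  lam <- space_constant(1, p$Rm, p$Ra)
  n <- nrow(cc$compartments)
  v <- solve_steady(cc, n, 0.01)
  x <- cc$compartments$path_dist
  analytic <- cosh(x[1] / lam) / cosh(x[n] / lam)
  expect_rel(v[1] / v[n], analytic, 0.005)
})

test_that("current transfer equals the reverse voltage transfer (reciprocity)", {
  for (seed in 1:2) {
    cm <- desc_tree(seed)
    sites <- which(cm$compartments$kind == "dendrite")
    ct <- vapply(sites, function(s) current_transfer(cm, s), numeric(1))
    v_soma <- solve_steady(cm, cm$soma, 0.01)
    vt_rev <- v_soma[sites] / v_soma[cm$soma]
    expect_rel(ct, vt_rev, 1e-8)
  }
  cm <- desc_cable()
  expect_equal(current_transfer(cm, cm$soma), 1)
  sites <- which(cm$compartments$kind == "dendrite")
  ct <- vapply(sites, function(s) current_transfer(cm, s), numeric(1))
  expect_true(all(diff(ct) < 0))   # distal sites deliver less charge
})

test_that("centroid delays: RC local delay, zero somatic propagation, input shape independence", {
  p <- plain_params()              # tau = 10 ms
  solo <- compartmentalize(iso_soma(5), p)
  expect_equal(delays_moment(solo, 1)$delay_local, 10, tolerance = 1e-10)
  d_td <- delays(solo, 1, t_stop = 200)
  expect_equal(d_td$delay_local, 10, tolerance = 0.01)

  cm <- desc_tree()
  d_soma <- delays(cm, cm$soma, t_stop = 250)
  expect_equal(d_soma$delay_prop, 0, tolerance = 1e-9)

  site <- nrow(cm$compartments)
  d_alpha <- delays(cm, site, t_stop = 300)
  d_pulse <- delays(cm, site,
                    stim = stimulus("current_step", site, amplitude = 0.1,
                                    duration = 1), t_stop = 300)
  expect_equal(d_alpha$delay_total, d_pulse$delay_total, tolerance = 1e-3)
  expect_equal(d_alpha$delay_local, d_pulse$delay_local, tolerance = 1e-3)

  # exact first-moment route agrees with the time-domain centroids
  d_m <- delays_moment(cm, site)
  expect_equal(d_alpha$delay_total, d_m$delay_total, tolerance = 1e-2)
  expect_equal(d_alpha$delay_local, d_m$delay_local, tolerance = 1e-2)
})

test_that("delay components are ordered and grow with distance along a cable", {
  cm <- desc_cable()
  dl <- delays_moment(cm)
  expect_true(all(dl$delay_local > 0))
  expect_true(all(dl$delay_prop >= 0))
  expect_equal(dl$delay_total, dl$delay_local + dl$delay_prop)
  expect_true(all(diff(dl$delay_total) > 0))  # non-decreasing outward
})

test_that("somatic EPSP shape broadens with synaptic distance", {
  cm <- desc_cable()
  sites <- which(cm$compartments$kind == "dendrite")
  probe <- sites[c(2, 15, 30)]
  shp <- purrr::map_dfr(probe, function(s) somatic_epsp_shape(cm, s))
  expect_true(all(diff(shp$rise_10_90) > 0))
  expect_true(all(diff(shp$half_width) > 0))
  # proximal site has the narrowest somatic EPSP over a scan
  scan <- purrr::map_dfr(sites[seq(1, length(sites), by = 4)],
                         function(s) somatic_epsp_shape(cm, s))
  expect_equal(which.min(scan$half_width), 1)
  # quasi-linear regime at the AMPAR-scale conductance
  s1 <- somatic_epsp_shape(cm, probe[2], g_max = 0.25)
  s2 <- somatic_epsp_shape(cm, probe[2], g_max = 0.5)
  expect_rel(s2$rise_10_90, s1$rise_10_90, 0.01)
})

test_that("electrotonic distance accumulates l/lambda with spine correction", {
  p <- plain_params()
  lam <- space_constant(1, p$Rm, p$Ra)
  cm <- compartmentalize(make_cylinder(1, lam, 101), p, max_len = lam / 40)
  expect_equal(electrotonic_distance(cm, cm$soma), 0)
  comp <- cm$compartments
  sites <- which(comp$kind == "dendrite")
  L <- vapply(sites, function(s) electrotonic_distance(cm, s), numeric(1))
  expect_equal(L, comp$path_dist[sites] / lam, tolerance = 1e-9)
  # a full space constant of cable spans L = 1
  expect_equal(max(comp$path_dist[sites] + comp$length[sites] / 2) / lam, 1,
               tolerance = 1e-9)

  # spine density 1.25 on a 1-um cable scales L by sqrt(q)
  ps <- plain_params(spine_density = 1.25)
  cms <- compartmentalize(make_cylinder(1, 400, 81), ps, max_len = 10)
  cm0 <- compartmentalize(make_cylinder(1, 400, 81), plain_params(), max_len = 10)
  q <- spine_correction_factor(1, 1.25, 1.5)
  expect_rel(electrotonic_distance(cms, 30) / electrotonic_distance(cm0, 30),
             sqrt(q), 1e-6)
})

test_that("electrotonic summary is exact on degenerate and symmetric trees", {
  one <- compartmentalize(make_cylinder(1, 30, 4), plain_params())
  es <- electrotonic_summary(one)
  expect_equal(es$var_L[es$arbor == "all"], 0)

  # symmetric twin branches: same mean L as a single branch
  twin_pts <- rbind(
    c(1, 1, 0, 0, 0, 4, -1),
    c(2, 3, 20, 0, 0, 0.5, 1), c(3, 3, 60, 0, 0, 0.5, 2),
    c(4, 3, -20, 0, 0, 0.5, 1), c(5, 3, -60, 0, 0, 0.5, 4))
  twin <- as_morphology(as.data.frame(twin_pts))
  single <- as_morphology(as.data.frame(twin_pts[1:3, , drop = FALSE]))
  p <- plain_params()
  es_t <- electrotonic_summary(compartmentalize(twin, p))
  es_s <- electrotonic_summary(compartmentalize(single, p))
  expect_equal(es_t$mean_L[es_t$arbor == "all"],
               es_s$mean_L[es_s$arbor == "all"], tolerance = 1e-12)

  # hand-computed mean/variance on a five-value toy list
  L5 <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(mean(L5), 0.3)
  expect_equal(var(L5), 0.025)
})

test_that("descriptor table is complete, finite and deterministic", {
  cm <- desc_tree()
  tbl <- descriptor_table(cm, neuron_id = "n1",
                          descriptors = c("transfers", "delays", "electrotonic"))
  expect_equal(nrow(tbl), sum(cm$compartments$kind == "dendrite"))
  expect_true(all(tbl$v_transfer_ss > 0 & tbl$v_transfer_ss <= 1))
  expect_true(all(tbl$v_transfer_sin <= tbl$v_transfer_ss + 1e-12))
  expect_true(all(tbl$c_transfer > 0 & tbl$c_transfer <= 1))
  expect_equal(tbl$delay_total, tbl$delay_local + tbl$delay_prop)
  expect_true(all(tbl$L >= 0))
  expect_true(all(is.finite(as.matrix(tbl[vapply(tbl, is.numeric, TRUE)]))))
  tbl2 <- descriptor_table(cm, neuron_id = "n1",
                           descriptors = c("transfers", "delays", "electrotonic"))
  expect_identical(tbl, tbl2)
  # spine-corrected area weights are q * smooth area
  sites <- tbl$site
  expect_equal(tbl$area, cm$compartments$q[sites] * cm$compartments$area[sites])
  smooth <- descriptor_table(cm, descriptors = "electrotonic",
                             spine_corrected_areas = FALSE)
  expect_equal(smooth$area, cm$compartments$area[sites])
})

test_that("area-weighted mean matches hand arithmetic and a brute-force loop", {
  tbl <- tibble::tibble(neuron = "n", arbor = "basal", area = c(1, 3),
                        d = c(0, 1))
  expect_equal(area_weighted_mean(tbl, "d"), 0.75)
  tbl$d <- c(2, 2)
  expect_equal(area_weighted_mean(tbl, "d"), 2)

  set.seed(42)
  big <- tibble::tibble(neuron = "n", arbor = "apical",
                        area = runif(50, 10, 100), d = rnorm(50))
  acc <- 0; wsum <- 0
  for (i in 1:50) { acc <- acc + big$area[i] * big$d[i]; wsum <- wsum + big$area[i] }
  expect_equal(area_weighted_mean(big, "d", "apical"), acc / wsum, tolerance = 1e-12)
  expect_error(area_weighted_mean(big, "nope"))
})
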