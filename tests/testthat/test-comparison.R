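# synthetic site-level descriptor records for two groups: descriptor value is
# a smooth function of distance plus neuron-level and site-level noise
fake_sites <- function(n_per_group = 6, shift = 0, seed = 1, n_sites = 40) {
  set.seed(seed)
  purrr::map_dfr(seq_len(2 * n_per_group), function(i) {
    grp <- if (i <= n_per_group) "A" else "B"
    x <- sort(runif(n_sites, 0, 400))
    tibble::tibble(
      neuron = sprintf("%s%02d", grp, i), group = grp, arbor = "basal",
      path_distance = x, area = runif(n_sites, 20, 80),
      d = 10 + 0.02 * x + rnorm(1, sd = 0.5) + rnorm(n_sites, sd = 0.5) +
        if (grp == "B") shift else 0)
  })
}

test_that("comparison graphs bin sites per neuron in both modes and scales", {
  tbl <- fake_sites()
  tbl$d <- 5   # uniform descriptor
  g <- build_graph(tbl, "d", mode = "distance_dependence", scale = "absolute", arbor = "basal")
  expect_true(all(g$data$value == 5))

  g2 <- build_graph(fake_sites(), "d", mode = "surface_distribution",
                    scale = "absolute", bin_width = 2, arbor = "basal")
  sums <- g2$data |> dplyr::group_by(neuron) |> dplyr::summarise(s = sum(value))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)

  gn <- build_graph(fake_sites(), "d", mode = "distance_dependence",
                    scale = "normalized", arbor = "basal")
  last_bin <- max(gn$data$bin)
  per_neuron_max_bin <- gn$data |> dplyr::group_by(neuron) |>
    dplyr::summarise(mb = max(bin))
  expect_true(all(per_neuron_max_bin$mb == last_bin))  # max site in last bin

  expect_error(build_graph(fake_sites(), "d", arbor = "apical"))
  expect_error(build_graph(dplyr::select(fake_sites(), -group), "d", arbor = "basal"))
})

test_that("two-way ANOVA detects a constant group offset and not its permutation", {
  tbl <- fake_sites(n_per_group = 8, shift = 3 * 0.7, seed = 7)  # ~3 sigma
  g <- build_graph(tbl, "d", scale = "absolute", arbor = "basal")
  a <- two_way_anova(g)
  p_orig <- a$p[a$term == "group"]
  expect_lt(p_orig, 0.001)

  set.seed(11)
  shuf <- tbl
  relab <- sample(unique(tbl$neuron))
  names(relab) <- unique(tbl$neuron)
  map_grp <- rep(c("A", "B"), each = 8)
  names(map_grp) <- relab
  shuf$group <- unname(map_grp[shuf$neuron])
  a_perm <- two_way_anova(build_graph(shuf, "d", scale = "absolute", arbor = "basal"))
  expect_gt(a_perm$p[a_perm$term == "group"], p_orig)

  expect_error(two_way_anova(build_graph(dplyr::mutate(tbl, d = 1), "d", arbor = "basal")),
               class = "dendrisig_degenerate_error")
})

test_that("Bonferroni post hoc honours the three-per-group rule and finds a shifted bin", {
  tbl <- fake_sites(n_per_group = 6, seed = 3)
  # make one bin's values jump by ~5 sigma in group B only
  sel <- tbl$group == "B" & tbl$path_distance >= 200 & tbl$path_distance < 250
  tbl$d[sel] <- tbl$d[sel] + 5 * 0.7
  g <- build_graph(tbl, "d", scale = "absolute", arbor = "basal")
  ph <- bonferroni_posthoc(g)
  expect_true(all(ph$n1 >= 3 & ph$n2 >= 3))
  hot <- ph$bin_lo == 200
  expect_true(any(ph$significant[hot]))
  expect_true(all(ph$p_adj >= ph$p))

  # a bin where one group has < 3 values is excluded
  tbl2 <- fake_sites(n_per_group = 3, seed = 5)
  tbl2 <- tbl2[!(tbl2$group == "B" & tbl2$path_distance > 350), ]
  g2 <- build_graph(tbl2, "d", scale = "absolute", arbor = "basal")
  ph2 <- bonferroni_posthoc(g2)
  expect_false(any(ph2$bin_lo == 350))

  # identical groups under this seed produce no flags
  ph0 <- bonferroni_posthoc(build_graph(fake_sites(seed = 8), "d", arbor = "basal"))
  expect_equal(sum(ph0$significant), 0)
})

test_that("KS identity test separates identical from disjoint distributions", {
  d <- c(0.2, 0.3, 0.4, 0.1)
  ks <- ks_identity(d, d)
  expect_equal(ks$D, 0)
  expect_equal(ks$p, 1)

  # constant-diameter synthetic neuron: length and area distributions coincide
  cab <- make_cylinder(1, 400, 81)
  ks2 <- ks_identity(distribution_by_distance(cab, "length", 50, "basal"),
                     distribution_by_distance(cab, "area", 50, "basal"))
  expect_gt(ks2$p, 0.999)

  ks3 <- ks_identity(c(1, 0, 0, 0), c(0, 0, 0, 1))
  expect_lt(ks3$p, 0.01)
})

test_that("Mann-Whitney is rank-based, two-sided, and powered for large shifts", {
  x <- c(1, 2, 3, 4, 5)
  expect_gt(mann_whitney(x, x)$p, 0.9)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10) + 10
  expect_lt(mann_whitney(a, b)$p, 0.001)
  # invariant under a monotone transform of both samples
  expect_equal(mann_whitney(a, b)$p, mann_whitney(exp(a), exp(b))$p)
})

test_that("percent significant counts flagged over eligible intervals", {
  mk <- function(n, k) tibble::tibble(bin = seq_len(n), significant =
                                        seq_len(n) <= k)
  expect_equal(percent_significant(mk(10, 0)), 0)
  expect_equal(percent_significant(mk(7, 7)), 100)
  expect_equal(percent_significant(list(mk(10, 3), mk(5, 2))), 100 * 5 / 15)
  # invariant to bin order permutation
  r <- mk(12, 4)
  expect_equal(percent_significant(r[sample(12), ]), percent_significant(r))
  expect_true(is.na(percent_significant(list())))
})

test_that("stat_report bundles ANOVA, post hoc and the percentage summary", {
  g <- build_graph(fake_sites(n_per_group = 6, shift = 2, seed = 13), "d", arbor = "basal")
  r <- stat_report(g)
  expect_s3_class(r, "stat_report")
  expect_equal(r$n_eligible, nrow(r$posthoc))
  expect_equal(r$percent_significant,
               100 * r$n_significant / max(1, r$n_eligible))
  expect_true(all(c("group", "bin", "group:bin") %in% r$anova$term))
})
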