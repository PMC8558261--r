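default_bin_width <- function(descriptor, scale) {
  if (scale == "normalized") return(10)
  switch(descriptor,
         v_transfer_ss = , v_transfer_sin = , c_transfer = 0.05,
         delay_total = , delay_local = , delay_prop = , half_width = 2,
         rise_10_90 = 1,
         path_distance = 50,
         NULL)
}

#' Build a binned two-group comparison graph
#'
#' The two families of comparison graphs used to contrast dendritic
#' signalling between groups of neurons:
#' \describe{
#'   \item{`distance_dependence`}{per-neuron mean of a descriptor in bins of
#'     path distance of the PSP initiation site (absolute um bins, or bins of
#'     percentage of each neuron's maximal path distance on the normalized
#'     scale).}
#'   \item{`surface_distribution`}{fraction of each neuron's arbor surface
#'     area falling in bins of the descriptor's value, i.e. the estimated
#'     fraction of synapses whose PSPs share similar descriptor values;
#'     per-neuron fractions sum to 1.}
#' }
#'
#' @param tbl combined [descriptor_table()] rows for all neurons, with a
#'   `group` column (two levels) added.
#' @param descriptor descriptor column name.
#' @param mode `"distance_dependence"` or `"surface_distribution"`.
#' @param scale `"absolute"` or `"normalized"` (percent of per-neuron
#'   maximum, 10% bins).
#' @param arbor `"apical"` or `"basal"`.
#' @param bin_width bin width (um, descriptor units, or percent); defaults
#'   depend on descriptor and scale.
#' @return a `comparison_graph`: `data` (neuron x bin values), plus metadata.
#' @export
build_graph <- function(tbl, descriptor,
                        mode = c("distance_dependence", "surface_distribution"),
                        scale = c("absolute", "normalized"),
                        arbor = c("apical", "basal"), bin_width = NULL) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  arbor <- match.arg(arbor)
  if (!"group" %in% names(tbl)) abort("`tbl` needs a `group` column.")
  if (!descriptor %in% names(tbl)) abort(sprintf("no column '%s'.", descriptor))
  if (length(unique(tbl$group)) != 2) abort("exactly two groups are required.")
  tbl <- tbl[tbl$arbor == arbor, ]
  if (nrow(tbl) == 0) abort(sprintf("no sites in %s arbor.", arbor))

  x_var <- if (mode == "distance_dependence") "path_distance" else descriptor
  bw <- bin_width %||% default_bin_width(if (mode == "distance_dependence")
    "path_distance" else descriptor, scale)
  if (is.null(bw)) abort("no default bin width for this descriptor; give bin_width.")

  df <- tbl |>
    group_by(.data$neuron) |>
    mutate(x = if (scale == "normalized") {
      100 * .data[[x_var]] / max(.data[[x_var]])
    } else .data[[x_var]]) |>
    ungroup()
  # normalized scale: the per-neuron maximum lands exactly in the last bin
  edges_max <- if (scale == "normalized") 100 else max(df$x)
  edges <- seq(0, edges_max + bw * 1e-9, by = bw)
  if (max(df$x) > edges[length(edges)]) edges <- c(edges, edges[length(edges)] + bw)
  df$bin <- pmin(findInterval(df$x, edges, rightmost.closed = TRUE),
                 length(edges) - 1L)

  data <- if (mode == "distance_dependence") {
    df |>
      group_by(.data$group, .data$neuron, .data$bin) |>
      summarise(value = mean(.data[[descriptor]]), n_sites = n(), .groups = "drop")
  } else {
    totals <- df |> group_by(.data$neuron) |> summarise(tot = sum(.data$area))
    df |>
      group_by(.data$group, .data$neuron, .data$bin) |>
      summarise(w = sum(.data$area), n_sites = n(), .groups = "drop") |>
      left_join(totals, by = "neuron") |>
      mutate(value = .data$w / .data$tot) |>
      select(-"w", -"tot")
  }
  data$bin_lo <- edges[data$bin]
  data$bin_hi <- edges[data$bin + 1L]
  structure(list(data = data, mode = mode, scale = scale,
                 descriptor = descriptor, arbor = arbor, bin_width = bw,
                 edges = edges, groups = sort(unique(as.character(tbl$group)))),
            class = "comparison_graph")
}

#' @export
print.comparison_graph <- function(x, ...) {
  cat(sprintf("<comparison_graph: %s of %s, %s arbor, %s scale, %d occupied bins, groups %s vs %s>\n",
              x$mode, x$descriptor, x$arbor, x$scale,
              length(unique(x$data$bin)), x$groups[1], x$groups[2]))
  invisible(x)
}

#' Two-way group-by-bin ANOVA on a comparison graph
#'
#' Fixed-effects two-factor analysis of variance on the per-neuron bin
#' values (each neuron contributes at most one value per bin, so neurons —
#' not sites — are the independent units), with Type-II sums of squares for
#' the unbalanced design.  Only bins occupied by both groups enter.
#'
#' @param g a `comparison_graph`.
#' @return tibble with `term` (`group`, `bin`, `group:bin`) and `p`.
#' @export
two_way_anova <- function(g) {
  stopifnot(inherits(g, "comparison_graph"))
  d <- g$data
  shared <- d |>
    group_by(.data$bin) |>
    summarise(both = length(unique(.data$group)) == 2) |>
    filter(.data$both)
  d <- d[d$bin %in% shared$bin, ]
  if (length(unique(d$bin)) < 2) abort("need at least two bins occupied by both groups.")
  counts <- table(d$group)
  if (any(counts < 2)) abort("need at least two neurons per group.")
  if (var(d$value) == 0) {
    abort("degenerate (zero-variance) comparison data.",
          class = "dendrisig_degenerate_error")
  }
  d$bin_f <- factor(d$bin)
  d$group_f <- factor(d$group)
  fit <- stats::lm(value ~ group_f * bin_f, data = d)
  a <- suppressWarnings(car::Anova(fit, type = 2, singular.ok = TRUE))
  p <- a[["Pr(>F)"]]
  terms <- rownames(a)
  tibble(term = c("group", "bin", "group:bin"),
         p = c(p[match("group_f", terms)], p[match("bin_f", terms)],
               p[match("group_f:bin_f", terms)]))
}

#' Per-bin Bonferroni post hoc comparisons
#'
#' Two-sample comparisons of the per-neuron bin values between the two
#' groups, performed only in bins where both groups contribute at least
#' three values; raw p-values are multiplied by the number of eligible bins
#' (Bonferroni) and flagged at `alpha`.
#'
#' @param g a `comparison_graph`.
#' @param alpha significance level.
#' @param test `"t"` (two-sample t test, consistent with the ANOVA) or
#'   `"wilcoxon"`.
#' @param min_n minimal per-group count for a bin to be eligible.
#' @return tibble with one row per eligible bin: `bin`, `bin_lo`, `bin_hi`,
#'   group counts and means, `p`, `p_adj`, `significant`.
#' @export
bonferroni_posthoc <- function(g, alpha = 0.05, test = c("t", "wilcoxon"),
                               min_n = 3L) {
  stopifnot(inherits(g, "comparison_graph"))
  test <- match.arg(test)
  d <- g$data
  g1 <- g$groups[1]; g2 <- g$groups[2]
  elig <- d |>
    group_by(.data$bin, .data$bin_lo, .data$bin_hi) |>
    summarise(n1 = sum(.data$group == g1), n2 = sum(.data$group == g2),
              .groups = "drop") |>
    filter(.data$n1 >= min_n, .data$n2 >= min_n)
  if (nrow(elig) == 0) {
    return(tibble(bin = integer(), bin_lo = numeric(), bin_hi = numeric(),
                  n1 = integer(), n2 = integer(), mean1 = numeric(),
                  mean2 = numeric(), p = numeric(), p_adj = numeric(),
                  significant = logical()))
  }
  m <- nrow(elig)
  res <- purrr::map_dfr(seq_len(m), function(k) {
    b <- elig$bin[k]
    x <- d$value[d$bin == b & d$group == g1]
    y <- d$value[d$bin == b & d$group == g2]
    p <- if (var(c(x, y)) == 0) 1 else if (test == "t") {
      tryCatch(t.test(x, y)$p.value, error = function(e) 1)
    } else {
      suppressWarnings(wilcox.test(x, y)$p.value)
    }
    tibble(bin = b, bin_lo = elig$bin_lo[k], bin_hi = elig$bin_hi[k],
           n1 = elig$n1[k], n2 = elig$n2[k], mean1 = mean(x), mean2 = mean(y),
           p = p)
  })
  res$p_adj <- pmin(1, res$p * m)
  res$significant <- res$p_adj < alpha
  res
}

#' Kolmogorov-Smirnov identity test for binned fraction distributions
#'
#' Maximum absolute difference between the cumulative binned curves, with an
#' approximate p-value from the classical asymptotic Kolmogorov formula
#' using the number of bins as the effective sample size.  Used to test
#' whether dendritic length and surface-area distributions over path
#' distance coincide.  The binned fractions are weighted quantities rather
#' than i.i.d. samples, so the p-value is approximate by construction.
#'
#' @param d1,d2 equal-length vectors of binned fractions (each summing to 1),
#'   or tibbles from [distribution_by_distance()].
#' @return tibble with `D` (KS statistic) and `p` (approximate).
#' @export
ks_identity <- function(d1, d2) {
  f1 <- if (is.data.frame(d1)) d1$fraction else d1
  f2 <- if (is.data.frame(d2)) d2$fraction else d2
  nb <- max(length(f1), length(f2))
  f1 <- c(f1, rep(0, nb - length(f1)))
  f2 <- c(f2, rep(0, nb - length(f2)))
  D <- max(abs(cumsum(f1) - cumsum(f2)))
  lambda <- sqrt(nb) * D
  p <- if (lambda < 1e-8) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  tibble(D = D, p = p, approximate = TRUE)
}

#' Two-sided Mann-Whitney test on per-neuron scalars
#'
#' Rank-based two-sample comparison (exact where possible, normal
#' approximation with tie and continuity correction otherwise), used for
#' specific membrane constants, electrotonic predictors and area-weighted
#' descriptor means.
#'
#' @param x,y per-neuron scalar values of the two groups.
#' @return tibble with `statistic` (U) and `p`.
#' @export
mann_whitney <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Percentage of significant intervals across comparison graphs
#'
#' Counts the Bonferroni-flagged bins over all supplied post hoc tables and
#' expresses them as a percentage of all intervals where the tests could be
#' performed (bins with at least three values in both groups), the summary
#' used to rank descriptors by their degree of alteration.
#'
#' @param reports a single [bonferroni_posthoc()] tibble or a list of them.
#' @return percentage in `[0, 100]`.
#' @export
percent_significant <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  eligible <- sum(vapply(reports, nrow, integer(1)))
  if (eligible == 0) return(NA_real_)
  flagged <- sum(vapply(reports, function(r) sum(r$significant), numeric(1)))
  100 * flagged / eligible
}

#' Full statistics for one comparison graph
#'
#' Bundles the two-way ANOVA, the per-bin Bonferroni post hoc table and the
#' graph metadata into one report.
#'
#' @param g a `comparison_graph`.
#' @param alpha significance level.
#' @param test post hoc test, see [bonferroni_posthoc()].
#' @return a `stat_report` list with `anova`, `posthoc`,
#'   `percent_significant` and the graph metadata.
#' @export
stat_report <- function(g, alpha = 0.05, test = "t") {
  anova <- tryCatch(two_way_anova(g), error = function(e) {
    tibble(term = c("group", "bin", "group:bin"), p = NA_real_)
  })
  ph <- bonferroni_posthoc(g, alpha = alpha, test = test)
  structure(list(descriptor = g$descriptor, mode = g$mode, scale = g$scale,
                 arbor = g$arbor, anova = anova, posthoc = ph,
                 n_eligible = nrow(ph), n_significant = sum(ph$significant),
                 percent_significant = percent_significant(ph)),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report: %s / %s / %s / %s | group p = %.4g | %d/%d bins significant>\n",
              x$descriptor, x$mode, x$arbor, x$scale,
              x$anova$p[x$anova$term == "group"], x$n_significant, x$n_eligible))
  invisible(x)
}
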