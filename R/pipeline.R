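#' Default pipeline configuration
#'
#' Encodes the canonical run: two groups of synthetic pyramidal-like
#' neurons, the wild-type-like and tau-mutant-like presets with their group
#' fit targets and resting potentials, the standard biophysical constants
#' (Ra = 150 Ohm cm, dt = 0.025 ms, alpha synapse 0.25 nS / 0.5 ms), and
#' the comparison-graph settings.  Any field can be overridden, and a group
#' may point at a directory of SWC reconstructions instead of a generator
#' preset.
#'
#' @param n_per_group neurons per group.
#' @param seed RNG seed of the run.
#' @param descriptors descriptor blocks to compute, see [descriptor_table()].
#' @return nested configuration list.
#' @export
default_config <- function(n_per_group = 10, seed = 1,
                           descriptors = c("transfers", "delays",
                                           "electrotonic", "epsp")) {
  list(
    seed = seed,
    groups = list(
      list(name = "WT-like", preset = "wt_like", n = n_per_group, swc_dir = NULL),
      list(name = "TG-like", preset = "tg_like", n = n_per_group, swc_dir = NULL)
    ),
    solver = list(dt = 0.025),
    descriptors = descriptors,
    comparison = list(
      descriptor_cols = c("v_transfer_ss", "v_transfer_sin", "c_transfer",
                          "delay_total", "rise_10_90", "half_width"),
      arbors = c("apical", "basal"),
      modes = c("distance_dependence", "surface_distribution"),
      scales = c("absolute", "normalized"),
      alpha = 0.05
    )
  )
}

resolve_preset <- function(grp) {
  if (!is.null(grp$params)) return(do.call(group_params, grp$params))
  switch(grp$preset,
         wt_like = wt_like_params(),
         tg_like = tg_like_params(),
         abort(sprintf("unknown generator preset '%s'.", grp$preset)))
}

group_morphologies <- function(grp, seed_offset, gp) {
  if (!is.null(grp$swc_dir)) {
    if (!dir.exists(grp$swc_dir)) {
      abort(sprintf("SWC directory not found: %s", grp$swc_dir))
    }
    files <- sort(list.files(grp$swc_dir, pattern = "\\.swc$", full.names = TRUE))
    if (length(files) == 0) abort(sprintf("no .swc files in %s", grp$swc_dir))
    ms <- lapply(files, read_swc)
    names(ms) <- sub("\\.swc$", "", basename(files))
    ms
  } else {
    sample_population(gp, grp$n, seed = seed_offset)
  }
}

#' Run the full comparison pipeline
#'
#' Orchestrates generate (or load) -> membrane fit -> per-site descriptors ->
#' comparison graphs and statistics for two groups of neurons, writing all
#' intermediate tables and a manifest into `out_dir`.  Rerunning with the
#' same configuration reproduces every numeric output.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   of a YAML file holding one.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with the fitted models, descriptor table,
#'   per-graph `stat_report`s and summary tibbles; the same content is on
#'   disk in `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("dendrisig_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  # group definitions replace, never merge (their list elements are unnamed)
  if (!is.null(config$groups)) cfg$groups <- config$groups
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))

  groups <- cfg$groups
  all_desc <- list()
  all_fits <- list()
  all_el <- list()
  all_aw <- list()
  all_ks <- list()

  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    gp <- resolve_preset(grp)
    log_stage("stage generate: group %s", grp$name)
    ms <- withCallingHandlers(
      group_morphologies(grp, seed_offset = cfg$seed + gi, gp = gp),
      warning = function(w) invokeRestart("muffleWarning"))
    p0 <- membrane_params(Rm = 12000, Cm = 1.0, Ra = 150,
                          E_leak = gp$rest_mV,
                          spine_density = gp$spine_density,
                          spine_area = gp$spine_area)
    targets <- fit_targets(gp$target_Rin, gp$target_tau)
    log_stage("stage fit: group %s (%d neurons)", grp$name, length(ms))
    for (nm in names(ms)) {
      fit <- fit_membrane(ms[[nm]], targets, p0, dt = cfg$solver$dt)
      all_fits[[nm]] <- mutate(glance(fit), neuron = nm, group = grp$name,
                               .before = 1)
      log_stage("  fitted %s: Rm %.0f, Cm %.3f, residuals %.2e / %.2e", nm,
                fit$params$Rm, fit$params$Cm,
                abs(fit$achieved_Rin - targets$target_Rin) / targets$target_Rin,
                abs(fit$achieved_tau - targets$target_tau) / targets$target_tau)
      dtab <- descriptor_table(fit$model, neuron_id = nm,
                               descriptors = cfg$descriptors,
                               dt = cfg$solver$dt)
      dtab$group <- grp$name
      all_desc[[nm]] <- dtab
      el <- electrotonic_summary(fit$model)
      el$neuron <- nm; el$group <- grp$name
      all_el[[nm]] <- el
      for (arb in intersect(cfg$comparison$arbors, unique(dtab$arbor))) {
        cols <- intersect(cfg$comparison$descriptor_cols, names(dtab))
        all_aw[[paste(nm, arb)]] <- tibble(
          neuron = nm, group = grp$name, arbor = arb,
          descriptor = cols,
          value = vapply(cols, function(cc) area_weighted_mean(dtab, cc, arb),
                         numeric(1)))
      }
      for (arb in c("apical", "basal")) {
        ok <- tryCatch({
          dl <- distribution_by_distance(ms[[nm]], "length", arbor = arb)
          da <- distribution_by_distance(ms[[nm]], "area", arbor = arb)
          ks <- ks_identity(dl, da)
          all_ks[[paste(nm, arb)]] <- tibble(neuron = nm, group = grp$name,
                                             arbor = arb, D = ks$D, p = ks$p)
          TRUE
        }, error = function(e) FALSE)
      }
    }
  }

  desc <- bind_rows(all_desc)
  fits <- bind_rows(all_fits)
  eltab <- bind_rows(all_el)
  awtab <- bind_rows(all_aw)
  kstab <- bind_rows(all_ks)

  log_stage("stage compare: %d descriptor columns", length(cfg$comparison$descriptor_cols))
  reports <- list()
  for (dc in intersect(cfg$comparison$descriptor_cols, names(desc))) {
    for (arb in cfg$comparison$arbors) {
      for (md in cfg$comparison$modes) {
        for (sc in cfg$comparison$scales) {
          g <- tryCatch(build_graph(desc, dc, mode = md, scale = sc, arbor = arb),
                        error = function(e) NULL)
          if (is.null(g)) next
          reports[[paste(dc, arb, md, sc, sep = "|")]] <-
            stat_report(g, alpha = cfg$comparison$alpha)
        }
      }
    }
  }
  stats_tbl <- purrr::map_dfr(reports, function(r) {
    tibble(descriptor = r$descriptor, arbor = r$arbor, mode = r$mode,
           scale = r$scale,
           p_group = r$anova$p[r$anova$term == "group"],
           p_bin = r$anova$p[r$anova$term == "bin"],
           p_interaction = r$anova$p[r$anova$term == "group:bin"],
           n_eligible = r$n_eligible, n_significant = r$n_significant,
           percent_significant = r$percent_significant)
  })
  posthoc_tbl <- purrr::map_dfr(names(reports), function(nm) {
    r <- reports[[nm]]
    if (nrow(r$posthoc) == 0) return(NULL)
    mutate(r$posthoc, descriptor = r$descriptor, arbor = r$arbor,
           mode = r$mode, scale = r$scale, .before = 1)
  })

  utils::write.csv(desc, file.path(out_dir, "descriptors.csv"), row.names = FALSE)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(eltab, file.path(out_dir, "electrotonic.csv"), row.names = FALSE)
  utils::write.csv(awtab, file.path(out_dir, "area_weighted.csv"), row.names = FALSE)
  utils::write.csv(kstab, file.path(out_dir, "ks_identity.csv"), row.names = FALSE)
  utils::write.csv(stats_tbl, file.path(out_dir, "graph_stats.csv"), row.names = FALSE)
  if (nrow(posthoc_tbl) > 0) {
    utils::write.csv(posthoc_tbl, file.path(out_dir, "posthoc.csv"), row.names = FALSE)
  }
  manifest <- list(package = "dendrisig",
                   version = as.character(utils::packageVersion("dendrisig")),
                   seed = cfg$seed, config = cfg, config_hash = rlang::hash(cfg),
                   finished = format(t0, "%Y-%m-%d"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("done: %s", out_dir)
  invisible(list(out_dir = out_dir, descriptors = desc, fits = fits,
                 electrotonic = eltab, area_weighted = awtab, ks = kstab,
                 reports = reports, stats = stats_tbl))
}

#' Summarise a finished pipeline run
#'
#' Reads the tables written by [run_pipeline()] and assembles the
#' group-level summary: area-weighted descriptor means per group with
#' Mann-Whitney p-values, the two electrotonic pattern-recognition
#' predictors (within-cell mean and variance of electrotonic distances) with
#' Mann-Whitney p-values, and the percent-significant-intervals matrix per
#' descriptor, arbor and scale.  Regenerating the report from the same run
#' directory is idempotent.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return a `pipeline_report` list of tibbles.
#' @export
report_run <- function(out_dir) {
  need <- file.path(out_dir, c("area_weighted.csv", "electrotonic.csv",
                               "graph_stats.csv"))
  if (!all(file.exists(need))) {
    abort(sprintf("'%s' does not contain a complete pipeline run.", out_dir))
  }
  aw <- as_tibble(utils::read.csv(file.path(out_dir, "area_weighted.csv")))
  el <- as_tibble(utils::read.csv(file.path(out_dir, "electrotonic.csv")))
  st <- as_tibble(utils::read.csv(file.path(out_dir, "graph_stats.csv")))
  grps <- sort(unique(aw$group))

  aw_sum <- aw |>
    group_by(.data$descriptor, .data$arbor) |>
    summarise(
      mean_1 = mean(.data$value[.data$group == grps[1]]),
      mean_2 = mean(.data$value[.data$group == grps[2]]),
      p_mw = mann_whitney(.data$value[.data$group == grps[1]],
                          .data$value[.data$group == grps[2]])$p,
      .groups = "drop") |>
    dplyr::rename(!!paste0("mean_", grps[1]) := "mean_1",
                  !!paste0("mean_", grps[2]) := "mean_2")

  el_long <- el |>
    tidyr::pivot_longer(c("mean_L", "var_L"), names_to = "predictor")
  el_sum <- el_long |>
    group_by(.data$arbor, .data$predictor) |>
    summarise(
      mean_1 = mean(.data$value[.data$group == grps[1]]),
      mean_2 = mean(.data$value[.data$group == grps[2]]),
      p_mw = mann_whitney(.data$value[.data$group == grps[1]],
                          .data$value[.data$group == grps[2]])$p,
      .groups = "drop") |>
    dplyr::rename(!!paste0("mean_", grps[1]) := "mean_1",
                  !!paste0("mean_", grps[2]) := "mean_2")

  pct <- st |>
    group_by(.data$descriptor, .data$arbor, .data$scale) |>
    summarise(n_eligible = sum(.data$n_eligible),
              n_significant = sum(.data$n_significant),
              percent_significant = 100 * sum(.data$n_significant) /
                max(1, sum(.data$n_eligible)),
              .groups = "drop")
  pct_combined <- st |>
    group_by(.data$descriptor, .data$arbor) |>
    summarise(n_eligible = sum(.data$n_eligible),
              n_significant = sum(.data$n_significant),
              percent_significant = 100 * sum(.data$n_significant) /
                max(1, sum(.data$n_eligible)),
              .groups = "drop") |>
    mutate(scale = "combined")

  structure(list(groups = grps, area_weighted = aw_sum,
                 electrotonic = el_sum,
                 percent_significant = bind_rows(pct, pct_combined),
                 anova = st),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("== dendrisig pipeline report (%s vs %s) ==\n\n", x$groups[1], x$groups[2]))
  cat("Area-weighted descriptor means:\n")
  print(x$area_weighted, n = Inf)
  cat("\nElectrotonic pattern-recognition predictors:\n")
  print(x$electrotonic, n = Inf)
  cat("\nPercent of intervals with significant group differences:\n")
  print(x$percent_significant, n = Inf)
  invisible(x)
}
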