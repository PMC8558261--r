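#' Per-site descriptors of somatopetal dendritic signal transfer
#'
#' Each descriptor characterizes how a PSP generated at a dendritic site is
#' seen at the soma.  Voltage transfer is the ratio of somatic to local PSP
#' amplitude for a current injection at the site (steady state, or the
#' amplitude ratio of the 50-Hz phasor solution); current transfer is the
#' fraction of injected charge delivered to the soma, computed from the
#' soma-clamped system and equal, by reciprocity, to the somatofugal voltage
#' transfer from the soma to the site.
#'
#' @param cm a `cable_model` with a soma compartment.
#' @param site dendritic compartment index.
#' @param f sinusoid frequency, Hz.
#' @return a ratio in (0, 1].
#' @export
voltage_transfer_ss <- function(cm, site) {
  v <- solve_steady(cm, site)
  v[cm$soma] / v[site]
}

#' @rdname voltage_transfer_ss
#' @export
voltage_transfer_sin <- function(cm, site, f = 50) {
  v <- solve_phasor(cm, site, f = f)
  Mod(v[cm$soma]) / Mod(v[site])
}

#' @rdname voltage_transfer_ss
#' @export
current_transfer <- function(cm, site) {
  if (is.na(cm$soma)) abort("current_transfer needs a soma compartment.")
  if (site == cm$soma) return(1)
  ct <- current_transfer_all(cm)
  ct[site]
}

# fraction of current injected at every compartment that reaches the
# voltage-clamped soma (Schur complement of the conductance matrix)
current_transfer_all <- function(cm) {
  sys <- assemble_system(cm)
  s <- cm$soma
  n <- nrow(sys$G)
  d <- setdiff(seq_len(n), s)
  Vd <- solve(sys$G[d, d, drop = FALSE], diag(1, length(d)))
  # axial conductances into the soma are the negated off-diagonal entries
  ct <- numeric(n)
  ct[d] <- drop(-sys$G[s, d, drop = FALSE] %*% Vd)
  ct[s] <- 1
  ct
}

#' Centroid delays of a propagating PSP
#'
#' Latencies measured as differences between centroids (first temporal
#' moments) of baseline-subtracted time courses: the local delay between the
#' injected current and the local voltage at the site, the propagation delay
#' between the voltages at the site and the soma, and their sum, the total
#' delay between synaptic current flow and the somatic response.
#' `delays()` integrates the model with a transient current stimulus and
#' computes the centroids by the trapezoid rule; for a linear passive system
#' the result is independent of the stimulus shape.  `delays_moment()`
#' evaluates the same quantities exactly from the first moment of the
#' transfer function, \eqn{delay_{j \leftarrow i} = (G^{-1} C G^{-1})_{ji} /
#' (G^{-1})_{ji}}, for every site at once.
#'
#' @param cm a `cable_model`.
#' @param site injection compartment.
#' @param stim transient current [stimulus()] (default: an alpha-shaped
#'   current, 0.25 nA scale, 0.5 ms time-to-peak).
#' @param t_stop integration window, ms (several times tau so the centroid
#'   integrals converge).
#' @param dt time step, ms.
#' @return tibble with `delay_local`, `delay_prop`, `delay_total` (ms);
#'   `delays_moment()` returns one row per requested site.
#' @export
delays <- function(cm, site, stim = NULL, t_stop = 400, dt = 0.025) {
  if (is.na(cm$soma)) abort("delays need a soma compartment.")
  stim <- stim %||% stimulus("alpha_current", site, amplitude = 0.25, t_peak = 0.5)
  if (stim$kind == "alpha_conductance") abort("delays() needs a current stimulus.")
  stim$site <- as.integer(site)
  tr <- simulate_traces(cm, stim, t_stop = t_stop, dt = dt,
                        record = unique(c(site, cm$soma)))
  i_site <- match(site, unique(c(site, cm$soma)))
  i_soma <- match(cm$soma, unique(c(site, cm$soma)))
  cen <- function(y) sum_trapz(tr$times * y) / sum_trapz(y)
  # the integrator consumes the current at half steps; for that sequence the
  # centroid identity of the discrete linear system is exact, whereas a
  # trapezoid over full-step samples misplaces step discontinuities by O(dt)
  t_half <- tr$times[-1] - dt / 2
  i_half <- stim_current(stim, t_half)
  c_I <- sum(t_half * i_half) / sum(i_half)
  c_vs <- cen(tr$v[, i_site])
  c_vr <- cen(tr$v[, i_soma])
  tibble(site = site, delay_local = c_vs - c_I, delay_prop = c_vr - c_vs,
         delay_total = c_vr - c_I)
}

sum_trapz <- function(y) sum(y) - (y[1] + y[length(y)]) / 2

#' @param sites dendritic compartment indices (default: all).
#' @rdname delays
#' @export
delays_moment <- function(cm, sites = NULL) {
  if (is.na(cm$soma)) abort("delays need a soma compartment.")
  sys <- assemble_system(cm)
  R <- solve(sys$G)
  s <- cm$soma
  sites <- sites %||% which(cm$compartments$kind == "dendrite")
  # first-moment matrix entries W_ji = sum_k R_jk C_k R_ki  (W = R C R)
  w_s <- drop(crossprod(R[, sites, drop = FALSE], sys$C * R[, s]))
  w_ii <- colSums(R[, sites, drop = FALSE]^2 * sys$C)
  total <- w_s / R[s, sites]
  local <- w_ii / diag(R)[sites]
  tibble(site = sites, delay_local = local, delay_prop = total - local,
         delay_total = total)
}

#' Shape of the somatic EPSP evoked by a dendritic alpha synapse
#'
#' Activates an alpha-conductance synapse (AMPAR-like defaults: 0.25 nS,
#' 0.5 ms time-to-peak, 0 mV reversal) at a dendritic site and measures the
#' 10-90% rise time and the width at half amplitude of the somatic EPSP,
#' both located by linear interpolation on the integration grid.
#'
#' @param cm a `cable_model`.
#' @param site dendritic compartment of the synapse.
#' @param g_max peak synaptic conductance, nS.
#' @param t_peak alpha-function time-to-peak, ms.
#' @param E_syn synaptic reversal potential, mV.
#' @param t_stop simulation window, ms.
#' @param dt time step, ms.
#' @return tibble with `rise_10_90`, `half_width` and `peak_mV`.
#' @export
somatic_epsp_shape <- function(cm, site, g_max = 0.25, t_peak = 0.5,
                               E_syn = 0, t_stop = 250, dt = 0.025) {
  if (is.na(cm$soma)) abort("somatic_epsp_shape needs a soma compartment.")
  st <- stimulus("alpha_conductance", site, g_max = g_max, t_peak = t_peak,
                 E_syn = E_syn)
  tr <- simulate_traces(cm, st, t_stop = t_stop, dt = dt, record = cm$soma)
  v <- tr$v[, 1]
  tt <- tr$times
  ipk <- which.max(v)
  pk <- v[ipk]
  if (pk <= 0) abort("no somatic EPSP measured.", class = "dendrisig_measurement_error")
  if (v[length(v)] > 0.5 * pk) {
    abort("window too short: EPSP has not decayed to half amplitude.",
          class = "dendrisig_measurement_error")
  }
  cross_up <- function(level) {
    i <- which(v[seq_len(ipk)] >= level)[1]
    tt[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) * dt
  }
  cross_down <- function(level) {
    rest_v <- v[ipk:length(v)]
    i <- which(rest_v <= level)[1]
    j <- ipk + i - 1L
    tt[j - 1] + (level - v[j - 1]) / (v[j] - v[j - 1]) * dt
  }
  tibble(site = site,
         rise_10_90 = cross_up(0.9 * pk) - cross_up(0.1 * pk),
         half_width = cross_down(0.5 * pk) - cross_up(0.5 * pk),
         peak_mV = pk)
}

#' Electrotonic distance of a site from the soma
#'
#' \eqn{L_i = \sum_k l_k / \lambda_k} along the path from the soma to the
#' midpoint of the site's compartment, with every segment's space constant
#' computed from its spine-corrected membrane resistance \eqn{R_m / q_k}.
#' The two pattern-recognition predictors — within-cell mean and variance of
#' these distances over all sites — are returned by
#' `electrotonic_summary()` per arbor and for the whole cell.
#'
#' @param cm a `cable_model`.
#' @param site compartment index (the soma has `L = 0`).
#' @return `electrotonic_distance()`: dimensionless L;
#'   `electrotonic_summary()`: tibble with `arbor`, `mean_L`, `var_L`, `n`.
#' @export
electrotonic_distance <- function(cm, site) {
  electrotonic_all(cm)[site]
}

electrotonic_all <- function(cm) {
  comp <- cm$compartments
  p <- cm$params
  lam <- ifelse(comp$kind == "dendrite",
                space_constant(comp$diameter, p$Rm / comp$q, p$Ra), Inf)
  el <- ifelse(is.finite(lam), comp$length / lam, 0)
  L <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {   # parents precede children by construction
    par <- comp$parent[i]
    L[i] <- el[i] / 2 + if (!is.na(par)) L[par] + el[par] / 2 else 0
  }
  L
}

#' @rdname electrotonic_distance
#' @export
electrotonic_summary <- function(cm) {
  comp <- cm$compartments
  L <- electrotonic_all(cm)
  dend <- comp$kind == "dendrite"
  per_arbor <- tibble(arbor = comp$arbor[dend], L = L[dend]) |>
    group_by(.data$arbor) |>
    summarise(mean_L = mean(.data$L),
              var_L = if (n() > 1) var(.data$L) else 0,
              n = n(), .groups = "drop")
  whole <- tibble(arbor = "all",
                  mean_L = mean(L[dend]),
                  var_L = if (sum(dend) > 1) var(L[dend]) else 0,
                  n = sum(dend))
  bind_rows(per_arbor, whole)
}

#' Full per-site descriptor table of a model neuron
#'
#' One row per dendritic compartment midpoint (the modeled synaptic loci),
#' carrying the site's arbor, path distance, spine-corrected receptive
#' surface area, and the requested signalling descriptors.  Transfers and
#' centroid delays are computed in closed form from the assembled system
#' (the delays by the exact first-moment identity, cross-validated against
#' the time-domain centroids); EPSP shapes require one time-domain
#' simulation per site and can be switched off for large batch runs.
#'
#' @param cm a `cable_model` with a soma.
#' @param neuron_id identifier copied into the `neuron` column.
#' @param descriptors subset of `c("transfers", "delays", "electrotonic",
#'   "epsp")`.
#' @param f_sin sinusoid frequency for the AC voltage transfer, Hz.
#' @param spine_corrected_areas if `TRUE` (default) the area weights include
#'   spine membrane (`q * A_d`), reading the receptive surface as including
#'   spines; set `FALSE` for smooth cylinder areas.
#' @param dt integration step for EPSP simulations, ms.
#' @return a tibble, one row per dendritic compartment.
#' @export
descriptor_table <- function(cm, neuron_id = "neuron",
                             descriptors = c("transfers", "delays",
                                             "electrotonic", "epsp"),
                             f_sin = 50, spine_corrected_areas = TRUE,
                             dt = 0.025) {
  if (is.na(cm$soma)) abort("descriptor_table needs a soma compartment.")
  descriptors <- match.arg(descriptors, several.ok = TRUE)
  comp <- cm$compartments
  sites <- which(comp$kind == "dendrite")
  if (length(sites) == 0) abort("no dendritic compartments.")
  out <- tibble(neuron = neuron_id, site = sites,
                arbor = comp$arbor[sites],
                path_distance = comp$path_dist[sites],
                area = if (spine_corrected_areas) {
                  comp$q[sites] * comp$area[sites]
                } else comp$area[sites])
  sys <- assemble_system(cm)
  R <- solve(sys$G)
  s <- cm$soma
  if ("transfers" %in% descriptors) {
    out$v_transfer_ss <- R[s, sites] / diag(R)[sites]
    Z <- solve(sys$G + 2i * pi * f_sin * 1e-3 * diag(sys$C, nrow = length(sys$C)))
    out$v_transfer_sin <- Mod(Z[s, sites]) / Mod(diag(Z)[sites])
    out$c_transfer <- current_transfer_all(cm)[sites]
  }
  if ("delays" %in% descriptors) {
    dl <- delays_moment(cm, sites)
    out$delay_local <- dl$delay_local
    out$delay_prop <- dl$delay_prop
    out$delay_total <- dl$delay_total
  }
  if ("electrotonic" %in% descriptors) {
    out$L <- electrotonic_all(cm)[sites]
  }
  if ("epsp" %in% descriptors) {
    shp <- purrr::map_dfr(sites, function(i) {
      somatic_epsp_shape(cm, i, dt = dt)
    })
    out$rise_10_90 <- shp$rise_10_90
    out$half_width <- shp$half_width
  }
  out
}

#' Area-weighted mean of a descriptor
#'
#' \eqn{\sum_i A_i D_i / \sum_i A_i} over the sites of a descriptor table:
#' each site's descriptor weighted by its receptive surface area, a proxy for
#' the number of synapses generating PSPs with that descriptor value.
#'
#' @param tbl a [descriptor_table()] tibble.
#' @param descriptor column name, e.g. `"delay_total"`.
#' @param arbor optional arbor filter (`"apical"` or `"basal"`).
#' @return the weighted mean (scalar).
#' @export
area_weighted_mean <- function(tbl, descriptor, arbor = NULL) {
  if (!descriptor %in% names(tbl)) abort(sprintf("no column '%s'.", descriptor))
  if (!is.null(arbor)) tbl <- tbl[tbl$arbor == arbor, ]
  if (nrow(tbl) == 0) abort("no sites after arbor filter.")
  sum(tbl$area * tbl[[descriptor]]) / sum(tbl$area)
}
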