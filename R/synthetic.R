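#' Parameters for the synthetic pyramidal-neuron generator
#'
#' Describes one population of pyramidal-like test morphologies: a set of
#' basal stems grown as a depth-limited branching (Galton-Watson) process
#' with lognormal segment lengths and diameter taper, plus an apical trunk
#' carrying oblique branches and a terminal tuft whose extent is scaled by
#' `tuft_size_factor`.  The two packaged presets differ the way the study
#' groups differ: spine density 1.25 vs 1.00 /um, a reduced apical tuft and
#' a mild diameter change in the tau-mutant-like group.
#'
#' @param name label for the group.
#' @param n_basal_stems number of basal stems leaving the soma.
#' @param branch_probability probability that a branch bifurcates at the end
#'   of a segment (depth-limited at `max_depth`).
#' @param segment_length_mean,segment_length_sd mean and sd (um) of the
#'   lognormal inter-branch segment length.
#' @param stem_diameter basal stem diameter (um).
#' @param taper_ratio daughter/parent diameter ratio at bifurcations, in (0,1].
#' @param apical_trunk_length apical trunk length (um).
#' @param apical_diameter apical trunk diameter at the soma (um).
#' @param tuft_size_factor scaling of the terminal tuft extent, in (0,1].
#' @param spine_density linear spine density (spines/um).
#' @param spine_area membrane area of a single spine (um^2).
#' @param max_total_extent maximal path distance from the soma (um).
#' @param max_depth branching depth limit of the Galton-Watson process.
#' @param soma_radius mean soma radius (um).
#' @param rest_mV resting membrane potential (mV).
#' @param target_Rin,target_tau somatic input-resistance (MOhm) and membrane
#'   time-constant (ms) targets the membrane fit matches for this group.
#' @return a `group_params` list.
#' @export
group_params <- function(name = "custom",
                         n_basal_stems = 4L,
                         branch_probability = 0.55,
                         segment_length_mean = 45,
                         segment_length_sd = 12,
                         stem_diameter = 1.0,
                         taper_ratio = 0.82,
                         apical_trunk_length = 220,
                         apical_diameter = 1.7,
                         tuft_size_factor = 1.0,
                         spine_density = 1.25,
                         spine_area = 1.5,
                         max_total_extent = 560,
                         max_depth = 6L,
                         soma_radius = 3.41,
                         rest_mV = -75,
                         target_Rin = 197,
                         target_tau = 32.5) {
  gp <- list(name = name, n_basal_stems = as.integer(n_basal_stems),
             branch_probability = branch_probability,
             segment_length_mean = segment_length_mean,
             segment_length_sd = segment_length_sd,
             stem_diameter = stem_diameter, taper_ratio = taper_ratio,
             apical_trunk_length = apical_trunk_length,
             apical_diameter = apical_diameter,
             tuft_size_factor = tuft_size_factor,
             spine_density = spine_density, spine_area = spine_area,
             max_total_extent = max_total_extent, max_depth = as.integer(max_depth),
             soma_radius = soma_radius, rest_mV = rest_mV,
             target_Rin = target_Rin, target_tau = target_tau)
  num <- gp[!names(gp) %in% "name"]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num[c("n_basal_stems", "branch_probability", "segment_length_mean",
                       "segment_length_sd", "stem_diameter", "taper_ratio",
                       "apical_trunk_length", "tuft_size_factor", "spine_density",
                       "max_total_extent")]) < 0)) {
    abort("group_params fields must be numeric and non-negative.")
  }
  if (gp$tuft_size_factor > 1 || gp$taper_ratio > 1) {
    abort("tuft_size_factor and taper_ratio must lie in (0, 1].")
  }
  structure(gp, class = "group_params")
}

#' @rdname group_params
#' @export
wt_like_params <- function() {
  group_params(name = "WT-like", spine_density = 1.25, tuft_size_factor = 1.0,
               stem_diameter = 1.0, soma_radius = 3.41, rest_mV = -75,
               target_Rin = 197, target_tau = 32.5)
}

#' @rdname group_params
#' @export
tg_like_params <- function() {
  group_params(name = "TG-like", spine_density = 1.00, tuft_size_factor = 0.8,
               stem_diameter = 0.93, apical_diameter = 1.45,
               soma_radius = 4.04, rest_mV = -65,
               target_Rin = 228, target_tau = 35.2)
}

#' Analytic fixture morphologies
#'
#' `make_cylinder()` builds an unbranched constant-diameter cable (optionally
#' hanging off a soma point) with evenly spaced samples: total lateral area is
#' exactly \eqn{\pi d l} and the tip path distance is `l`.
#' `make_rall_tree()` builds a symmetric binary tree whose daughter diameters
#' obey the 3/2-power rule \eqn{d_{child} = d_{parent}/2^{2/3}} at every
#' bifurcation, so the whole tree is electrically equivalent to a single
#' cylinder of the stem diameter — the classical closed-form benchmark for a
#' branched cable solver.
#'
#' @param d,parent_d diameter (um).
#' @param l total cable length (um).
#' @param n_points number of sample points including the root.
#' @param soma if `TRUE`, the root is a soma sample of radius `d/2` and the
#'   cable is labelled basal; if `FALSE`, a pure dendritic cable.
#' @return a `morphology`.
#' @export
make_cylinder <- function(d, l, n_points, soma = TRUE) {
  if (n_points < 2) abort("make_cylinder() needs n_points >= 2.")
  if (d <= 0 || l <= 0) abort("d and l must be positive.")
  x <- seq(0, l, length.out = n_points)
  type <- c(if (soma) 1L else 3L, rep(3L, n_points - 1L))
  pts <- tibble(id = seq_len(n_points), type = type, x = x, y = 0, z = 0,
                radius = c(if (soma) d / 2 else d / 2, rep(d / 2, n_points - 1L)),
                parent_id = c(-1L, seq_len(n_points - 1L)))
  as_morphology(pts)
}

#' @param depth number of cable levels (1 = unbranched).
#' @param segment_l length of each level's cable (um).
#' @param spacing sample spacing within a level (um).
#' @rdname make_cylinder
#' @export
make_rall_tree <- function(parent_d, depth, segment_l, spacing = 5) {
  if (depth < 1) abort("make_rall_tree() needs depth >= 1.")
  if (parent_d <= 0 || segment_l <= 0) abort("parent_d and segment_l must be positive.")
  rows <- list(tibble(id = 1L, type = 3L, x = 0, y = 0, z = 0,
                      radius = parent_d / 2, parent_id = -1L))
  next_id <- 2L
  grow <- function(parent_id, origin, dir, d, level) {
    pid <- parent_id
    pos <- origin
    remaining <- segment_l
    if (level > 1L) {
      # sharp diameter transition: sample densely right after the bifurcation
      # (segment diameters are endpoint means, so a coarse first sample would
      # smear the parent->daughter diameter step over a whole spacing)
      eps <- min(0.25, segment_l / 100)
      pos <- pos + dir * eps
      rows[[length(rows) + 1L]] <<- tibble(id = next_id, type = 3L,
                                           x = pos[1], y = pos[2], z = pos[3],
                                           radius = d / 2, parent_id = pid)
      pid <- next_id
      next_id <<- next_id + 1L
      remaining <- remaining - eps
    }
    n_seg <- max(1L, ceiling(remaining / spacing))
    step <- remaining / n_seg
    for (k in seq_len(n_seg)) {
      pos <- pos + dir * step
      rows[[length(rows) + 1L]] <<- tibble(id = next_id, type = 3L,
                                           x = pos[1], y = pos[2], z = pos[3],
                                           radius = d / 2, parent_id = pid)
      pid <- next_id
      next_id <<- next_id + 1L
    }
    if (level < depth) {
      child_d <- d / 2^(2 / 3)
      spread <- 0.5 / level
      for (s in c(-1, 1)) {
        nd <- dir + c(0, s * spread, 0)
        nd <- nd / sqrt(sum(nd^2))
        grow(pid, pos, nd, child_d, level + 1L)
      }
    }
  }
  grow(1L, c(0, 0, 0), c(1, 0, 0), parent_d, 1L)
  as_morphology(bind_rows(rows))
}

# unit vector with a seeded random perturbation
wiggle <- function(dir, sd) {
  v <- dir + stats::rnorm(3, sd = sd)
  v / sqrt(sum(v^2))
}

rlnorm_ms <- function(n, mean, sd) {
  # lognormal parameterized by its own mean and sd
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate one synthetic pyramidal-like morphology
#'
#' Draws a tree from the generator described in [group_params()]; uses the
#' current RNG state (see [sample_population()] for seeded batches).
#'
#' @param gp a `group_params` object.
#' @return a `morphology` with apical and basal arbors.
#' @export
synth_neuron <- function(gp) {
  stopifnot(inherits(gp, "group_params"))
  r_soma <- gp$soma_radius * stats::runif(1, 0.92, 1.08)
  rows <- list(tibble(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = r_soma, parent_id = -1L))
  next_id <- 2L
  add_point <- function(parent, pos, radius, type) {
    rows[[length(rows) + 1L]] <<- tibble(id = next_id, type = type,
                                         x = pos[1], y = pos[2], z = pos[3],
                                         radius = radius, parent_id = parent)
    next_id <<- next_id + 1L
    next_id - 1L
  }
  # grow a branch of the Galton-Watson process: bifurcation is guaranteed at
  # the first two branch orders (pyramidal arbors are reliably bushy near the
  # soma) and its probability decays with depth, which keeps tree-size
  # variance moderate while preserving topological variability
  grow <- function(parent, pos, dir, d, depth, used, type, len_scale = 1,
                   p_branch = gp$branch_probability, max_depth = gp$max_depth,
                   extent_cap = gp$max_total_extent) {
    remaining <- extent_cap - used
    if (remaining <= 5) return(invisible())
    len <- min(rlnorm_ms(1, gp$segment_length_mean * len_scale,
                         gp$segment_length_sd * len_scale), remaining)
    n_seg <- max(1L, ceiling(len / 10))
    step <- len / n_seg
    pid <- parent
    for (k in seq_len(n_seg)) {
      dir <- wiggle(dir, 0.12)
      pos <- pos + dir * step
      pid <- add_point(pid, pos, d / 2, type)
    }
    used <- used + len
    p_here <- if (depth <= 2L) 1 else p_branch * 0.85^(depth - 3L)
    if (depth < max_depth && stats::runif(1) < p_here &&
        extent_cap - used > 5) {
      child_d <- max(d * gp$taper_ratio, 0.3)
      for (s in c(-1, 1)) {
        nd <- wiggle(dir + s * 0.45 * orthonormal(dir), 0.05)
        grow(pid, pos, nd, child_d, depth + 1L, used, type, len_scale,
             p_branch, max_depth, extent_cap)
      }
    }
  }
  # basal stems: spread around the lower hemisphere, reaching about half as
  # far from the soma as the apical tree
  for (b in seq_len(gp$n_basal_stems)) {
    ang <- 2 * pi * (b - 0.5) / gp$n_basal_stems
    dir <- c(cos(ang) * 0.9, -abs(stats::runif(1, 0.3, 0.8)), sin(ang) * 0.9)
    dir <- dir / sqrt(sum(dir^2))
    start <- dir * r_soma
    grow(1L, start, dir, gp$stem_diameter * stats::runif(1, 0.9, 1.1),
         1L, r_soma, 3L, len_scale = 0.75, max_depth = gp$max_depth - 1L,
         extent_cap = gp$max_total_extent / 2)
  }
  # apical trunk straight up, with oblique side branches
  trunk_len <- gp$apical_trunk_length * stats::runif(1, 0.95, 1.05)
  d_tr <- gp$apical_diameter * stats::runif(1, 0.95, 1.05)
  n_tr <- max(2L, ceiling(trunk_len / 15))
  step <- trunk_len / n_tr
  pid <- 1L
  pos <- c(0, r_soma, 0)
  dir <- c(0, 1, 0)
  used <- r_soma
  for (k in seq_len(n_tr)) {
    if (used + step > gp$max_total_extent) break
    dir <- wiggle(c(0, 1, 0), 0.05)
    pos <- pos + dir * step
    used <- used + step
    d_here <- d_tr * (1 - 0.3 * k / n_tr)   # gentle trunk taper
    pid <- add_point(pid, pos, d_here / 2, 4L)
    if (k < n_tr && k %% 2 == 0 && stats::runif(1) < 0.5) {
      od <- wiggle(c(stats::runif(1, -1, 1), 0.3, stats::runif(1, -1, 1)), 0.1)
      grow(pid, pos, od, max(d_here * 0.55, 0.35), 4L, used, 4L,
           len_scale = 0.8, max_depth = gp$max_depth)
    }
  }
  # terminal tuft, extent scaled by tuft_size_factor
  for (s in c(-1, 1)) {
    td <- wiggle(c(0.35 * s, 1, 0), 0.08)
    grow(pid, pos, td, max(d_tr * 0.5, 0.35), 2L, used, 4L,
         len_scale = gp$tuft_size_factor, p_branch = 0.85,
         max_depth = gp$max_depth)
  }
  pts <- bind_rows(rows)
  if (sum(pts$type != 1L) < 2) {
    abort("degenerate group parameters produced no dendrite.",
          class = "dendrisig_generation_error")
  }
  as_morphology(pts)
}

orthonormal <- function(dir) {
  v <- c(-dir[2], dir[1], 0)
  if (sum(v^2) < 1e-12) v <- c(0, -dir[3], dir[2])
  v / sqrt(sum(v^2))
}

#' Generate a seeded population of synthetic morphologies
#'
#' Draws `n_neurons` independent trees from one [group_params()] preset with
#' a fixed RNG seed (Mersenne-Twister), so the same call reproduces the same
#' SWC output bit for bit.
#'
#' @param gp a `group_params` object.
#' @param n_neurons number of neurons.
#' @param seed integer RNG seed.
#' @return named list of `morphology` objects
#'   (`<group>_001`, `<group>_002`, ...).
#' @export
sample_population <- function(gp, n_neurons, seed) {
  if (n_neurons < 1) abort("n_neurons must be >= 1.")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- lapply(seq_len(n_neurons), function(i) synth_neuron(gp))
  names(out) <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "", gp$name), seq_len(n_neurons))
  out
}
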