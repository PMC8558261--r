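#' Passive membrane parameters
#'
#' The global passive constants of the cable model: specific membrane
#' resistance `Rm` (Ohm cm^2) and capacitance `Cm` (uF/cm^2), axial
#' resistivity `Ra` (Ohm cm), resting potential `E_leak` (mV), and the spine
#' specification (linear density in spines/um and single-spine membrane area
#' in um^2) used to fold spine membrane into dendritic compartments.
#'
#' @param Rm specific membrane resistance, Ohm cm^2.
#' @param Cm specific membrane capacitance, uF/cm^2.
#' @param Ra axial resistivity, Ohm cm (150 for pyramidal-cell cytosol).
#' @param E_leak resting membrane potential, mV.
#' @param spine_density linear spine density, spines/um.
#' @param spine_area single spine membrane area, um^2.
#' @return a `membrane_params` list.
#' @export
membrane_params <- function(Rm = 12000, Cm = 1.0, Ra = 150, E_leak = -75,
                            spine_density = 0, spine_area = 1.5) {
  if (Rm <= 0 || Cm <= 0 || Ra <= 0) abort("Rm, Cm and Ra must be positive.")
  if (spine_density < 0 || spine_area < 0) abort("spine spec must be non-negative.")
  structure(list(Rm = Rm, Cm = Cm, Ra = Ra, E_leak = E_leak,
                 spine_density = spine_density, spine_area = spine_area),
            class = "membrane_params")
}

#' Spine membrane folding factor
#'
#' Relative increase in membrane area of a dendritic compartment caused by
#' its spines, \eqn{q = (A_s + A_d)/A_d} with \eqn{A_s} the total spine area
#' received by the compartment and \eqn{A_d} the smooth cylinder area
#' \eqn{\pi d l}.  Specific capacitance and leak conductance are scaled by
#' `q` instead of modelling spines as geometry; the soma gets `q = 1`.
#' Because \eqn{A_s = \rho l a_s} and \eqn{A_d = \pi d l}, `q` depends only
#' on the diameter: \eqn{q = 1 + \rho a_s / (\pi d)}.
#'
#' @param d compartment diameter (um).
#' @param density linear spine density (spines/um).
#' @param spine_area single spine area (um^2).
#' @return dimensionless factor `q >= 1`.
#' @examples
#' spine_correction_factor(1, 1.25, 1.5) # 1.5968
#' @export
spine_correction_factor <- function(d, density, spine_area = 1.5) {
  if (any(d <= 0)) abort("compartment diameter must be positive.")
  1 + density * spine_area / (pi * d)
}

#' Discretize a morphology into a passive compartmental cable model
#'
#' Dendrites are divided into cylindrical compartments and the soma becomes a
#' single spherical compartment.  Compartment length never exceeds
#' `min(max_len, 0.2 lambda)` where lambda is the space constant computed
#' with the spine-corrected membrane resistance `Rm/q`; the 37-um default
#' reproduces the spacing rule used for synaptic injection sites.  Each
#' compartment records its spine-corrected capacitance and leak conductance,
#' the axial resistances of its proximal and distal half-cylinders
#' (integrated over the underlying sample diameters), and the path distance
#' of its midpoint.  Adjacent compartments within an unbranched run couple
#' through the sum of their facing half-resistances; at branch points the
#' massless junction node is eliminated exactly (star-mesh transform), which
#' keeps the discretization second-order accurate.
#'
#' @param m a `morphology`.
#' @param p a [membrane_params()] object.
#' @param max_len hard cap on compartment length, um.
#' @return a `cable_model`: list with `compartments` (tibble), `coupling`
#'   (tibble of `i`, `j`, `g_uS`), `params`, and `soma` (compartment index or
#'   `NA` for soma-less fixtures).
#' @export
compartmentalize <- function(m, p, max_len = 37) {
  stopifnot(inherits(m, "morphology"), inherits(p, "membrane_params"))
  pts <- m$points
  seg <- morph_segments(m)
  has_soma <- any(pts$structure == "soma")
  if (!has_soma && nrow(seg) == 0) abort("morphology has neither soma nor dendrite.")

  # vector accumulators (tibble built once at the end)
  v_kind <- character(); v_arbor <- character(); v_len <- numeric()
  v_diam <- numeric(); v_area <- numeric(); v_q <- numeric()
  v_rprox <- numeric(); v_rdist <- numeric(); v_pd <- numeric()
  v_parent <- integer()
  cpl_i <- integer(); cpl_j <- integer(); cpl_g <- numeric()
  soma_idx <- NA_integer_
  if (has_soma) {
    A_soma <- soma_surface(m)
    v_kind <- "soma"; v_arbor <- "none"; v_len <- 0
    v_diam <- 2 * sqrt(A_soma / (4 * pi)); v_area <- A_soma; v_q <- 1
    v_rprox <- 0; v_rdist <- 0; v_pd <- 0; v_parent <- NA_integer_
    soma_idx <- 1L
  }

  if (nrow(seg) > 0) {
    # dendritic children per morphology point
    n_children <- tabulate(seg$parent, nbins = nrow(pts))
    root_pt <- which(pts$parent_id == -1L)
    is_start <- pts$structure[seg$parent] == "soma" |
      seg$parent == root_pt | n_children[seg$parent] >= 2
    # also break sections at sizeable diameter steps so no compartment lumps
    # membrane across a step off-centre (keeps the discretization second order)
    parent_seg <- match(seg$parent, seg$child)
    jump <- !is.na(parent_seg) &
      abs(log(seg$diameter / seg$diameter[ifelse(is.na(parent_seg), 1L, parent_seg)])) > 0.18
    is_start <- is_start | jump
    children_of <- split(seq_len(nrow(seg)), seg$parent)
    point_comp <- rep(NA_integer_, nrow(pts))
    next_comp <- length(v_kind) + 1L
    # legs meeting at each massless junction point: (compartment, half-R)
    junction <- list()

    start_idx <- which(is_start)
    # order sections so parents are compartmentalized before children
    start_idx <- start_idx[order(seg$start_dist[start_idx])]
    for (s0 in start_idx) {
      chain <- s0
      repeat {
        tip <- seg$child[chain[length(chain)]]
        nxt <- children_of[[as.character(tip)]]
        if (length(nxt) != 1L || is_start[nxt]) break
        chain <- c(chain, nxt)
      }
      sec_len <- seg$length[chain]
      sec_d <- seg$diameter[chain]
      q_seg <- spine_correction_factor(sec_d, p$spine_density, p$spine_area)
      lam <- space_constant(sec_d, p$Rm / q_seg, p$Ra)
      h <- min(pmin(max_len, 0.2 * lam))
      L <- sum(sec_len)
      n_cmp <- max(1L, ceiling(L / h - 1e-9))
      edges <- seq(0, L, length.out = n_cmp + 1L)
      cum <- c(0, cumsum(sec_len))
      d0 <- seg$start_dist[s0]
      a <- edges[-length(edges)]; b <- edges[-1]
      lk <- b - a
      # overlap of compartment [a,b] with each underlying morphology segment
      W <- outer(b, cum[-1], pmin) - outer(a, cum[-length(cum)], pmax)
      W[W < 0] <- 0
      dl <- drop(W %*% sec_d)                 # sum of d_j * overlap_j
      dk <- dl / lk
      A_d <- pi * dl
      qk <- 1 + p$spine_density * lk * p$spine_area / A_d
      # axial half-resistances integrate 4*Ra/(pi d^2) over the underlying
      # pieces of each half-compartment (exact for stepwise diameters)
      mid <- (a + b) / 2
      Wp <- outer(mid, cum[-1], pmin) - outer(a, cum[-length(cum)], pmax)
      Wp[Wp < 0] <- 0
      Wd <- W - Wp
      inv_d2 <- 4 * p$Ra / (pi * sec_d^2) * 1e-2    # MOhm per um of cable
      r_prox <- drop(Wp %*% inv_d2)
      r_dist <- drop(Wd %*% inv_d2)
      # attach the section's first compartment: directly to the soma (which
      # is a real, membrane-carrying node), or to the massless junction node
      # at its start point, which is eliminated exactly afterwards
      start_pt <- seg$parent[s0]
      ids <- next_comp:(next_comp + n_cmp - 1L)
      if (has_soma && pts$structure[start_pt] == "soma") {
        parent_first <- soma_idx
        cpl_i <- c(cpl_i, soma_idx); cpl_j <- c(cpl_j, ids[1])
        cpl_g <- c(cpl_g, 1 / r_prox[1])
      } else {
        key <- as.character(start_pt)
        if (is.null(junction[[key]]) && !is.na(point_comp[start_pt])) {
          pc <- point_comp[start_pt]
          junction[[key]] <- list(comp = pc, r = v_rdist[pc])
        }
        parent_first <- if (is.null(junction[[key]])) NA_integer_
          else junction[[key]]$comp[1]
        junction[[key]]$comp <- c(junction[[key]]$comp, ids[1])
        junction[[key]]$r <- c(junction[[key]]$r, r_prox[1])
      }
      if (n_cmp > 1L) {
        cpl_i <- c(cpl_i, ids[-n_cmp]); cpl_j <- c(cpl_j, ids[-1])
        cpl_g <- c(cpl_g, 1 / (r_dist[-n_cmp] + r_prox[-1]))
      }
      parents <- c(parent_first, if (n_cmp > 1L) ids[-n_cmp])
      v_kind <- c(v_kind, rep("dendrite", n_cmp))
      v_arbor <- c(v_arbor, rep(seg$arbor[s0], n_cmp))
      v_len <- c(v_len, lk); v_diam <- c(v_diam, dk)
      v_area <- c(v_area, A_d); v_q <- c(v_q, qk)
      v_rprox <- c(v_rprox, r_prox)
      v_rdist <- c(v_rdist, r_dist)
      v_pd <- c(v_pd, d0 + (a + b) / 2)
      v_parent <- c(v_parent, parents)
      next_comp <- next_comp + n_cmp
      # distal endpoints of underlying segments -> containing compartment
      ends <- cum[-1]
      comp_of_end <- pmin(findInterval(ends, edges, rightmost.closed = TRUE), n_cmp)
      point_comp[seg$child[chain]] <- ids[comp_of_end]
    }
    # eliminate each massless junction node exactly (star-mesh transform):
    # legs i,j gain a direct conductance g_i g_j / sum(g)
    for (jn in junction) {
      if (length(jn$comp) < 2L) next
      gl <- 1 / jn$r
      gs <- sum(gl)
      pairs <- utils::combn(seq_along(jn$comp), 2)
      for (cidx in seq_len(ncol(pairs))) {
        i1 <- pairs[1, cidx]; i2 <- pairs[2, cidx]
        cpl_i <- c(cpl_i, jn$comp[i1]); cpl_j <- c(cpl_j, jn$comp[i2])
        cpl_g <- c(cpl_g, gl[i1] * gl[i2] / gs)
      }
    }
  }

  comp <- tibble(kind = v_kind, arbor = v_arbor, length = v_len,
                 diameter = v_diam, area = v_area, q = v_q,
                 r_half_prox = v_rprox, r_half_dist = v_rdist,
                 path_dist = v_pd, parent = v_parent)
  comp$comp <- seq_len(nrow(comp))
  comp$g_leak_uS <- leak_conductance_uS(comp$q * comp$area, p$Rm)
  comp$c_nF <- capacitance_nF(comp$q * comp$area, p$Cm)
  comp <- comp[, c("comp", "kind", "arbor", "length", "diameter", "area", "q",
                   "c_nF", "g_leak_uS", "r_half_prox", "r_half_dist",
                   "path_dist", "parent")]

  # i is always the proximal (parent-side) compartment of the pair
  cpl <- tibble(i = cpl_i, j = cpl_j, g_uS = cpl_g)

  cm <- structure(list(compartments = comp, coupling = cpl, params = p,
                       soma = soma_idx, max_len = max_len),
                  class = "cable_model")
  check_connected(cm)
  cm
}

check_connected <- function(cm) {
  n <- nrow(cm$compartments)
  if (n == 1L) return(invisible(TRUE))
  adj <- vector("list", n)
  for (k in seq_len(nrow(cm$coupling))) {
    i <- cm$coupling$i[k]; j <- cm$coupling$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  if (!all(seen)) abort("cable model is disconnected.", class = "dendrisig_structure_error")
  invisible(TRUE)
}

#' @export
print.cable_model <- function(x, ...) {
  comp <- x$compartments
  cat(sprintf("<cable_model: %d compartments (%s soma, %d apical, %d basal), Rm = %.0f, Cm = %.3g>\n",
              nrow(comp), if (is.na(x$soma)) "no" else "1",
              sum(comp$arbor == "apical"), sum(comp$arbor == "basal"),
              x$params$Rm, x$params$Cm))
  invisible(x)
}

#' Assemble the conductance matrix and capacitance vector
#'
#' Builds the symmetric system of the discretized passive cable equation:
#' diagonal entries are leak plus the sum of incident axial conductances,
#' off-diagonals are negated axial conductances, so each row sums exactly to
#' the compartment's leak conductance (charge conservation).
#'
#' @param cm a `cable_model`.
#' @return list with `G` (uS matrix, leak + axial) and `C` (nF vector).
#' @export
assemble_system <- function(cm) {
  stopifnot(inherits(cm, "cable_model"))
  n <- nrow(cm$compartments)
  G <- matrix(0, n, n)
  diag(G) <- cm$compartments$g_leak_uS
  for (k in seq_len(nrow(cm$coupling))) {
    i <- cm$coupling$i[k]; j <- cm$coupling$j[k]; g <- cm$coupling$g_uS[k]
    G[i, j] <- G[i, j] - g
    G[j, i] <- G[j, i] - g
    G[i, i] <- G[i, i] + g
    G[j, j] <- G[j, j] + g
  }
  list(G = G, C = cm$compartments$c_nF)
}

#' Write a cable model to JSON
#'
#' Serializes the compartment table and coupling list (plus the membrane
#' parameters) for external inspection.
#'
#' @param cm a `cable_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cable_model <- function(cm, path) {
  stopifnot(inherits(cm, "cable_model"))
  obj <- list(params = unclass(cm$params),
              soma = cm$soma,
              compartments = cm$compartments,
              coupling = cm$coupling)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
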