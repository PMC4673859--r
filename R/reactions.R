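# Surface reactions and calibration of their per-surface runtime parameters.
#
# Bimolecular reactions are executed with the binding-radius method: two
# reactants closer than sigma_b at the end of a step react. sigma_b is
# calibrated so that a pair-capture process at timestep dt with mutual
# diffusion coefficient D_mutual reproduces the requested macroscopic rate k.
# The calibration works in reduced units (length unit = per-axis rms step
# s = sqrt(2 D dt)): the radial density of the pair separation is propagated
# deterministically with the Rice-distribution transition kernel of a 2-D
# Gaussian step, all probability inside sigma_b is absorbed each step, the far
# field is held at density 1, and the steady-state absorbed flux per step is
# the effective rate. Root finding on sigma_b matches it to k. In two
# dimensions the steady rate depends (logarithmically) on where the far field
# is maintained; `far_field` fixes that distance in rms steps.

#' Define a reaction
#'
#' Reactant and product identifiers are species names with an optional state
#' suffix, e.g. `"AMPAR"` or `"AMPAR(surface)"`. Order is inferred from the
#' number of reactants (an empty reactant vector or `"0"` gives a
#' zeroth-order source). Rate units are order-dependent: 1/(um^2 s) for order
#' 0, 1/s for order 1, um^2/s for order 2.
#'
#' @param name reaction name.
#' @param reactants,products character vectors (at most 2 reactants).
#' @param rate macroscopic rate constant, >= 0.
#' @param pgem geminate-recombination probability used to place the products
#'   of a dissociation (or the two products of a bimolecular reaction);
#'   default 0.2 when needed.
#' @export
reaction <- function(name, reactants, products, rate, pgem = NULL) {
  reactants <- setdiff(as.character(reactants), "0")
  products <- setdiff(as.character(products), "0")
  if (length(reactants) > 2) stop("at most 2 reactants")
  if (rate < 0) stop("rate must be >= 0")
  structure(list(name = name, order = length(reactants),
                 reactants = reactants, products = products,
                 rate = rate, pgem = pgem), class = "surfdiff_reaction")
}

.split_key <- function(key) {
  m <- regmatches(key, regexec("^([^()]+)\\(([^()]+)\\)$", key))[[1]]
  if (length(m) == 3) list(species = m[2], state = m[3])
  else list(species = key, state = "surface")
}

#' First-order per-step reaction probability
#'
#' Exponential-waiting discretisation: 1 - exp(-k dt).
#'
#' @param k rate constant (1/s), >= 0.
#' @param dt timestep (s), > 0.
#' @export
unimolecular_prob <- function(k, dt) {
  if (k < 0) stop("negative rate")
  if (!(dt > 0)) stop("dt must be > 0")
  1 - exp(-k * dt)
}

# --- reduced-unit radial propagation machinery ------------------------------

.calib_cache <- new.env(parent = emptyenv())

# Rice-distribution transition matrix: K[i, j] = P(radius r_j -> cell i) for a
# 2-D Gaussian step with unit per-axis sd, on cell centres r, spacing dr.
# exp-scaled I0 switches to its asymptotic series for large arguments (error
# < 1e-4 at the switch point), which also keeps large-radius grids fast.
.radial_kernel <- function(r, dr) {
  n <- length(r)
  Ri <- matrix(r, n, n)
  Rj <- matrix(r, n, n, byrow = TRUE)
  Z <- Ri * Rj
  B <- matrix(0, n, n)
  small <- Z <= 50
  if (any(small)) B[small] <- besselI(Z[small], 0, expon.scaled = TRUE)
  if (any(!small)) {
    z <- Z[!small]
    B[!small] <- (1 + 1 / (8 * z) + 9 / (128 * z^2)) / sqrt(2 * pi * z)
  }
  Ri * exp(-(Ri - Rj)^2 / 2) * B * dr
}

# Radial window around the absorbing boundary: only a band of ~8 rms steps
# below sigma and (far_field + 6) above it matters; deeper absorbed cells are
# unreachable and the far field is reset anyway, so the grid size -- and the
# iteration count -- stay bounded for arbitrarily large reduced radii.
.radial_window <- function(sig, span_above, n_cells = 500) {
  r_lo <- max(0, sig - 8)
  r_hi <- sig + span_above
  dr <- (r_hi - r_lo) / n_cells
  r <- seq(r_lo + dr / 2, r_hi, by = dr)
  list(r = r, dr = dr, K = .radial_kernel(r, dr))
}

# effective per-step absorbed flux (reduced rate k dt / s^2) at reduced
# binding radius sig, with far field held at density 1 beyond sig + far_field.
# The steady state of (propagate, absorb inside sig, reset far field) is an
# affine fixed point and is solved directly:
#   m_live = D (K_ll m_live + K_lr m_far),  D = diag(1 - frac)
.keff_hat <- function(sig, far_field = 10) {
  if (sig <= 0) return(0)
  g <- .radial_window(sig, far_field + 6)
  r <- g$r; dr <- g$dr; K <- g$K
  lo <- r - dr / 2; hi <- r + dr / 2
  frac <- pmin(1, pmax(0, (sig^2 - lo^2) / (hi^2 - lo^2)))
  aM <- 2 * pi * r * dr
  reset <- r > sig + far_field
  live <- !reset
  Dl <- 1 - frac[live]
  A <- K[live, live, drop = FALSE] * Dl        # row-scaled
  b <- Dl * as.vector(K[live, reset, drop = FALSE] %*% aM[reset])
  m_live <- solve(diag(nrow(A)) - A, b)
  m <- numeric(length(r))
  m[live] <- m_live; m[reset] <- aM[reset]
  sum(frac * as.vector(K %*% m))
}

#' Calibrate a binding radius from a macroscopic rate constant
#'
#' Finds sigma_b such that irreversible pair capture at timestep `dt` with
#' mutual diffusion coefficient `D_mutual` reproduces the 2-D macroscopic
#' rate `k`, by root finding on the steady-state absorbed flux of a
#' deterministic radially-symmetric diffusion-with-absorption propagation.
#'
#' @param k bimolecular rate constant (um^2/s), >= 0.
#' @param D_mutual sum of the reactants' diffusion coefficients (um^2/s);
#'   must be > 0 when `k > 0`.
#' @param dt timestep (s).
#' @param far_field distance (in rms steps sqrt(2 D dt)) beyond the binding
#'   radius at which the pair density is held at its bulk value; the 2-D
#'   steady rate depends logarithmically on this screening distance.
#' @param tol relative root tolerance.
#' @param max_sigma largest admissible reduced radius sigma_b / sqrt(2 D dt).
#' @param cap if FALSE (default), an unachievable rate is an error reporting
#'   the achievable maximum; if TRUE it returns the capped radius with a
#'   warning, leaving the reaction diffusion-limited.
#' @return binding radius sigma_b (um).
#' @export
binding_radius_from_rate <- function(k, D_mutual, dt, far_field = 10,
                                     tol = 1e-3, max_sigma = 1e3,
                                     cap = FALSE) {
  if (k < 0) stop("negative rate")
  if (k == 0) return(0)
  if (!(dt > 0)) stop("dt must be > 0")
  if (!(D_mutual > 0)) stop("D_mutual must be > 0 when k > 0")
  s <- sqrt(2 * D_mutual * dt)
  khat <- k * dt / s^2
  key <- sprintf("b:%.10e:%g:%g:%d", khat, far_field, max_sigma, cap)
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit * s)
  guess <- sqrt(khat / pi)
  hi <- min(max(guess * 2, 0.5), max_sigma)
  f <- function(sg) .keff_hat(sg, far_field) - khat
  fhi <- f(hi)
  while (fhi < 0 && hi < max_sigma) {
    hi <- min(hi * 2, max_sigma)
    fhi <- f(hi)
  }
  if (fhi < 0) {
    kmax <- (fhi + khat) * s^2 / dt
    if (!cap)
      stop(sprintf("rate %.4g um^2/s not achievable at dt = %.3g s within sigma_b = %g rms steps; achievable maximum ~ %.4g um^2/s",
                   k, dt, max_sigma, kmax))
    warning(sprintf("rate %.4g um^2/s exceeds the achievable maximum %.4g um^2/s at dt = %.3g s; capping sigma_b at %g rms steps (diffusion-limited reaction)",
                    k, kmax, dt, max_sigma), call. = FALSE)
    .calib_cache[[key]] <- max_sigma
    return(max_sigma * s)
  }
  lo <- min(guess / 4, hi / 4); flo <- f(lo)
  while (flo > 0 && lo > 1e-8) { lo <- lo / 4; flo <- f(lo) }
  if (flo > 0) { lo <- 0; flo <- -khat }
  root <- uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                  tol = tol * max(guess, 1e-4))$root
  .calib_cache[[key]] <- root
  root * s
}

#' Calibrate an unbinding radius from a geminate-recombination probability
#'
#' Finds sigma_u such that a product pair released at separation sigma_u
#' re-enters the binding radius (recombines) with probability `pgem`,
#' computed with the same radial propagation machinery. A 2-D random walk is
#' recurrent, so "escape" is defined as reaching `escape` rms steps beyond
#' the binding radius before recombining.
#'
#' @param pgem target recombination probability in `[0, 1)`.
#' @param sigma_b binding radius (um), > 0.
#' @param D_mutual,dt as in [binding_radius_from_rate()].
#' @param escape escape distance in rms steps beyond sigma_b.
#' @return unbinding radius sigma_u (um), always >= sigma_b.
#' @export
unbinding_radius_from_pgem <- function(pgem, sigma_b, D_mutual, dt,
                                       escape = 12) {
  if (pgem < 0 || pgem >= 1) stop("pgem must be in [0, 1)")
  if (!(sigma_b > 0)) stop("sigma_b must be > 0")
  if (!(D_mutual > 0) || !(dt > 0)) stop("need D_mutual > 0 and dt > 0")
  s <- sqrt(2 * D_mutual * dt)
  sb <- sigma_b / s
  key <- sprintf("u:%.8e:%.8e:%g", sb, pgem, escape)
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(max(sigma_b, hit * s))
  r_esc <- sb + escape
  g <- .radial_window(sb, escape + 2)
  r <- g$r; dr <- g$dr; K <- g$K
  lo <- r - dr / 2; hi <- r + dr / 2
  frac <- pmin(1, pmax(0, (sb^2 - lo^2) / (hi^2 - lo^2)))
  esc <- r >= r_esc
  # p_j = P(recombine before escaping | currently at r_j):
  # p = A + t(Kl) p with absorption on arrival and escape cells killed
  A <- colSums(K * frac)
  Kl <- K * (1 - frac)
  Kl[esc, ] <- 0
  # p = A + t(Kl) p is affine; solve it directly
  p <- solve(diag(length(r)) - t(Kl), A)
  live <- which(frac == 0 & !esc)
  if (length(live) < 2) stop("grid too coarse for unbinding calibration")
  pl <- p[live]; rl <- r[live]
  if (pgem >= pl[1]) {
    root <- rl[1]          # pgem at or above the contact value: release at contact
  } else if (pgem <= pl[length(pl)]) {
    root <- rl[length(rl)] # essentially no recombination requested
  } else {
    i <- which(pl <= pgem)[1]
    w <- (pl[i - 1] - pgem) / (pl[i - 1] - pl[i])
    root <- rl[i - 1] + w * (rl[i] - rl[i - 1])
  }
  .calib_cache[[key]] <- root
  max(sigma_b, root * s)
}

# --- per-surface reaction tables --------------------------------------------

#' Compute per-surface reaction parameters
#'
#' For each bimolecular reaction and each ordered surface pair (surface of
#' reactant 1, surface of reactant 2), the mutual diffusion coefficient is
#' looked up through the diffusion table (override or default) and the
#' binding radius calibrated from it, so slower surfaces get larger radii for
#' the same macroscopic rate. First-order probabilities are
#' surface-independent; zeroth-order expected counts are k * area * dt per
#' surface. Reactions with two products additionally get an unbinding radius
#' (separation at which the products are placed) calibrated from `pgem`.
#'
#' @param reactions list of [reaction()] definitions.
#' @param difc_table a [diffusion_table()].
#' @param mesh a mesh.
#' @param dt timestep (s).
#' @param pgem_default geminate-recombination probability used when a
#'   reaction does not set one.
#' @param far_field passed to [binding_radius_from_rate()].
#' @param sigma_max_steps cap on the binding radius in units of the rms step
#'   sqrt(2 D dt). A macroscopic rate far above the diffusion-limited
#'   encounter rate (e.g. binding to scaffolds on a nearly frozen surface)
#'   would otherwise demand an unbounded capture radius; beyond the cap the
#'   reaction simply runs diffusion-limited, with a warning.
#' @return an object of class `reaction_table`.
#' @export
compute_reaction_tables <- function(reactions, difc_table, mesh, dt,
                                    pgem_default = 0.2, far_field = 10,
                                    sigma_max_steps = 50) {
  surfs <- mesh$surfaces
  ns <- length(surfs)
  lookupD <- function(key, s) {
    sp <- .split_key(key)
    lookup_difc(difc_table, sp$species, sp$state, surfs[s])
  }
  entries <- lapply(reactions, function(rx) {
    ent <- list(name = rx$name, order = rx$order, reactants = rx$reactants,
                products = rx$products, rate = rx$rate,
                pgem = rx$pgem %||% pgem_default,
                prob = NULL, rate0 = NULL, sigb = NULL, sigu2 = NULL,
                sigu1 = NULL)
    if (rx$order == 0) {
      ent$rate0 <- setNames(rx$rate * mesh$surface_area * dt, surfs)
    } else if (rx$order == 1) {
      ent$prob <- unimolecular_prob(rx$rate, dt)
    } else {
      sigb <- matrix(0, ns, ns, dimnames = list(surfs, surfs))
      sigu2 <- matrix(0, ns, ns, dimnames = list(surfs, surfs))
      for (si in seq_len(ns)) for (sj in seq_len(ns)) {
        if (rx$rate == 0) next
        Dm <- lookupD(rx$reactants[1], si) + lookupD(rx$reactants[2], sj)
        if (!(Dm > 0))
          stop(sprintf("reaction '%s': both reactants immobile on surfaces %s/%s but rate > 0",
                       rx$name, surfs[si], surfs[sj]))
        sigb[si, sj] <- binding_radius_from_rate(rx$rate, Dm, dt,
                                                 far_field = far_field,
                                                 max_sigma = sigma_max_steps,
                                                 cap = TRUE)
        if (length(rx$products) >= 2)
          sigu2[si, sj] <- unbinding_radius_from_pgem(ent$pgem, sigb[si, sj],
                                                      Dm, dt)
      }
      ent$sigb <- sigb
      if (length(rx$products) >= 2) ent$sigu2 <- sigu2
    }
    ent
  })
  # dissociations (order 1, >= 2 products): unbinding radius per surface from
  # the partner binding reaction (same species pair), if one exists
  for (i in seq_along(entries)) {
    ent <- entries[[i]]
    if (ent$order != 1 || length(ent$products) < 2) next
    partner <- NULL
    for (e2 in entries)
      if (e2$order == 2 &&
          identical(sort(e2$reactants), sort(ent$products[1:2]))) partner <- e2
    sigu1 <- setNames(numeric(ns), surfs)
    for (s in seq_len(ns)) {
      Dm <- lookupD(ent$products[1], s) + lookupD(ent$products[2], s)
      if (!is.null(partner) && partner$sigb[s, s] > 0 && Dm > 0)
        sigu1[s] <- unbinding_radius_from_pgem(ent$pgem, partner$sigb[s, s],
                                               Dm, dt)
    }
    entries[[i]]$sigu1 <- sigu1
  }
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  structure(list(reactions = entries, dt = dt, surfaces = surfs),
            class = "reaction_table")
}

#' Apply one round of bimolecular events to a molecule table
#'
#' Reference implementation of the pair rule used by the engine: candidate
#' pairs whose 3-D separation is within the binding radius of their surface
#' pair react, processed in ascending separation; a molecule reacts at most
#' once. Reactants are removed; a single product is placed at the projected
#' midpoint, two products at separation sigma_u along the pair axis
#' (re-projected onto the mesh).
#'
#' @param molecules data.frame with columns id, species, panel, lx, ly.
#' @param reaction_name name of an order-2 reaction in `table`.
#' @param table a [compute_reaction_tables()] result.
#' @param mesh a mesh.
#' @return list with updated `molecules` and an `events` data.frame
#'   (id_a, id_b, separation).
#' @export
apply_bimolecular <- function(molecules, reaction_name, table, mesh) {
  ent <- table$reactions[[reaction_name]]
  if (is.null(ent) || ent$order != 2) stop("unknown bimolecular reaction")
  w <- t(vapply(seq_len(nrow(molecules)), function(i)
    to_world(surface_position(molecules$panel[i],
                              c(molecules$lx[i], molecules$ly[i])), mesh),
    numeric(3)))
  ia <- which(molecules$species == ent$reactants[1])
  ib <- which(molecules$species == ent$reactants[2])
  cand <- NULL
  for (i in ia) for (j in ib) {
    if (i == j) next
    if (ent$reactants[1] == ent$reactants[2] &&
        molecules$id[i] >= molecules$id[j]) next
    sb <- ent$sigb[mesh$surf[molecules$panel[i]], mesh$surf[molecules$panel[j]]]
    if (sb <= 0) next
    d <- sqrt(sum((w[i, ] - w[j, ])^2))
    if (d <= sb) cand <- rbind(cand, c(i, j, d))
  }
  events <- data.frame(id_a = integer(0), id_b = integer(0),
                       separation = numeric(0))
  if (is.null(cand))
    return(list(molecules = molecules, events = events))
  cand <- cand[order(cand[, 3], molecules$id[cand[, 1]],
                     molecules$id[cand[, 2]]), , drop = FALSE]
  used <- rep(FALSE, nrow(molecules))
  kill <- logical(nrow(molecules))
  newm <- NULL
  next_id <- max(molecules$id) + 1L
  for (c in seq_len(nrow(cand))) {
    i <- cand[c, 1]; j <- cand[c, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    kill[i] <- kill[j] <- TRUE
    events <- rbind(events, data.frame(id_a = molecules$id[i],
                                       id_b = molecules$id[j],
                                       separation = cand[c, 3]))
    p <- molecules$panel[i]
    mid <- (w[i, ] + w[j, ]) / 2
    loc <- from_world(mid, mesh, p)$local
    bl <- .clamp_local_r(mesh, p, loc)
    if (length(ent$products) == 1) {
      newm <- rbind(newm, data.frame(id = next_id, species = ent$products[1],
                                     panel = p, lx = bl[1], ly = bl[2]))
      next_id <- next_id + 1L
    } else if (length(ent$products) >= 2) {
      su <- if (!is.null(ent$sigu2))
        ent$sigu2[mesh$surf[molecules$panel[i]], mesh$surf[molecules$panel[j]]]
      else 0
      phi <- 2 * pi * runif(1)   # fallback direction, drawn unconditionally
      ax3 <- w[i, ] - w[j, ]
      a <- c(sum(ax3 * mesh$e1[p, ]), sum(ax3 * mesh$e2[p, ]))
      if (sqrt(sum(a^2)) < 1e-12) a <- c(cos(phi), sin(phi))
      a <- a / sqrt(sum(a^2))
      for (q in seq_along(ent$products)) {
        dd <- if (q == 1) su / 2 * a else if (q == 2) -su / 2 * a else c(0, 0)
        fin <- propagate(surface_position(p, bl), dd, mesh)$position
        newm <- rbind(newm, data.frame(id = next_id, species = ent$products[q],
                                       panel = fin$panel, lx = fin$local[1],
                                       ly = fin$local[2]))
        next_id <- next_id + 1L
      }
    }
  }
  molecules <- molecules[!kill, , drop = FALSE]
  if (!is.null(newm)) molecules <- rbind(molecules, newm)
  rownames(molecules) <- NULL
  list(molecules = molecules, events = events)
}

# barycentric clamp of a local point into its panel (numerical guard)
.clamp_local_r <- function(mesh, p, loc) {
  b <- mesh$bx[p]; cx <- mesh$cx[p]; cy <- mesh$cy[p]
  wC <- loc[2] / cy
  wB <- (loc[1] - wC * cx) / b
  wA <- 1 - wB - wC
  if (wA >= 0 && wB >= 0 && wC >= 0) return(loc)
  w <- pmax(c(wA, wB, wC), 0)
  w <- w / sum(w)
  c(w[2] * b + w[3] * cx, w[3] * cy)
}
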