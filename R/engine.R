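# Fixed-timestep simulation loop.
#
# Each step executes, in this fixed order: (1) zeroth-order creations,
# (2) first-order events, (3) diffusion of all molecules in ascending-id
# order, (4) bimolecular events in ascending-separation order, (5) observers.
# Molecules created in phases 1-2 diffuse in phase 3 of the same step. All
# randomness is drawn from R's RNG in this fixed order, so equal
# (config, seed) gives byte-identical outputs. Simulation time is accumulated
# by step count, never by float addition.

.reactions_for_cpp <- function(plan) {
  surfs <- plan$mesh$surfaces
  lapply(plan$rtable$reactions, function(ent) {
    list(order = as.integer(ent$order),
         r1 = if (ent$order >= 1) match(ent$reactants[1], plan$species) else 1L,
         r2 = if (ent$order == 2) match(ent$reactants[2], plan$species) else NULL,
         prods = match(ent$products, plan$species),
         prob = ent$prob,
         rate0 = if (!is.null(ent$rate0)) as.numeric(ent$rate0[surfs]) else NULL,
         sigb = ent$sigb,
         sigu2 = ent$sigu2,
         sigu1 = if (!is.null(ent$sigu1)) as.numeric(ent$sigu1[surfs]) else NULL)
  })
}

#' Initialise a simulation state
#'
#' Seeds the RNG (argument takes precedence over the config's
#' `random_seed`), then executes the config's placements in order.
#'
#' @param plan a [validate_config()] result.
#' @param seed integer seed, or NULL to use the config's seed (or the
#'   current RNG state if neither is set).
#' @return an object of class `surfdiff_state`.
#' @export
sim_init <- function(plan, seed = NULL) {
  seed <- seed %||% plan$config$random_seed
  if (!is.null(seed)) set.seed(seed)
  mol <- list(id = integer(0), species = integer(0), panel = integer(0),
              lx = numeric(0), ly = numeric(0))
  nid <- 1L
  pl <- plan$config$placements
  if (nrow(pl)) for (i in seq_len(nrow(pl))) {
    n <- pl$n[i]
    if (n == 0) next
    rp <- random_positions(plan$mesh, n, pl$surface[i])
    mol$id <- c(mol$id, seq.int(nid, nid + n - 1L))
    nid <- nid + as.integer(n)
    mol$species <- c(mol$species, rep(match(pl$species[i], plan$species), n))
    mol$panel <- c(mol$panel, rp$panel)
    mol$lx <- c(mol$lx, rp$local[, 1])
    mol$ly <- c(mol$ly, rp$local[, 2])
  }
  structure(list(plan = plan, molecules = mol, next_id = nid, step = 0L,
                 counts_step = integer(0), counts_data = integer(0),
                 traj = list(time = numeric(0), id = integer(0),
                             x = numeric(0), y = numeric(0), z = numeric(0),
                             panel = integer(0), surface = integer(0),
                             species = integer(0)),
                 events = setNames(numeric(length(plan$rtable$reactions)),
                                   names(plan$rtable$reactions))),
            class = "surfdiff_state")
}

#' Advance a simulation by n steps
#'
#' @param state a [sim_init()] result.
#' @param n number of timesteps.
#' @param max_crossings per-step panel-crossing budget; exceeding it signals
#'   a pathological step size relative to panel size.
#' @return the updated state.
#' @export
sim_step <- function(state, n = 1, max_crossings = 1000) {
  plan <- state$plan
  cfg <- plan$config
  res <- run_sim_cpp(plan$mesh, state$molecules$id, state$molecules$species,
                     state$molecules$panel, state$molecules$lx,
                     state$molecules$ly, state$next_id, plan$D,
                     plan$confined, .reactions_for_cpp(plan),
                     as.integer(n), cfg$time_step,
                     cfg$time_start + state$step * cfg$time_step,
                     as.integer(state$step), cfg$output_interval, plan$track,
                     as.integer(max_crossings), state$step == 0L)
  state$molecules <- res$molecules
  state$next_id <- res$next_id
  state$counts_step <- c(state$counts_step, state$step + res$counts$step)
  state$counts_data <- c(state$counts_data, res$counts$data)
  # the engine reports global step counts; one multiplication per record
  # keeps times exact and independent of how the run was chunked
  res$traj$time <- cfg$time_start + res$traj$time * cfg$time_step
  for (f in names(state$traj))
    state$traj[[f]] <- c(state$traj[[f]], res$traj[[f]])
  state$events <- state$events + res$events
  state$step <- state$step + as.integer(n)
  state
}

#' Per-surface molecule counts recorded so far
#'
#' @param state a simulation state.
#' @return data.frame (time, species, surface, count), long format.
#' @export
sim_counts <- function(state) {
  plan <- state$plan
  ns <- plan$mesh$nsurf
  nsp <- length(plan$species)
  nrec <- length(state$counts_step)
  data.frame(
    time = rep(plan$config$time_start +
                 state$counts_step * plan$config$time_step, each = nsp * ns),
    species = rep(rep(plan$species, each = ns), times = nrec),
    surface = rep(plan$mesh$surfaces, times = nsp * nrec),
    count = state$counts_data,
    stringsAsFactors = FALSE)
}

#' Trajectory records collected so far
#'
#' @param state a simulation state.
#' @return data.frame (time, id, x, y, z, panel, surface, species).
#' @export
sim_traj <- function(state) {
  plan <- state$plan
  tr <- state$traj
  data.frame(time = tr$time, id = tr$id, x = tr$x, y = tr$y, z = tr$z,
             panel = tr$panel,
             surface = plan$mesh$surfaces[tr$surface],
             species = plan$species[tr$species],
             stringsAsFactors = FALSE)
}

.write_counts <- function(df, path) {
  writeLines(c("time\tspecies\tsurface\tcount",
               sprintf("%.10g\t%s\t%s\t%d", df$time, df$species, df$surface,
                       df$count)), path)
  invisible(path)
}

.write_traj <- function(df, path) {
  writeLines(c("time\tid\tx\ty\tz\tpanel\tsurface",
               sprintf("%.10g\t%d\t%.9g\t%.9g\t%.9g\t%d\t%s", df$time, df$id,
                       df$x, df$y, df$z, df$panel, df$surface)), path)
  invisible(path)
}

#' Run a simulation to completion
#'
#' Validates the configuration (errors are reported before any stepping),
#' places the initial molecules, runs all steps and optionally writes the
#' requested output files.
#'
#' @param config a `surfdiff_config`, a `surfdiff_plan`, a file path, or
#'   configuration text.
#' @param seed integer seed; overrides the config's `random_seed`.
#' @param out_dir directory for the config's `output` files (created if
#'   needed); NULL keeps results in memory only.
#' @param max_crossings per-step crossing budget.
#' @return (invisibly) a list with `counts` and `traj` data.frames, the
#'   per-reaction `events` vector, the final `molecules`, the written
#'   `files` and the final `state`.
#' @export
run_simulation <- function(config, seed = NULL, out_dir = NULL,
                           max_crossings = 1000) {
  plan <- if (inherits(config, "surfdiff_plan")) config
          else validate_config(config)
  state <- sim_init(plan, seed)
  state <- sim_step(state, plan$nsteps, max_crossings)
  counts <- sim_counts(state)
  traj <- sim_traj(state)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (o in plan$config$outputs) {
      path <- file.path(out_dir, o$file)
      if (o$type == "counts") {
        .write_counts(counts, path)
      } else {
        tr <- if (o$species == "all") traj else traj[traj$species == o$species, ]
        .write_traj(tr, path)
      }
      files <- c(files, path)
    }
  }
  invisible(list(counts = counts, traj = traj, events = state$events,
                 molecules = state$molecules, files = files, state = state))
}
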