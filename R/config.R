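# Plain-text configuration dialect.
#
# Line-oriented statements ('#' starts a comment):
#
#   species <name>[(state)] ...
#   difc <species>[(state)] <D>
#   surface_difc <surface> <species>[(state)] <D>
#   surface <name>
#   tri x1 y1 z1 x2 y2 z2 x3 y3 z3          (belongs to the last `surface`)
#   reaction <name> <A> [+ <B>] -> <C> [+ <D>] <rate>
#   reaction_pgem <name> <pgem>
#   confine <species>                        (reflect at surface-to-surface edges)
#   mol <n> <species> surface=<name|all> random
#   time_start <s> | time_stop <s> | time_step <s>
#   random_seed <int>
#   output_interval <steps>
#   output counts <file>
#   output trajectory <species|all> <file>
#
# Units are fixed: um, s, um^2/s. `surface_difc` adds a per-surface exemption
# on top of the species' default `difc`; with no surface_difc statements the
# model reduces to a uniform-coefficient simulator.

#' Parse a configuration
#'
#' @param x a file path, or the configuration text (single string with
#'   newlines, or a character vector of lines).
#' @return an object of class `surfdiff_config`.
#' @export
parse_config <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  cfg <- list(species = character(0), difc = list(),
              surface_difc = data.frame(surface = character(0),
                                        species = character(0),
                                        D = numeric(0),
                                        stringsAsFactors = FALSE),
              surfaces = list(), reactions = list(),
              placements = data.frame(n = integer(0), species = character(0),
                                      surface = character(0),
                                      stringsAsFactors = FALSE),
              confine = character(0),
              time_start = 0, time_stop = 0, time_step = NA_real_,
              random_seed = NULL, output_interval = 1L, outputs = list())
  cur_surface <- NULL
  err <- function(ln, msg) stop(sprintf("config line %d: %s", ln, msg),
                                call. = FALSE)
  num <- function(tok, ln, what) {
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) err(ln, sprintf("%s: not a number ('%s')", what, tok))
    v
  }
  need_species <- function(key, ln) {
    if (!key %in% cfg$species)
      err(ln, sprintf("undeclared species '%s'", key))
  }
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0) next
    stmt <- tok[1]; args <- tok[-1]
    if (stmt == "species") {
      if (length(args) < 1) err(ln, "species: expected at least one name")
      cfg$species <- unique(c(cfg$species, args))
    } else if (stmt == "difc") {
      if (length(args) != 2) err(ln, "difc: expected <species> <D>")
      need_species(args[1], ln)
      if (!is.null(cfg$difc[[args[1]]]))
        warning(sprintf("config line %d: duplicate difc for '%s'; last value wins",
                        ln, args[1]), call. = FALSE)
      cfg$difc[[args[1]]] <- num(args[2], ln, "difc")
      if (cfg$difc[[args[1]]] < 0) err(ln, "difc: D must be >= 0")
    } else if (stmt == "surface_difc") {
      if (length(args) != 3)
        err(ln, "surface_difc: expected <surface> <species> <D>")
      need_species(args[2], ln)
      D <- num(args[3], ln, "surface_difc")
      if (D < 0) err(ln, "surface_difc: D must be >= 0")
      dup <- cfg$surface_difc$surface == args[1] &
        cfg$surface_difc$species == args[2]
      if (any(dup)) {
        warning(sprintf("config line %d: duplicate surface_difc for (%s, %s); last value wins",
                        ln, args[1], args[2]), call. = FALSE)
        cfg$surface_difc <- cfg$surface_difc[!dup, , drop = FALSE]
      }
      cfg$surface_difc <- rbind(cfg$surface_difc,
                                data.frame(surface = args[1], species = args[2],
                                           D = D, stringsAsFactors = FALSE))
    } else if (stmt == "surface") {
      if (length(args) != 1) err(ln, "surface: expected <name>")
      cur_surface <- args[1]
      if (is.null(cfg$surfaces[[cur_surface]]))
        cfg$surfaces[[cur_surface]] <- list()
    } else if (stmt == "tri") {
      if (is.null(cur_surface)) err(ln, "tri before any surface statement")
      if (length(args) != 9) err(ln, "tri: expected 9 coordinates")
      v <- vapply(args, num, numeric(1), ln = ln, what = "tri")
      cfg$surfaces[[cur_surface]] <-
        c(cfg$surfaces[[cur_surface]], list(matrix(v, 3, 3, byrow = TRUE)))
    } else if (stmt == "reaction") {
      if (length(args) < 4) err(ln, "reaction: too few tokens")
      name <- args[1]
      rate <- num(args[length(args)], ln, "reaction rate")
      mid <- args[-c(1, length(args))]
      arrow <- which(mid == "->")
      if (length(arrow) != 1) err(ln, "reaction: expected '->'")
      lhs <- setdiff(mid[seq_len(arrow - 1)], "+")
      rhs <- setdiff(mid[-seq_len(arrow)], "+")
      for (sp in setdiff(c(lhs, rhs), "0")) need_species(sp, ln)
      if (rate < 0) err(ln, "reaction: rate must be >= 0")
      rx <- tryCatch(reaction(name, lhs, rhs, rate),
                     error = function(e) err(ln, conditionMessage(e)))
      if (name %in% vapply(cfg$reactions, `[[`, character(1), "name"))
        err(ln, sprintf("duplicate reaction name '%s'", name))
      cfg$reactions <- c(cfg$reactions, list(rx))
    } else if (stmt == "reaction_pgem") {
      if (length(args) != 2) err(ln, "reaction_pgem: expected <name> <pgem>")
      idx <- which(vapply(cfg$reactions, `[[`, character(1), "name") == args[1])
      if (length(idx) != 1) err(ln, sprintf("unknown reaction '%s'", args[1]))
      p <- num(args[2], ln, "pgem")
      if (p < 0 || p >= 1) err(ln, "pgem must be in [0, 1)")
      cfg$reactions[[idx]]$pgem <- p
    } else if (stmt == "confine") {
      if (length(args) != 1) err(ln, "confine: expected <species>")
      need_species(args[1], ln)
      cfg$confine <- unique(c(cfg$confine, args[1]))
    } else if (stmt == "mol") {
      if (length(args) != 4 || !grepl("^surface=", args[3]) ||
          args[4] != "random")
        err(ln, "mol: expected <n> <species> surface=<name> random")
      n <- num(args[1], ln, "mol count")
      if (n < 0 || n != round(n)) err(ln, "mol: count must be a non-negative integer")
      need_species(args[2], ln)
      cfg$placements <- rbind(cfg$placements,
                              data.frame(n = as.integer(n), species = args[2],
                                         surface = sub("^surface=", "", args[3]),
                                         stringsAsFactors = FALSE))
    } else if (stmt %in% c("time_start", "time_stop", "time_step")) {
      if (length(args) != 1) err(ln, sprintf("%s: expected one value", stmt))
      cfg[[stmt]] <- num(args[1], ln, stmt)
    } else if (stmt == "random_seed") {
      if (length(args) != 1) err(ln, "random_seed: expected one value")
      cfg$random_seed <- as.integer(num(args[1], ln, "random_seed"))
    } else if (stmt == "output_interval") {
      if (length(args) != 1) err(ln, "output_interval: expected one value")
      v <- num(args[1], ln, "output_interval")
      if (v < 1 || v != round(v)) err(ln, "output_interval must be a positive integer")
      cfg$output_interval <- as.integer(v)
    } else if (stmt == "output") {
      if (length(args) == 2 && args[1] == "counts") {
        cfg$outputs <- c(cfg$outputs, list(list(type = "counts", file = args[2])))
      } else if (length(args) == 3 && args[1] == "trajectory") {
        if (args[2] != "all") need_species(args[2], ln)
        cfg$outputs <- c(cfg$outputs, list(list(type = "trajectory",
                                                species = args[2],
                                                file = args[3])))
      } else err(ln, "output: expected 'counts <file>' or 'trajectory <species|all> <file>'")
    } else {
      err(ln, sprintf("unknown statement '%s'", stmt))
    }
  }
  structure(cfg, class = "surfdiff_config")
}

#' Serialise a configuration to its canonical text form
#'
#' `parse_config(serialize_config(cfg))` reproduces `cfg`;
#' serialise-then-parse is a fixed point.
#'
#' @param cfg a `surfdiff_config`.
#' @return character vector of lines.
#' @export
serialize_config <- function(cfg) {
  fmt <- function(x) sprintf("%.17g", x)
  out <- character(0)
  if (length(cfg$species))
    out <- c(out, paste("species", paste(cfg$species, collapse = " ")))
  for (sp in names(cfg$difc))
    out <- c(out, paste("difc", sp, fmt(cfg$difc[[sp]])))
  if (nrow(cfg$surface_difc))
    out <- c(out, sprintf("surface_difc %s %s %s", cfg$surface_difc$surface,
                          cfg$surface_difc$species, fmt(cfg$surface_difc$D)))
  for (s in names(cfg$surfaces)) {
    out <- c(out, paste("surface", s))
    for (tri in cfg$surfaces[[s]])
      out <- c(out, paste("tri", paste(fmt(as.vector(t(tri))), collapse = " ")))
  }
  for (rx in cfg$reactions) {
    lhs <- if (length(rx$reactants)) paste(rx$reactants, collapse = " + ") else "0"
    rhs <- if (length(rx$products)) paste(rx$products, collapse = " + ") else "0"
    out <- c(out, sprintf("reaction %s %s -> %s %s", rx$name, lhs, rhs,
                          fmt(rx$rate)))
    if (!is.null(rx$pgem))
      out <- c(out, sprintf("reaction_pgem %s %s", rx$name, fmt(rx$pgem)))
  }
  for (sp in cfg$confine) out <- c(out, paste("confine", sp))
  if (nrow(cfg$placements))
    out <- c(out, sprintf("mol %d %s surface=%s random", cfg$placements$n,
                          cfg$placements$species, cfg$placements$surface))
  out <- c(out, paste("time_start", fmt(cfg$time_start)),
           paste("time_stop", fmt(cfg$time_stop)),
           paste("time_step", fmt(cfg$time_step)))
  if (!is.null(cfg$random_seed))
    out <- c(out, paste("random_seed", cfg$random_seed))
  out <- c(out, paste("output_interval", cfg$output_interval))
  for (o in cfg$outputs)
    out <- c(out, if (o$type == "counts") paste("output counts", o$file)
             else paste("output trajectory", o$species, o$file))
  out
}

#' Write a configuration file
#' @param cfg a `surfdiff_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  writeLines(serialize_config(cfg), path)
  invisible(path)
}

#' Validate a configuration and resolve the run plan
#'
#' Cross-references all names, builds the mesh, resolves the (species x
#' surface) diffusion matrix and computes the per-surface reaction tables.
#'
#' @param cfg a `surfdiff_config` (or path/text, which is parsed first).
#' @param far_field passed to [compute_reaction_tables()].
#' @return an object of class `surfdiff_plan`.
#' @export
validate_config <- function(cfg, far_field = 10) {
  if (!inherits(cfg, "surfdiff_config")) cfg <- parse_config(cfg)
  if (is.na(cfg$time_step) || !(cfg$time_step > 0))
    stop("time_step must be set and > 0")
  if (cfg$time_stop < cfg$time_start)
    stop("time_stop must be >= time_start")
  if (length(cfg$surfaces) == 0) stop("no surfaces defined (empty mesh)")
  panels <- list(); labels <- character(0)
  for (s in names(cfg$surfaces)) {
    tris <- cfg$surfaces[[s]]
    if (length(tris) == 0) stop(sprintf("surface '%s' has no panels", s))
    panels <- c(panels, tris)
    labels <- c(labels, rep(s, length(tris)))
  }
  mesh <- build_mesh(panels, labels)
  for (sp in cfg$species)
    if (is.null(cfg$difc[[sp]]))
      stop(sprintf("species '%s' has no difc statement", sp))
  tab <- diffusion_table()
  for (sp in names(cfg$difc)) {
    k <- .split_key(sp)
    tab <- set_difc(tab, k$species, cfg$difc[[sp]], k$state)
  }
  if (nrow(cfg$surface_difc)) for (i in seq_len(nrow(cfg$surface_difc))) {
    srf <- cfg$surface_difc$surface[i]
    if (!srf %in% mesh$surfaces)
      stop(sprintf("surface_difc references unknown surface '%s'", srf))
    k <- .split_key(cfg$surface_difc$species[i])
    tab <- set_surface_difc(tab, srf, k$species, cfg$surface_difc$D[i], k$state)
  }
  keys <- lapply(cfg$species, .split_key)
  D <- .resolve_difc_matrix(tab, keys, mesh$surfaces)
  if (nrow(cfg$placements)) for (i in seq_len(nrow(cfg$placements))) {
    srf <- cfg$placements$surface[i]
    if (srf != "all" && !srf %in% mesh$surfaces)
      stop(sprintf("mol placement on unknown surface '%s'", srf))
  }
  rtable <- compute_reaction_tables(cfg$reactions, tab, mesh, cfg$time_step,
                                    far_field = far_field)
  nsteps <- as.integer(floor((cfg$time_stop - cfg$time_start) /
                               cfg$time_step + 1e-9))
  track <- cfg$species %in% unlist(lapply(cfg$outputs, function(o)
    if (o$type == "trajectory") o$species else NULL))
  if (any(vapply(cfg$outputs, function(o)
    o$type == "trajectory" && o$species == "all", logical(1))))
    track <- rep(TRUE, length(cfg$species))
  structure(list(config = cfg, mesh = mesh, difc_table = tab,
                 species = cfg$species, D = D,
                 confined = cfg$species %in% cfg$confine,
                 rtable = rtable, nsteps = nsteps, track = track),
            class = "surfdiff_plan")
}
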