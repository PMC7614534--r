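# Declarative scenario configuration: one JSON object fully describes a run
# (framework, geometry, parameters, cell types, cycle model, clock, seed,
# outputs). Parsing resolves every default and echoes the result into the run
# manifest, so each run is self-describing.

FRAMEWORKS <- c("CA", "CP", "PM", "VT", "VM")

scenario_fields <- c("framework", "geometry", "params", "cycle", "types",
                     "clock", "seed", "output_dir", "modifiers", "writers",
                     "name")

default_params_block <- function(framework, n_types) {
  switch(framework,
    VM = list(k_area = 50, k_perimeter = 1, gamma = 0.1, d_t1 = 0.05,
              t1_separation_ratio = 1.5, a_t2 = 0.01, drag = 1, noise = 0),
    CP = list(lambda_area = 1, adhesion = 1, temperature = 1,
              sweeps_per_step = 1),
    CA = list(motility = 1, division_into_vacant = TRUE),
    PM = ,
    VT = list(stiffness = 15, rest_length = 1, growth_duration = 1,
              newborn_separation = 0.3, cutoff = 1.5, drag = 1)
  )
}

default_geometry <- function(framework) {
  switch(framework,
    VM = list(generator = "honeycomb", nx = 4, ny = 4, edge = 1),
    CP = list(generator = "blob", width = 20, height = 20, radius = 6,
              n_cells = 8),
    CA = list(generator = "blob", width = 20, height = 20, radius = 4,
              n_cells = 10),
    PM = ,
    VT = list(generator = "random_points", n = 20, width = 5, height = 5)
  )
}

#' Build a scenario
#'
#' Fills documented defaults for every omitted field and validates the
#' result. All violations found are reported together.
#'
#' @param framework One of "CA", "CP", "PM", "VT", "VM".
#' @param geometry Geometry generator spec (list with `generator` and its
#'   arguments: "honeycomb" (nx, ny, edge), "blob" (width, height, radius,
#'   n_cells), "random_points" (n, width, height)).
#' @param params Framework parameter block (fields of [vertex_params()],
#'   [potts_params()], [ca_params()] or [centre_params()]).
#' @param cycle Cycle block: `model` ("none", "fixed", "uniform",
#'   "contact_inhibited") plus [cycle_params()] fields.
#' @param types Type-assignment rule: `list(rule = "single", type = 0)` or
#'   `list(rule = "random", p = c(...))` with one proportion per type.
#' @param clock List with `dt`, `end_time`, `sampling_interval`
#'   (a positive multiple of `dt`).
#' @param seed Integer RNG seed.
#' @param output_dir Output directory for [run_simulation()].
#' @param modifiers Ordered list of modifier configs
#'   (`list(name = "target_area_growth", growth_duration = 1)`).
#' @param writers Character vector of writer names ("vtk",
#'   "sorting_metric", "energy", "cell_count").
#' @param name Scenario name (used in the manifest).
#' @return A validated `scenario` object.
#' @export
scenario <- function(framework, geometry = NULL, params = list(),
                     cycle = list(model = "none"), types = list(rule = "single", type = 0),
                     clock = list(dt = 0.01, end_time = 1, sampling_interval = 0.1),
                     seed = 0L, output_dir = tempfile("tissuesim_"),
                     modifiers = list(), writers = "vtk", name = "scenario") {
  framework <- toupper(framework)
  if (is.null(geometry)) geometry <- default_geometry(framework)
  n_types <- scenario_n_types(types)
  defaults <- default_params_block(framework, n_types)
  if (is.null(defaults)) {
    ts_stop(sprintf("unknown framework '%s'", framework), "tissuesim_validation_error")
  }
  params <- utils::modifyList(defaults, params)
  cyc_defaults <- list(model = "none", g1_min = 4, g1_max = 6, s = 2, g2 = 3,
                       m = 1, quiescent_area_fraction = 0.9)
  cycle <- utils::modifyList(cyc_defaults, cycle)
  clock <- utils::modifyList(list(dt = 0.01, end_time = 1,
                                  sampling_interval = 0.1), clock)
  scn <- structure(list(framework = framework, geometry = geometry,
                        params = params, cycle = cycle, types = types,
                        clock = clock, seed = as.integer(seed),
                        output_dir = output_dir,
                        modifiers = modifiers, writers = writers,
                        name = name),
                   class = "scenario")
  validate_scenario(scn)
  scn
}

scenario_n_types <- function(types) {
  if (identical(types$rule, "random")) length(types$p) else 1L
}

#' Validate a scenario, reporting every violation
#'
#' @param scn A `scenario` (or plain list with its fields).
#' @return Invisibly TRUE; otherwise a `tissuesim_validation_error` whose
#'   message lists all violations.
#' @export
validate_scenario <- function(scn) {
  bad <- character(0)
  extra <- setdiff(names(scn), scenario_fields)
  if (length(extra) > 0L) {
    bad <- c(bad, sprintf("unknown field(s): %s", paste(extra, collapse = ", ")))
  }
  if (!scn$framework %in% FRAMEWORKS) {
    bad <- c(bad, sprintf("framework must be one of %s",
                          paste(FRAMEWORKS, collapse = "/")))
  }
  if (is.null(scn$params) || length(scn$params) == 0L) {
    bad <- c(bad, "missing framework parameter block")
  }
  cl <- scn$clock
  if (!is.numeric(cl$dt) || cl$dt <= 0) bad <- c(bad, "clock$dt must be > 0")
  if (!is.numeric(cl$end_time) || cl$end_time < 0) {
    bad <- c(bad, "clock$end_time must be >= 0")
  }
  if (is.numeric(cl$dt) && cl$dt > 0) {
    ratio <- cl$sampling_interval / cl$dt
    if (!is.numeric(cl$sampling_interval) || cl$sampling_interval <= 0 ||
        abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1) {
      bad <- c(bad, "clock$sampling_interval must be a positive multiple of dt")
    }
  }
  if (!identical(scn$types$rule, "single") && !identical(scn$types$rule, "random")) {
    bad <- c(bad, "types$rule must be 'single' or 'random'")
  }
  if (identical(scn$types$rule, "random") &&
      (length(scn$types$p) < 2L || abs(sum(scn$types$p) - 1) > 1e-9)) {
    bad <- c(bad, "types$p must be >= 2 proportions summing to 1")
  }
  if (!scn$cycle$model %in% c("none", "fixed", "uniform", "contact_inhibited")) {
    bad <- c(bad, "cycle$model must be none/fixed/uniform/contact_inhibited")
  }
  if (identical(scn$framework, "CP") && !identical(scn$cycle$model, "none")) {
    bad <- c(bad, "the CP framework is division-free: cycle$model must be 'none'")
  }
  if (scn$cycle$model == "contact_inhibited" && !scn$framework %in% c("VM", "CP")) {
    bad <- c(bad, "contact_inhibited cycle requires an areal framework (VM)")
  }
  gen <- scn$geometry$generator
  known_gen <- c(VM = "honeycomb", CA = "blob", CP = "blob",
                 PM = "random_points", VT = "random_points")
  if (scn$framework %in% names(known_gen) && !is.null(gen) &&
      gen != known_gen[[scn$framework]]) {
    bad <- c(bad, sprintf("geometry generator '%s' unsupported for %s",
                          gen, scn$framework))
  }
  bad_writers <- setdiff(unlist(scn$writers),
                         c("vtk", "sorting_metric", "energy", "cell_count"))
  if (length(bad_writers) > 0L) {
    bad <- c(bad, sprintf("unknown writer(s): %s", paste(bad_writers, collapse = ", ")))
  }
  for (m in scn$modifiers) {
    if (!identical(m$name, "target_area_growth")) {
      bad <- c(bad, sprintf("unknown modifier '%s'", m$name))
    }
  }
  if (length(bad) > 0L) {
    ts_stop(paste0("invalid scenario:\n", paste("  -", bad, collapse = "\n")),
            "tissuesim_validation_error")
  }
  invisible(TRUE)
}

#' Parse a scenario JSON file
#'
#' @param path Path to a scenario JSON file.
#' @return A validated `scenario` with all defaults resolved.
#' @export
parse_scenario <- function(path) {
  if (!file.exists(path)) {
    ts_stop(sprintf("scenario file not found: %s", path), "tissuesim_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), scenario_fields)
  if (length(extra) > 0L) {
    ts_stop(sprintf("invalid scenario:\n  - unknown field(s): %s",
                    paste(extra, collapse = ", ")),
            "tissuesim_validation_error")
  }
  if (is.null(raw$framework)) {
    ts_stop("invalid scenario:\n  - missing framework", "tissuesim_validation_error")
  }
  args <- raw
  args$modifiers <- scenario_modifier_list(raw$modifiers)
  do.call(scenario, args)
}

# fromJSON may return modifiers as a data.frame or list; normalise to a list
# of named lists
scenario_modifier_list <- function(m) {
  if (is.null(m)) return(list())
  if (is.data.frame(m)) return(lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])))
  if (!is.null(m$name)) return(list(m))
  m
}

#' Serialise a scenario to JSON
#'
#' Round-trips through [parse_scenario()]: parse, write, parse yields an
#' equal scenario.
#'
#' @param scn A `scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  jsonlite::write_json(unclass(scn), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Bundled demonstration scenarios
#'
#' * `sorting`: the differential-adhesion cell-sorting showcase on the vertex
#'   model -- two randomly mixed cell types on a honeycomb, heterotypic line
#'   tension above the homotypic mean, small nodal noise, heterotypic
#'   boundary fraction recorded over time.
#' * `monolayer`: relaxation of a perturbed honeycomb monolayer (VM) with an
#'   energy series.
#' * `potts-sort`: the cellular Potts analogue of `sorting` on a two-type
#'   blob.
#' * `ca-growth`: cellular automaton colony growth by division into vacant
#'   sites.
#' * `centre-relax`: overlapping-spheres relaxation of a random point cloud.
#'
#' @param which Demo name.
#' @param seed RNG seed override.
#' @param output_dir Output directory override.
#' @return A validated `scenario`.
#' @export
demo_scenario <- function(which = c("sorting", "monolayer", "potts-sort",
                                    "ca-growth", "centre-relax"),
                          seed = 1L, output_dir = tempfile("tissuesim_")) {
  which <- match.arg(which)
  switch(which,
    sorting = scenario(
      "VM", geometry = list(generator = "honeycomb", nx = 6, ny = 6, edge = 1),
      params = list(k_area = 50, k_perimeter = 0.05,
                    gamma = sorting_gamma(), d_t1 = 0.1,
                    t1_separation_ratio = 1.5, a_t2 = 0.02, drag = 1,
                    noise = 0.02),
      types = list(rule = "random", p = c(0.5, 0.5)),
      clock = list(dt = 0.005, end_time = 4, sampling_interval = 0.25),
      writers = c("vtk", "sorting_metric"),
      seed = seed, output_dir = output_dir, name = "sorting"),
    monolayer = scenario(
      "VM", geometry = list(generator = "honeycomb", nx = 4, ny = 4, edge = 1),
      params = list(k_area = 50, k_perimeter = 1, gamma = 0.1, noise = 0,
                    d_t1 = 0, a_t2 = 0),
      clock = list(dt = 0.002, end_time = 1, sampling_interval = 0.1),
      writers = c("vtk", "energy"),
      seed = seed, output_dir = output_dir, name = "monolayer"),
    `potts-sort` = scenario(
      "CP", geometry = list(generator = "blob", width = 30, height = 30,
                            radius = 10, n_cells = 12),
      params = list(lambda_area = 1, adhesion = potts_sorting_adhesion(),
                    temperature = 2, sweeps_per_step = 1),
      types = list(rule = "random", p = c(0.5, 0.5)),
      clock = list(dt = 1, end_time = 100, sampling_interval = 10),
      writers = c("vtk", "sorting_metric"),
      seed = seed, output_dir = output_dir, name = "potts-sort"),
    `ca-growth` = scenario(
      "CA", geometry = list(generator = "blob", width = 25, height = 25,
                            radius = 3, n_cells = 5),
      params = list(motility = 0.5),
      cycle = list(model = "uniform", g1_min = 2, g1_max = 4, s = 1, g2 = 1, m = 1),
      clock = list(dt = 1, end_time = 30, sampling_interval = 5),
      writers = c("vtk", "cell_count"),
      seed = seed, output_dir = output_dir, name = "ca-growth"),
    `centre-relax` = scenario(
      "PM", geometry = list(generator = "random_points", n = 25, width = 5,
                            height = 5),
      params = list(stiffness = 15, rest_length = 1, cutoff = 1.5, drag = 1),
      clock = list(dt = 0.01, end_time = 5, sampling_interval = 0.5),
      writers = c("vtk", "cell_count"),
      seed = seed, output_dir = output_dir, name = "centre-relax")
  )
}

# heterotypic tension above the homotypic mean; boundary tension in between
sorting_gamma <- function() {
  g <- matrix(0, 3, 3)  # index 1 = medium, 2 = type 0, 3 = type 1
  g[2, 2] <- 0.5; g[3, 3] <- 0.5
  g[2, 3] <- g[3, 2] <- 4
  g[1, 2] <- g[2, 1] <- 2
  g[1, 3] <- g[3, 1] <- 2
  g
}

potts_sorting_adhesion <- function() {
  j <- matrix(0, 3, 3)
  j[2, 2] <- j[3, 3] <- 2
  j[2, 3] <- j[3, 2] <- 11
  j[1, 2] <- j[2, 1] <- 16
  j[1, 3] <- j[3, 1] <- 16
  j
}
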