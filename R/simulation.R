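# The framework-agnostic time loop. Per step, in fixed order: (1) mechanics
# (forces + Euler update, or lattice sweeps); (2) topological events (VM: all
# T1 checks then T2 checks, ascending edge order); (3) cell-cycle advance and
# divisions (ascending cell id) / removals; (4) modifiers in declared order;
# (5) writers at sampling steps. One global RNG stream, seeded from the
# scenario, makes runs bit-reproducible.

build_initial_state <- function(scn) {
  fw <- scn$framework
  geo <- scn$geometry
  n_types <- scenario_n_types(scn$types)
  draw_types <- function(n) {
    if (identical(scn$types$rule, "random")) {
      sample.int(n_types, n, replace = TRUE, prob = scn$types$p) - 1L
    } else {
      rep(as.integer(scn$types$type %||% 0L), n)
    }
  }
  cyc <- cycle_params(scn$cycle$g1_min, scn$cycle$g1_max, scn$cycle$s,
                      scn$cycle$g2, scn$cycle$m, scn$cycle$quiescent_area_fraction)
  p <- scn$params
  if (fw == "VM") {
    mesh <- build_honeycomb_mesh(geo$nx, geo$ny, geo$edge %||% 1)
    n <- length(mesh$elements)
    a0 <- mean(element_areas(mesh))
    params <- vertex_params(k_area = p$k_area, k_perimeter = p$k_perimeter,
                            gamma = as_gamma_matrix(p$gamma, n_types),
                            d_t1 = p$d_t1,
                            t1_separation_ratio = p$t1_separation_ratio,
                            a_t2 = p$a_t2, drag = p$drag, dt = scn$clock$dt,
                            noise = p$noise)
    cells <- new_cell_table(n, types = draw_types(n), target_area = a0,
                            model = scn$cycle$model, params = cyc)
    structure_obj <- mesh
  } else if (fw %in% c("CA", "CP")) {
    lat <- build_lattice_blob(geo$width, geo$height, geo$radius, geo$n_cells,
                              mode = fw)
    n <- geo$n_cells
    a0 <- if (fw == "CP") mean(lattice_areas(lat)) else 1
    params <- if (fw == "CP") {
      potts_params(lambda_area = p$lambda_area,
                   adhesion = as_gamma_matrix(p$adhesion, n_types),
                   temperature = p$temperature,
                   sweeps_per_step = p$sweeps_per_step)
    } else {
      ca_params(motility = p$motility,
                division_into_vacant = p$division_into_vacant %||% TRUE)
    }
    cells <- new_cell_table(n, types = draw_types(n), target_area = a0,
                            model = scn$cycle$model, params = cyc)
    structure_obj <- lat
  } else {
    n <- geo$n
    coords <- cbind(stats::runif(n, 0, geo$width),
                    stats::runif(n, 0, geo$height))
    pop <- centre_population(coords,
                             mode = if (fw == "PM") "overlapping_spheres" else "voronoi",
                             cutoff = p$cutoff %||% 1.5)
    params <- centre_params(stiffness = p$stiffness,
                            rest_length = p$rest_length,
                            growth_duration = p$growth_duration %||% 1,
                            newborn_separation = p$newborn_separation %||% 0.3,
                            drag = p$drag, dt = scn$clock$dt)
    cells <- new_cell_table(n, types = draw_types(n), target_area = 1,
                            model = scn$cycle$model, params = cyc)
    structure_obj <- pop
  }
  list(t = 0, framework = fw, structure = structure_obj, cells = cells,
       params = params, cycle = cyc, cycle_model = scn$cycle$model,
       siblings = NULL, scenario = scn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_gamma_matrix <- function(g, n_types) {
  if (is.matrix(g)) g else matrix(g, n_types + 1L, n_types + 1L)
}

current_cell_areas <- function(state) {
  fw <- state$framework
  if (fw == "VM") {
    a <- element_areas(state$structure)
    a[match(state$cells$id, state$structure$cell_ids)]
  } else if (fw == "CP") {
    tab <- lattice_areas(state$structure)
    as.numeric(tab[as.character(state$cells$id)])
  } else {
    state$cells$target_area  # point cells: area not represented
  }
}

#' Target-area growth modifier
#'
#' Ramps each cell's target area linearly from half its mature value at
#' birth to the mature value over `growth_duration`; older cells sit exactly
#' at the mature value.
#'
#' @param state Simulation state.
#' @param growth_duration Ramp duration (time units).
#' @return The state with updated target areas.
#' @export
target_area_growth_modifier <- function(state, growth_duration = 1) {
  age <- state$t - state$cells$birth_time
  frac <- pmin(1, pmax(0, age / growth_duration))
  state$cells$target_area <- state$cells$mature_area * (0.5 + 0.5 * frac)
  state
}

apply_modifiers <- function(state) {
  for (m in state$scenario$modifiers) {
    if (identical(m$name, "target_area_growth")) {
      state <- target_area_growth_modifier(state, m$growth_duration %||% 1)
    }
  }
  state
}

#' Sorting-metric value of a state
#'
#' Heterotypic boundary length fraction for the vertex model; heterotypic
#' interface count for the cellular Potts model. `NA` (the sentinel written
#' to the series) when the metric is undefined.
#'
#' @param state Simulation state.
#' @return A single number, or NA.
#' @export
sorting_metric <- function(state) {
  if (state$framework == "VM") {
    tryCatch(heterotypic_fraction(state$structure, state$cells),
             tissuesim_undefined_metric = function(e) NA_real_)
  } else if (state$framework == "CP") {
    as.numeric(potts_heterotypic_interfaces(state$structure, state$cells))
  } else {
    NA_real_
  }
}

state_energy <- function(state) {
  switch(state$framework,
         VM = tissue_energy(state$structure, state$cells, state$params),
         CP = potts_energy(state$structure, state$cells, state$params),
         NA_real_)
}

#' Run a simulation scenario
#'
#' Builds the initial condition, iterates the time loop to `end_time`, fires
#' writers every `sampling_interval`, and writes `results.pvd`, numbered
#' `.vtu` frames, metric series (`metrics.csv`) and a run manifest
#' (`manifest.json`) into the scenario's output directory.
#'
#' @param scn A validated [scenario()].
#' @param check Re-validate structural invariants after every step (test
#'   mode; aborts with the step index on violation).
#' @return A `tissue_simulation` object: final `state`, `metrics` tibble,
#'   `output_dir`, `manifest`.
#' @export
run_simulation <- function(scn, check = FALSE) {
  validate_scenario(scn)
  out_dir <- scn$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(scn$seed)
  state <- build_initial_state(scn)
  dt <- scn$clock$dt
  n_steps <- as.integer(round(scn$clock$end_time / dt))
  sample_every <- as.integer(round(scn$clock$sampling_interval / dt))
  want_vtk <- "vtk" %in% scn$writers

  metrics <- list()
  frames <- data.frame(timestep = numeric(0), file = character(0))
  emit <- function(state, step) {
    frame_t <- state$t
    if (want_vtk) {
      fname <- sprintf("frame_%04d.vtu", length(frames$file))
      write_frame(state, file.path(out_dir, fname))
      frames <<- rbind(frames, data.frame(timestep = frame_t, file = fname))
    }
    row <- list(t = frame_t, n_cells = nrow(state$cells))
    if ("sorting_metric" %in% scn$writers) row$heterotypic <- sorting_metric(state)
    if ("energy" %in% scn$writers) row$energy <- state_energy(state)
    metrics[[length(metrics) + 1L]] <<- row
  }
  emit(state, 0L)

  for (step in seq_len(n_steps)) {
    state$t <- state$t + dt
    fw <- state$framework
    if (fw == "VM") {
      res <- vm_step(state$structure, state$cells, state$params)
      state$structure <- res$mesh
      state$cells <- res$cells
    } else if (fw == "CP") {
      res <- potts_step(state$structure, state$cells, state$params)
      state$structure <- res$lattice
      state$cells <- res$cells
    } else if (fw == "CA") {
      res <- ca_step(state$structure, state$cells, state$params,
                     ready = NULL, t = state$t, cycle = state$cycle)
      state$structure <- res$lattice
      state$cells <- res$cells
    } else {
      pop <- state$structure
      pairs <- neighbour_pairs(pop)
      f <- spring_forces(pop, pairs, state$params, t = state$t,
                         siblings = state$siblings)
      state$structure <- step_positions(pop, f, state$params)
    }
    # cell cycles and divisions
    if (state$cycle_model != "none" && nrow(state$cells) > 0L) {
      adv <- advance_cycle(state$cells, dt, state$t,
                           areas = current_cell_areas(state),
                           params = state$cycle)
      state$cells <- adv$cells
      if (fw == "CA") {
        if (any(adv$ready) && state$params$division_into_vacant) {
          res <- ca_divide(state$structure, state$cells, adv$ready,
                           t = state$t, cycle = state$cycle)
          state$structure <- res$lattice
          state$cells <- res$cells
        }
      } else {
        ready_ids <- sort(state$cells$id[adv$ready])
        for (id in ready_ids) {
          if (fw == "VM") {
            el <- match(id, state$structure$cell_ids)
            res <- divide_element(state$structure, el, state$cells,
                                  axis = "short-axis", t = state$t,
                                  params = state$cycle, ready = TRUE)
            if (res$divided) {
              state$structure <- res$mesh
              state$cells <- res$cells
            }
          } else if (fw %in% c("PM", "VT")) {
            res <- divide_centre_cell(state$structure, id, state$cells,
                                      state$params, t = state$t,
                                      cycle = state$cycle,
                                      siblings = state$siblings)
            state$structure <- res$pop
            state$cells <- res$cells
            state$siblings <- res$siblings
          }
        }
      }
    }
    state <- apply_modifiers(state)
    if (check) check_state(state, step)
    if (step %% sample_every == 0L) emit(state, step)
  }

  metrics <- do.call(rbind, lapply(metrics, function(r) as.data.frame(r)))
  metrics <- tibble::as_tibble(metrics)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (want_vtk) write_pvd(frames, file.path(out_dir, "results.pvd"))
  manifest <- list(name = scn$name, final_t = state$t,
                   n_cells = nrow(state$cells), seed = scn$seed,
                   n_frames = nrow(frames),
                   scenario = unclass(scn))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(state = state, metrics = metrics, output_dir = out_dir,
                 manifest = manifest),
            class = "tissue_simulation")
}

#' @export
print.tissue_simulation <- function(x, ...) {
  cat(sprintf("<tissue_simulation '%s' (%s): t = %g, %d cells, %d frames in %s>\n",
              x$manifest$name, x$state$framework, x$state$t,
              x$manifest$n_cells, x$manifest$n_frames, x$output_dir))
  invisible(x)
}

# structural invariant re-check (test mode)
check_state <- function(state, step) {
  ok <- tryCatch({
    fw <- state$framework
    if (fw == "VM") {
      validate_mesh(state$structure, check_simple = FALSE)
      stopifnot(length(state$structure$elements) == nrow(state$cells),
                all(sort(state$structure$cell_ids) == sort(state$cells$id)))
    } else if (fw %in% c("CA", "CP")) {
      ids <- setdiff(unique(as.vector(state$structure$occupancy)), 0L)
      stopifnot(all(ids %in% state$cells$id))
      if (fw == "CA") {
        stopifnot(all(table(as.vector(state$structure$occupancy)[
          as.vector(state$structure$occupancy) != 0L]) == 1L))
        stopifnot(setequal(ids, state$cells$id))
      } else {
        stopifnot(setequal(ids, state$cells$id))
      }
    } else {
      stopifnot(nrow(state$structure$coords) == nrow(state$cells),
                setequal(state$structure$cell_ids, state$cells$id),
                all(is.finite(state$structure$coords)))
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    ts_stop(sprintf("invariant violation at step %d: %s", step,
                    conditionMessage(ok)),
            "tissuesim_state_error")
  }
  invisible(TRUE)
}
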