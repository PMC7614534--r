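# Biological cell state and the cell-cycle model hierarchy shared by all
# frameworks. Cells live in a plain data.frame (one row per cell), so the
# population composes with dplyr-style manipulation and serialises trivially.

#' Cell-cycle parameters
#'
#' Parameterises the three cycle model kinds: `fixed` (deterministic phase
#' durations, G1 = `g1_min`), `uniform` (G1 drawn once per cell from
#' U(`g1_min`, `g1_max`)), and `contact_inhibited` (as `uniform`, but G1
#' progress pauses while the cell's current area falls below
#' `quiescent_area_fraction` of its target area).
#'
#' @param g1_min,g1_max Bounds of the G1 duration (time units);
#'   `g1_min <= g1_max`. The fixed model uses `g1_min`.
#' @param s,g2,m Fixed S, G2 and M phase durations.
#' @param quiescent_area_fraction Area fraction below which a
#'   contact-inhibited cell arrests, in (0, 1].
#' @return A `cycle_params` object.
#' @export
cycle_params <- function(g1_min = 4, g1_max = 6, s = 2, g2 = 3, m = 1,
                         quiescent_area_fraction = 0.9) {
  if (!(g1_min <= g1_max) || any(c(g1_min, s, g2, m) < 0)) {
    ts_stop("phase durations must be >= 0 with g1_min <= g1_max",
            "tissuesim_config_error")
  }
  if (quiescent_area_fraction <= 0 || quiescent_area_fraction > 1) {
    ts_stop("quiescent_area_fraction must be in (0, 1]", "tissuesim_config_error")
  }
  structure(list(g1_min = g1_min, g1_max = g1_max, s = s, g2 = g2, m = m,
                 quiescent_area_fraction = quiescent_area_fraction),
            class = "cycle_params")
}

draw_g1 <- function(model, params, n = 1L) {
  switch(model,
         fixed = rep(params$g1_min, n),
         uniform = ,
         contact_inhibited = stats::runif(n, params$g1_min, params$g1_max),
         ts_stop(sprintf("unknown cycle model '%s'", model), "tissuesim_config_error"))
}

#' Create a cell population table
#'
#' @param n Number of cells.
#' @param types Integer type labels (recycled), 0-based ("Cell types" in
#'   output).
#' @param target_area Target (preferred) area per cell, > 0.
#' @param model Cycle model kind: "fixed", "uniform", "contact_inhibited", or
#'   "none" (non-proliferative).
#' @param params A [cycle_params()]; ignored for model "none".
#' @param birth_time Birth time of the initial cells (default 0).
#' @return A data.frame with one row per cell: id, type, birth_time,
#'   target_area, mature_area, model, drawn_g1, arrested, arrest_total.
#' @export
new_cell_table <- function(n, types = 0L, target_area = 1,
                           model = "none", params = cycle_params(),
                           birth_time = 0) {
  if (any(target_area <= 0)) {
    ts_stop("target_area must be positive", "tissuesim_config_error")
  }
  g1 <- if (model == "none") rep(NA_real_, n) else draw_g1(model, params, n)
  data.frame(
    id = seq_len(n),
    type = rep_len(as.integer(types), n),
    birth_time = rep_len(birth_time, n),
    target_area = rep_len(target_area, n),
    mature_area = rep_len(target_area, n),
    model = rep_len(model, n),
    drawn_g1 = g1,
    arrested = FALSE,
    arrest_total = 0
  )
}

cycle_duration <- function(cells, params) {
  cells$drawn_g1 + params$s + params$g2 + params$m
}

#' Advance cell cycles by one time step
#'
#' Ages every cell to time `t` and flags division readiness: a cell is ready
#' when its effective age (wall age minus accumulated arrested time) reaches
#' its total cycle duration. Contact-inhibited cells in G1 whose current area
#' is below `quiescent_area_fraction * target_area` arrest for this step:
#' the step's `dt` is added to their arrested time, extending the cycle.
#'
#' @param cells Cell table (see [new_cell_table()]).
#' @param dt Time step (>= 0).
#' @param t Current simulation time (after the step).
#' @param areas Current cell areas, one per row of `cells` (used by the
#'   contact-inhibited model; ignored otherwise).
#' @param params A [cycle_params()].
#' @return List with elements `cells` (updated table) and `ready` (logical
#'   vector of division-ready flags).
#' @export
advance_cycle <- function(cells, dt, t, areas = NULL, params = cycle_params()) {
  if (length(dt) != 1L || !is.finite(dt) || dt < 0) {
    ts_stop("dt must be a single non-negative number", "tissuesim_clock_error")
  }
  n <- nrow(cells)
  if (n == 0L) return(list(cells = cells, ready = logical(0)))
  cells$arrested <- rep(FALSE, n)
  active <- cells$model != "none"
  if (dt > 0 && any(active)) {
    ci <- active & cells$model == "contact_inhibited"
    if (any(ci)) {
      if (is.null(areas)) {
        ts_stop("contact-inhibited model requires current areas",
                "tissuesim_state_error")
      }
      eff_age <- (t - cells$birth_time) - cells$arrest_total
      in_g1 <- eff_age < cells$drawn_g1 + dt  # still progressing through G1
      small <- areas < params$quiescent_area_fraction * cells$target_area
      arrest <- ci & in_g1 & small
      cells$arrested[arrest] <- TRUE
      cells$arrest_total[arrest] <- cells$arrest_total[arrest] + dt
    }
  }
  eff_age <- (t - cells$birth_time) - cells$arrest_total
  ready <- active & !cells$arrested & eff_age >= cycle_duration(cells, params) &
    !is.na(cells$drawn_g1)
  ready[is.na(ready)] <- FALSE
  list(cells = cells, ready = ready)
}

#' Create two daughter cells from a division-ready parent
#'
#' Daughters inherit the parent's type and target area, are born at time `t`
#' with fresh ids, and (for the stochastic models) redraw their G1 durations
#' independently.
#'
#' @param cells Cell table.
#' @param parent_row Row index of the dividing cell.
#' @param t Division time.
#' @param params A [cycle_params()].
#' @param ready Logical readiness flag for the parent (guard; see
#'   [advance_cycle()]).
#' @return List with `cells` (parent row replaced by two daughter rows,
#'   appended at the end) and `daughter_ids` (length 2).
#' @export
make_daughters <- function(cells, parent_row, t, params = cycle_params(),
                           ready = TRUE) {
  if (!isTRUE(ready)) {
    ts_stop("make_daughters called on a cell that is not division-ready",
            "tissuesim_state_error")
  }
  parent <- cells[parent_row, ]
  new_ids <- max(cells$id) + 1:2
  d <- parent[c(1, 1), ]
  d$id <- new_ids
  d$birth_time <- t
  d$target_area <- parent$target_area
  d$arrested <- FALSE
  d$arrest_total <- 0
  d$drawn_g1 <- if (parent$model == "none") NA_real_ else
    draw_g1(parent$model, params, 2L)
  cells <- rbind(cells[-parent_row, ], d)
  rownames(cells) <- NULL
  list(cells = cells, daughter_ids = new_ids)
}
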