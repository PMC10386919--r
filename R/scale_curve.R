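#' Default enrolment grid for economy-of-scale analysis
#'
#' Every multiple of 40 from 40 to 3200 participants; step 40 resolves
#' the sawtooth structure of stand-alone staffing at plausible
#' counselor capacities.
#'
#' @return Integer vector of enrolment sizes.
#' @export
default_scale_grid <- function() seq(40L, 3200L, by = 40L)

#' Per-participant cost curve over enrolment size
#'
#' Evaluates a replication scenario at every enrolment size on the
#' grid and records total cost / n. Integrated scenarios give smooth,
#' monotone non-increasing curves; stand-alone scenarios give a
#' sawtooth, jumping each time another whole counselor must be hired.
#' The curve's large-n limit is recorded as its asymptote (see
#' [asymptotic_cost()]).
#'
#' @param template An [arm_template()].
#' @param spec A [scenario_spec()]; its `n_participants` is ignored
#'   and swept over the grid.
#' @param grid Strictly increasing enrolment sizes, all >= 1.
#' @return A `scale_curve`: tibble with columns `arm, scenario, n,
#'   per_participant` and attributes `asymptote` and `spec`.
#' @examples
#' tpl <- observed_templates()$live
#' spec <- canonical_scenarios(tpl, n = 1, include_startup = TRUE)$ngo_integrated
#' curve <- cost_curve(tpl, spec)
#' head(curve)
#' @export
cost_curve <- function(template, spec, grid = default_scale_grid()) {
  stopifnot(inherits(template, "arm_template"), inherits(spec, "scenario_spec"))
  if (length(grid) == 0 || any(grid < 1)) {
    abort("`grid` must be non-empty with all sizes >= 1.",
      class = "boostercost_validation_error"
    )
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing.",
      class = "boostercost_validation_error"
    )
  }
  pp <- vapply(grid, function(n) {
    s <- spec
    s$n_participants <- n
    apply_scenario(template, s)$total / n
  }, numeric(1))
  out <- tibble(
    arm = template$arm, scenario = spec$name,
    n = as.numeric(grid), per_participant = pp
  )
  attr(out, "asymptote") <- asymptotic_cost(template, spec)
  attr(out, "spec") <- spec
  class(out) <- c("scale_curve", class(out))
  out
}

#' Large-enrolment asymptote of the per-participant cost
#'
#' As enrolment grows, fixed programme costs (start-up,
#' intervention-level recurring) vanish per head and staffing
#' approaches `n / capacity` FTE, so cost per participant tends to the
#' participant-level unit cost plus the annual loaded counselor cost
#' divided by capacity (plus the per-head connectivity rate when
#' connectivity is usage-based). Every point of [cost_curve()] is
#' bounded below by this limit.
#'
#' @inheritParams cost_curve
#' @return Money per participant.
#' @export
asymptotic_cost <- function(template, spec) {
  stopifnot(inherits(template, "arm_template"), inherits(spec, "scenario_spec"))
  unit <- sum(template$participant_units$unit)
  counselor_term <- (spec$salary_table[["counselor"]] + spec$counselor_overhead) /
    spec$counselor_capacity
  conn_term <- if (spec$scale_connectivity &&
    !"connectivity" %in% spec$excluded_categories) {
    template$connectivity_obs / template$n_obs
  } else {
    0
  }
  unname(unit + counselor_term + conn_term)
}

#' First crossover between two cost curves
#'
#' Returns the smallest grid size at which the sign of
#' `per_participant(a) - per_participant(b)` differs from its sign at
#' the start of the grid (exact equality counts as a crossover at that
#' size), or `NA` if the ordering never changes. Reported at grid
#' resolution; no interpolation.
#'
#' @param curve_a,curve_b `scale_curve`s on the same grid.
#' @return Enrolment size, or `NA` if the curves never cross.
#' @export
find_crossover <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "scale_curve"), inherits(curve_b, "scale_curve"))
  if (!identical(curve_a$n, curve_b$n)) {
    abort("curves must share the same enrolment grid.",
      class = "boostercost_validation_error"
    )
  }
  d <- curve_a$per_participant - curve_b$per_participant
  s0 <- sign(d[1])
  if (s0 == 0) {
    return(curve_a$n[1])
  }
  changed <- which(sign(d) != s0)
  if (length(changed) == 0) NA_real_ else curve_a$n[changed[1]]
}

#' Export scale curves as delimited text
#'
#' One row per (curve, enrolment size):
#' `arm, scenario, n, per_participant`.
#'
#' @param curves A `scale_curve` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_curves <- function(curves, path) {
  if (inherits(curves, "scale_curve")) curves <- list(curves)
  readr::write_csv(dplyr::bind_rows(lapply(curves, as_tibble)), path,
    progress = FALSE
  )
  invisible(path)
}

#' Plot economy-of-scale curves
#'
#' Per-participant cost against enrolment size, one line per arm,
#' facetted by scenario — the four-panel economy-of-scale layout.
#'
#' @param curves List of `scale_curve`s (any mix of arms/scenarios).
#' @return A ggplot object.
#' @export
plot_cost_curves <- function(curves) {
  if (inherits(curves, "scale_curve")) curves <- list(curves)
  dat <- dplyr::bind_rows(lapply(curves, as_tibble))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$n, y = .data$per_participant, colour = .data$arm)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(
      x = "Participants enrolled",
      y = "Cost per participant (USD)",
      colour = "Booster delivery"
    ) +
    ggplot2::theme_minimal()
}
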