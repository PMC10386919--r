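#' Specify a synthetic costing dataset
#'
#' The generator emits random but structurally valid cost ledgers,
#' effort logs and participant counts with *recorded ground truth*, so
#' the whole pipeline (allocation, aggregation, scenarios) can be
#' property-tested without external data. The same seed always yields
#' the same dataset, and both generators derive the same underlying
#' arm weights from it, so a generated effort log allocates a
#' generated ledger back to its recorded per-arm totals.
#'
#' Default amount ranges are loosely calibrated to the magnitude of
#' the observed trial (hundreds to low thousands of USD per category);
#' default recipient counts are the observed 160/40/61. They model
#' orders of magnitude only, not Ugandan price distributions.
#'
#' @param seed Integer seed; part of the public contract.
#' @param arms Non-empty subset of [delivery_arms()].
#' @param category_ranges Named list of `c(min, max)` USD ranges per
#'   category; defaults cover the full vocabulary.
#' @param shared_fraction Probability that an implementation-phase
#'   item is emitted as `arm = "shared"` (pre-allocation) instead of
#'   arm-specific.
#' @param effort_profile List with `total_hours` and `research_hours`
#'   ranges for the counselor effort log.
#' @param n_per_arm Named recipient counts.
#' @return A `synthetic_spec` object.
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' gen <- generate_ledger(spec)
#' gen$ground_truth$arm_totals
#' @export
synthetic_spec <- function(seed,
                           arms = delivery_arms(),
                           category_ranges = NULL,
                           shared_fraction = 0.3,
                           effort_profile = list(
                             total_hours = c(100, 400),
                             research_hours = c(20, 200)
                           ),
                           n_per_arm = c(live = 160, sms = 40, ivr = 61)) {
  if (length(arms) == 0 || !all(arms %in% delivery_arms())) {
    abort("`arms` must be a non-empty subset of delivery_arms().",
      class = "boostercost_validation_error"
    )
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must lie in [0, 1].",
      class = "boostercost_validation_error"
    )
  }
  defaults <- list(
    hardware = c(0, 200), software = c(500, 8000), training = c(50, 300),
    office_equipment = c(100, 800), staff_salaries = c(1000, 8000),
    connectivity = c(100, 5000), office_consumables = c(10, 2000),
    counselor_time = c(500, 9000), printed_material = c(100, 2000),
    phone_credit_counselor = c(0, 200), phone_credit_participant = c(0, 300),
    sms_charges = c(0, 100)
  )
  category_ranges <- utils::modifyList(defaults, category_ranges %||% list())
  if (any(vapply(category_ranges, function(r) any(r < 0) || r[2] < r[1], logical(1)))) {
    abort("`category_ranges` must be non-negative c(min, max) pairs.",
      class = "boostercost_validation_error"
    )
  }
  structure(
    list(
      seed = as.integer(seed), arms = arms,
      category_ranges = category_ranges,
      shared_fraction = shared_fraction,
      effort_profile = effort_profile,
      n_per_arm = n_per_arm
    ),
    class = "synthetic_spec"
  )
}

# cell skeleton shared by generator and fixtures: which categories sit
# in which (phase, resource_class, level) block
ledger_skeleton <- function() {
  tibble(
    category = c(
      "hardware", "software", "training", "office_equipment",
      "staff_salaries", "connectivity", "office_consumables",
      "counselor_time", "office_equipment", "office_consumables",
      "printed_material", "phone_credit_counselor",
      "phone_credit_participant", "sms_charges"
    ),
    phase = rep(c("start_up", "implementation"), c(4, 10)),
    resource_class = rep(c("capital", "recurring"), c(4, 10)),
    level = rep(
      c("intervention", "intervention", "counselor", "participant"),
      c(4, 3, 3, 4)
    )
  )
}

# arm weights are the first draws from the seed in BOTH generators, so
# a generated effort log reproduces the weights used for the ledger's
# shared items
draw_weights <- function(spec) {
  u <- stats::runif(length(spec$arms))
  w <- stats::setNames(u / sum(u), spec$arms)
  full <- stats::setNames(numeric(length(delivery_arms())), delivery_arms())
  full[names(w)] <- w
  full
}

#' Generate a synthetic cost ledger with known ground truth
#'
#' One line item per arm and skeleton cell, drawn uniformly within the
#' category's range and rounded to cents at generation;
#' implementation-phase items are emitted as `arm = "shared"` with
#' probability `shared_fraction`. The ground truth records the arm
#' weights used for shared items and the full-precision per-arm,
#' per-cell totals after allocation, so
#' `summarize_arm(allocate_ledger(ledger, weights), arm)` must
#' reproduce them.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ledger` (a `cost_ledger`), and `ground_truth`:
#'   `weights` ([allocation_weights()]), `arm_totals` (named numeric),
#'   `cell_totals` (tibble `arm, phase, level, category, amount`).
#' @export
generate_ledger <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    weights <- draw_weights(spec)
    skel <- ledger_skeleton()
    rows <- purrr::map_dfr(spec$arms, function(a) {
      x <- skel
      x$arm <- a
      x$amount <- vapply(x$category, function(cat) {
        r <- spec$category_ranges[[cat]]
        round_half_up(stats::runif(1, r[1], r[2]))
      }, numeric(1), USE.NAMES = FALSE)
      x
    })
    to_share <- rows$phase == "implementation" &
      stats::runif(nrow(rows)) < spec$shared_fraction
    truth_rows <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (to_share[i]) {
        active <- names(weights)[weights > 0]
        purrr::map_dfr(active, function(a) {
          out <- r
          out$arm <- a
          out$amount <- r$amount * weights[[a]]
          out
        })
      } else {
        r
      }
    })
    rows$arm[to_share] <- "shared"
    rows$currency <- "USD"
    rows$note <- ifelse(to_share, "synthetic shared pool", "synthetic")
    ledger <- validate_ledger(rows)

    cell_totals <- truth_rows %>%
      dplyr::group_by(.data$arm, .data$phase, .data$level, .data$category) %>%
      dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
    arm_totals <- vapply(
      spec$arms,
      function(a) sum(cell_totals$amount[cell_totals$arm == a]),
      numeric(1)
    )
    list(
      ledger = ledger,
      ground_truth = list(
        weights = allocation_weights(weights),
        arm_totals = arm_totals,
        cell_totals = cell_totals
      )
    )
  })
}

#' Generate a synthetic counselor effort log with known weights
#'
#' Draws the same arm weights as [generate_ledger()] under the same
#' seed, a total number of intervention hours, and research hours.
#' Per-arm hours are exactly proportional to the weights (split across
#' session, booster-call, preparation and administration tasks), so
#' [effort_fractions()] on the log recovers the recorded weights to
#' numerical precision.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `log` (an `effort_log`) and `ground_truth`
#'   (`weights`, `total_hours`, `research_hours`).
#' @export
generate_effort_log <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    weights <- draw_weights(spec)
    total <- stats::runif(
      1, spec$effort_profile$total_hours[1], spec$effort_profile$total_hours[2]
    )
    research <- stats::runif(
      1, spec$effort_profile$research_hours[1], spec$effort_profile$research_hours[2]
    )
    task_split <- c(
      in_person_session = 0.4, live_booster_call = 0.3,
      session_prep = 0.2, admin = 0.1
    )
    active <- names(weights)[weights > 0]
    rows <- purrr::map_dfr(active, function(a) {
      tibble(
        staff_role = "counselor",
        task = names(task_split),
        arm = a,
        hours = total * weights[[a]] * unname(task_split),
        period_start = NA_character_, period_end = NA_character_
      )
    })
    rows <- dplyr::bind_rows(rows, tibble(
      staff_role = "counselor", task = "research", arm = "research",
      hours = research,
      period_start = NA_character_, period_end = NA_character_
    ))
    list(
      log = validate_effort_log(rows),
      ground_truth = list(
        weights = allocation_weights(weights),
        total_hours = total, research_hours = research
      )
    )
  })
}

#' Generate a synthetic participant flow
#'
#' Recipient counts from the spec's `n_per_arm`, split between
#' randomized and wait-list uptake.
#'
#' @param spec A [synthetic_spec()].
#' @return A [participant_flow()].
#' @export
generate_flow <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- stats::setNames(numeric(length(delivery_arms())), delivery_arms())
  n[names(spec$n_per_arm)] <- spec$n_per_arm
  randomized <- floor(n / 2)
  participant_flow(
    randomized = randomized,
    waitlist_uptake = n - randomized,
    declined = 0, lost = 0
  )
}
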