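#' Build a staff effort log
#'
#' Effort logs record hours worked by staff role, task and delivery
#' arm over calendar periods; they drive the allocation of shared
#' costs across arms. Research activity (adapting the intervention,
#' running the trial) is logged with `task = "research"` and
#' `arm = "research"` and is excluded from all intervention costing.
#'
#' @param staff_role One of [staff_roles()].
#' @param task One of [effort_tasks()].
#' @param arm A delivery arm, `"shared"`, or `"research"`.
#' @param hours Non-negative hours.
#' @param period_start,period_end Optional period bounds (ISO dates as
#'   text; kept as-is).
#' @return A validated `effort_log` tibble.
#' @examples
#' effort_records(
#'   staff_role = "counselor",
#'   task = c("live_booster_call", "research"),
#'   arm = c("live", "research"),
#'   hours = c(30, 100)
#' )
#' @export
effort_records <- function(staff_role, task, arm, hours,
                           period_start = NA_character_,
                           period_end = NA_character_) {
  x <- tibble(
    staff_role = as.character(staff_role),
    task = as.character(task),
    arm = as.character(arm),
    hours = as.numeric(hours),
    period_start = as.character(period_start),
    period_end = as.character(period_end)
  )
  validate_effort_log(x)
}

#' @param x A data frame with effort-log columns.
#' @rdname effort_records
#' @export
validate_effort_log <- function(x) {
  x <- as_tibble(x)
  for (col in c("period_start", "period_end")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  missing_cols <- setdiff(c("staff_role", "task", "arm", "hours"), names(x))
  if (length(missing_cols) > 0) {
    validation_error(paste0(
      "effort log is missing required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- function(ok, what, values) {
    if (any(!ok)) {
      validation_error(
        sprintf("invalid %s in effort log", what),
        rows = which(!ok), values = values[!ok]
      )
    }
  }
  bad(x$staff_role %in% staff_roles(), "staff_role", x$staff_role)
  bad(x$task %in% effort_tasks(), "task", x$task)
  bad(x$arm %in% c(ledger_arms(), "research"), "arm", x$arm)
  bad(!is.na(x$hours) & x$hours >= 0, "hours", x$hours)
  bad(
    !(x$task == "research" & x$arm != "research"),
    "arm (research tasks must carry arm = research)", x$arm
  )
  x <- x[, effort_columns()]
  class(x) <- c("effort_log", class(x))
  x
}

#' Read and write effort-log files
#'
#' Delimited text, header
#' `staff_role,task,arm,hours,period_start,period_end`.
#'
#' @param path File path.
#' @param log An `effort_log` tibble.
#' @return `read_effort_log` returns a validated `effort_log`;
#'   `write_effort_log` returns `path` invisibly.
#' @export
read_effort_log <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      hours = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  validate_effort_log(x)
}

#' @rdname read_effort_log
#' @export
write_effort_log <- function(log, path) {
  log <- validate_effort_log(log)
  readr::write_csv(as_tibble(log), path, progress = FALSE)
  invisible(path)
}

#' Effort-based allocation weights for one staff pool
#'
#' Computes, for one staff role, the fraction of that role's shared
#' costs attributable to each delivery arm: research hours are dropped
#' entirely (non-intervention activity is removed from the costing),
#' hours logged against `"shared"` carry no arm information and are
#' likewise excluded from the weights, and the remaining per-arm hours
#' are normalized to sum to one. An arm with no effort receives weight
#' zero; if *all* intervention effort for the pool is zero the pool is
#' unallocatable and an error is raised.
#'
#' @param records An `effort_log`.
#' @param pool Staff role whose costs are being allocated.
#' @return An `allocation_weights` object: named fractions over
#'   [delivery_arms()] summing to 1.
#' @examples
#' log <- effort_records(
#'   staff_role = "counselor",
#'   task = c("live_booster_call", "in_person_session", "in_person_session", "research"),
#'   arm = c("live", "sms", "ivr", "research"),
#'   hours = c(30, 5, 8.3, 100)
#' )
#' effort_fractions(log, "counselor") # 30/43.3, 5/43.3, 8.3/43.3
#' @export
effort_fractions <- function(records, pool = "counselor") {
  records <- validate_effort_log(records)
  pool <- check_enum(pool, staff_roles(), "pool")
  rel <- records[records$staff_role == pool & records$task != "research" &
    records$arm %in% delivery_arms(), ]
  hours <- vapply(
    delivery_arms(),
    function(a) sum(rel$hours[rel$arm == a]),
    numeric(1)
  )
  total <- sum(hours)
  if (nrow(records[records$staff_role == pool, ]) == 0 || total <= 0) {
    abort(
      sprintf(
        "pool %s has no intervention effort; shared costs cannot be allocated.",
        pool
      ),
      class = "boostercost_unallocatable_pool"
    )
  }
  allocation_weights(hours / total)
}

#' @param fractions Named non-negative fractions over delivery arms
#'   summing to 1 (within 1e-9).
#' @rdname effort_fractions
#' @export
allocation_weights <- function(fractions) {
  fractions <- fractions[!is.na(names(fractions))]
  unknown <- setdiff(names(fractions), delivery_arms())
  if (length(unknown) > 0) {
    validation_error("unknown arm in allocation weights", values = unknown)
  }
  w <- stats::setNames(numeric(length(delivery_arms())), delivery_arms())
  w[names(fractions)] <- as.numeric(fractions)
  if (any(w < 0) || any(w > 1)) {
    abort("allocation weights must lie in [0, 1].",
      class = "boostercost_validation_error"
    )
  }
  if (abs(sum(w) - 1) > 1e-9) {
    abort(
      sprintf("allocation weights must sum to 1 (got %.12f).", sum(w)),
      class = "boostercost_validation_error"
    )
  }
  structure(w, class = "allocation_weights")
}

#' @export
print.allocation_weights <- function(x, ...) {
  cat("Allocation weights:",
    paste(sprintf("%s = %.4f", names(x), unclass(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Split shared cost items across arms
#'
#' `allocate_pool()` splits each `arm = "shared"` line item into one
#' item per arm with positive weight, conserving the total amount at
#' full precision and preserving category, phase, resource class and
#' level. `allocate_ledger()` applies this to the shared rows of a
#' mixed ledger and passes arm-specific rows through unchanged (so a
#' fully allocated ledger is a fixed point).
#'
#' @param pool_items A `cost_ledger` whose rows all have `arm = "shared"`.
#' @param weights An [allocation_weights()] object.
#' @return A `cost_ledger` of arm-specific items.
#' @examples
#' pool <- cost_items(
#'   category = "staff_salaries", phase = "implementation",
#'   resource_class = "recurring", level = "intervention",
#'   arm = "shared", amount = 100
#' )
#' allocate_pool(pool, allocation_weights(c(live = 0.5, sms = 0.25, ivr = 0.25)))
#' @export
allocate_pool <- function(pool_items, weights) {
  pool_items <- validate_ledger(pool_items)
  if (nrow(pool_items) == 0) {
    abort("`pool_items` is empty.", class = "boostercost_validation_error")
  }
  if (any(pool_items$arm != "shared")) {
    abort("`pool_items` must all have arm = \"shared\"; use allocate_ledger() for mixed ledgers.",
      class = "boostercost_validation_error"
    )
  }
  weights <- allocation_weights(weights)
  arms <- names(weights)[unclass(weights) > 0]
  out <- purrr::map_dfr(arms, function(a) {
    piece <- as_tibble(pool_items)
    piece$arm <- a
    piece$amount <- piece$amount * weights[[a]]
    piece
  })
  validate_ledger(out)
}

#' @param ledger A `cost_ledger` possibly mixing shared and
#'   arm-specific rows.
#' @rdname allocate_pool
#' @export
allocate_ledger <- function(ledger, weights) {
  ledger <- validate_ledger(ledger)
  shared <- ledger[ledger$arm == "shared", ]
  specific <- ledger[ledger$arm != "shared", ]
  if (nrow(shared) == 0) {
    return(ledger)
  }
  validate_ledger(dplyr::bind_rows(
    as_tibble(specific),
    as_tibble(allocate_pool(shared, weights))
  ))
}

#' Counselor time cost for one arm
#'
#' Values the counselor hours attributable to a delivery arm
#' (in-person sessions, live booster calls, session preparation and
#' administration) at an hourly rate. Research hours are excluded.
#'
#' @param records An `effort_log`.
#' @param hourly_rate Positive money per hour.
#' @param arm Delivery arm.
#' @return Cost in the rate's currency (full precision).
#' @examples
#' log <- effort_records(
#'   staff_role = "counselor",
#'   task = c("live_booster_call", "research"),
#'   arm = c("live", "research"), hours = c(4, 1)
#' )
#' counselor_time_cost(log, 20, "live") # 80
#' @export
counselor_time_cost <- function(records, hourly_rate, arm) {
  records <- validate_effort_log(records)
  arm <- check_enum(arm, delivery_arms(), "arm")
  if (!is.numeric(hourly_rate) || length(hourly_rate) != 1 ||
      is.na(hourly_rate) || hourly_rate <= 0) {
    abort("`hourly_rate` must be a single positive number.",
      class = "boostercost_validation_error"
    )
  }
  rel <- records[records$staff_role == "counselor" &
    records$task != "research" & records$arm == arm, ]
  sum(rel$hours) * hourly_rate
}
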