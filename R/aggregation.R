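#' Recipients of one booster delivery mode
#'
#' Participants who received the intervention with a given booster
#' delivery mode: those randomized to it plus wait-list control
#' participants who chose it. With the default [participant_flow()]
#' this gives 160 live, 40 SMS and 61 IVR recipients.
#'
#' @param flow A [participant_flow()].
#' @param arm `"live"`, `"sms"` or `"ivr"`.
#' @return Integer count.
#' @examples
#' recipients(participant_flow(), "sms") # 40
#' @export
recipients <- function(flow, arm) {
  if (!inherits(flow, "participant_flow")) {
    abort("`flow` must be a participant_flow object.",
      class = "boostercost_validation_error"
    )
  }
  arm <- check_enum(arm, delivery_arms(), "arm")
  flow$randomized[[arm]] + flow$waitlist_uptake[[arm]]
}

cell_order <- function(x) {
  order(
    match(x$phase, cost_phases()),
    match(x$level, cost_levels()),
    match(x$category, cost_categories())
  )
}

#' Summarize the observed costs of one delivery arm
#'
#' Aggregates a fully allocated ledger into the per-arm cost table:
#' one cell per (phase, level, category) with its amount and its share
#' of the arm total, plus block subtotals per (phase, level) and the
#' arm total. Shares are computed on full-precision amounts and only
#' rounded when printed. Every ledger row for the arm lands in exactly
#' one cell; rows for other arms are ignored, but `arm = "shared"`
#' rows are an error — allocate first (see [allocate_ledger()]).
#'
#' @param ledger A fully allocated `cost_ledger`.
#' @param arm Delivery arm to summarize.
#' @return An `arm_summary`: list with `arm`, `total`, `cells`
#'   (tibble `phase, level, category, amount, share`) and `subtotals`
#'   (tibble `phase, level, amount, share`). Shares are percentages of
#'   the arm total, full precision.
#' @examples
#' s <- summarize_arm(load_observed_fixture("live"), "live")
#' s$total # 23082.93
#' @export
summarize_arm <- function(ledger, arm) {
  ledger <- validate_ledger(ledger)
  arm <- check_enum(arm, delivery_arms(), "arm")
  if (any(ledger$arm == "shared")) {
    abort(
      "ledger contains shared items; run allocate_ledger() before summarizing.",
      class = "boostercost_validation_error"
    )
  }
  items <- ledger[ledger$arm == arm, ]
  total <- sum(items$amount)
  cells <- items %>%
    dplyr::group_by(.data$phase, .data$level, .data$category) %>%
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
  cells <- cells[cell_order(cells), ]
  cells$share <- if (total > 0) cells$amount / total * 100 else rep(0, nrow(cells))
  subtotals <- cells %>%
    dplyr::group_by(.data$phase, .data$level) %>%
    dplyr::summarise(
      amount = sum(.data$amount), share = sum(.data$share), .groups = "drop"
    )
  subtotals <- subtotals[order(
    match(subtotals$phase, cost_phases()),
    match(subtotals$level, cost_levels())
  ), ]
  structure(
    list(arm = arm, total = total, cells = cells, subtotals = subtotals),
    class = "arm_summary"
  )
}

#' Per-participant cost table for one arm
#'
#' Divides every cell, subtotal and the total of an [summarize_arm()]
#' summary by the number of recipients `n` and rounds half-up to
#' cents. Percentage shares are *copied* from the arm-level summary
#' rather than recomputed: the published per-participant table prints
#' the same composition as the overall table, and recomputing from
#' rounded per-head amounts would not.
#'
#' @param summary An `arm_summary`.
#' @param n Number of recipients (>= 1); see [recipients()].
#' @return A `per_participant_summary` with the same shape plus `n`.
#' @examples
#' s <- summarize_arm(load_observed_fixture("live"), "live")
#' per_participant(s, 160)$total # 144.27
#' @export
per_participant <- function(summary, n) {
  if (!inherits(summary, "arm_summary")) {
    abort("`summary` must be an arm_summary.", class = "boostercost_validation_error")
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort("`n` must be a single integer >= 1 (per-participant cost is undefined for n = 0).",
      class = "boostercost_validation_error"
    )
  }
  cells <- summary$cells
  cells$amount <- round_half_up(cells$amount / n)
  subtotals <- summary$subtotals
  subtotals$amount <- round_half_up(subtotals$amount / n)
  structure(
    list(
      arm = summary$arm, n = as.integer(n),
      total = round_half_up(summary$total / n),
      cells = cells, subtotals = subtotals
    ),
    class = c("per_participant_summary", "arm_summary")
  )
}

#' Flat table rendering of a cost summary
#'
#' Returns the summary as a tidy tibble (cells, block subtotals and
#' the total as rows) suitable for delimited-text or JSON export.
#'
#' @param summary An `arm_summary` or `per_participant_summary`.
#' @param round Apply presentation rounding (half-up; cents for
#'   amounts, 2 decimals for shares)? Per-participant amounts are
#'   already in cents by construction.
#' @return A tibble with columns
#'   `arm, row_type, phase, level, category, amount, share`.
#' @export
summary_table <- function(summary, round = TRUE) {
  stopifnot(inherits(summary, "arm_summary"))
  cells <- summary$cells
  cells$row_type <- "cell"
  sub <- summary$subtotals
  sub$category <- NA_character_
  sub$row_type <- "subtotal"
  tot <- tibble(
    phase = NA_character_, level = NA_character_, category = NA_character_,
    amount = summary$total, share = if (summary$total > 0) 100 else 0,
    row_type = "total"
  )
  out <- dplyr::bind_rows(as_tibble(cells), as_tibble(sub), tot)
  if (round) {
    out$amount <- round_half_up(out$amount)
    out$share <- round_half_up(out$share)
  }
  out <- out[, c("row_type", "phase", "level", "category", "amount", "share")]
  out$arm <- summary$arm
  out[, c("arm", "row_type", "phase", "level", "category", "amount", "share")]
}

#' Export a cost summary
#'
#' Writes the flat rendering of [summary_table()] as comma-separated
#' text or JSON.
#'
#' @inheritParams summary_table
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_summary <- function(summary, path, format = c("csv", "json"), round = TRUE) {
  format <- match.arg(format)
  tab <- summary_table(summary, round = round)
  if (format == "csv") {
    readr::write_csv(tab, path, progress = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null", digits = NA)
  }
  invisible(path)
}

#' @export
print.arm_summary <- function(x, ...) {
  per_head <- inherits(x, "per_participant_summary")
  cat(sprintf(
    "%s cost summary, arm = %s%s\n",
    if (per_head) "Per-participant" else "Observed", x$arm,
    if (per_head) sprintf(" (n = %d)", x$n) else ""
  ))
  for (i in seq_len(nrow(x$subtotals))) {
    s <- x$subtotals[i, ]
    cat(sprintf(
      "  %-14s %-12s $%11s  %6.2f%%\n", s$phase, s$level,
      format(round_half_up(s$amount), big.mark = ",", nsmall = 2),
      round_half_up(s$share)
    ))
    block <- x$cells[x$cells$phase == s$phase & x$cells$level == s$level, ]
    for (j in seq_len(nrow(block))) {
      cat(sprintf(
        "    %-26s $%11s  %6.2f%%\n", block$category[j],
        format(round_half_up(block$amount[j]), big.mark = ",", nsmall = 2),
        round_half_up(block$share[j])
      ))
    }
  }
  cat(sprintf(
    "  %-27s $%11s  100.00%%\n", "Total",
    format(round_half_up(x$total), big.mark = ",", nsmall = 2)
  ))
  invisible(x)
}
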