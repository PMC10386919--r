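#' Controlled vocabularies for cost ledgers
#'
#' The ledger schema is closed: every line item must use one of these
#' values. `cost_categories()` is returned in the canonical display
#' order of the observed cost tables, so reports are bit-reproducible.
#'
#' @return A character vector of allowed values.
#' @examples
#' cost_categories()
#' cost_levels()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
cost_categories <- function() {
  c(
    "hardware", "software", "training", "office_equipment",
    "staff_salaries", "connectivity", "office_consumables",
    "counselor_time", "printed_material",
    "phone_credit_counselor", "phone_credit_participant", "sms_charges"
  )
}

#' @rdname vocabularies
#' @export
cost_phases <- function() c("start_up", "implementation")

#' @rdname vocabularies
#' @export
resource_classes <- function() c("capital", "recurring")

#' @rdname vocabularies
#' @export
cost_levels <- function() c("intervention", "counselor", "participant")

#' @rdname vocabularies
#' @export
delivery_arms <- function() c("live", "sms", "ivr")

#' @rdname vocabularies
#' @export
ledger_arms <- function() c(delivery_arms(), "shared")

#' @rdname vocabularies
#' @export
currencies <- function() c("USD", "UGX")

#' @rdname vocabularies
#' @export
staff_roles <- function() c("counselor", "coordinator", "data_manager", "oversight")

#' @rdname vocabularies
#' @export
effort_tasks <- function() {
  c("in_person_session", "live_booster_call", "session_prep", "admin", "research")
}

# column order of a ledger file / cost_item tibble
ledger_columns <- function() {
  c("category", "phase", "resource_class", "level", "arm", "amount", "currency", "note")
}

effort_columns <- function() {
  c("staff_role", "task", "arm", "hours", "period_start", "period_end")
}
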