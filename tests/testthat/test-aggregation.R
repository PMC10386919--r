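test_that("arm summaries reproduce every published overall-cost cell", {
  cells <- expected_cells()
  for (arm in c("live", "sms", "ivr")) {
    s <- summarize_arm(load_observed_fixture(arm), arm)
    got <- dplyr::left_join(
      cells[, c("phase", "level", "category")],
      s$cells,
      by = c("phase", "level", "category")
    )
    expect_equal(got$amount, cells[[paste0("amount_", arm)]])
    expect_equal(round_half_up(got$share), cells[[paste0("share_", arm)]])
  }
})

test_that("per-participant tables reproduce the published table cell-for-cell", {
  cells <- expected_cells()
  subs <- expected_subtotals()
  totals <- expected_totals()
  flow <- participant_flow()
  for (arm in c("live", "sms", "ivr")) {
    n <- recipients(flow, arm)
    expect_equal(n, totals$n[[arm]])
    p <- per_participant(summarize_arm(load_observed_fixture(arm), arm), n)
    expect_equal(p$total, totals$pp[[arm]])
    got <- dplyr::left_join(
      cells[, c("phase", "level", "category")], p$cells,
      by = c("phase", "level", "category")
    )
    expect_equal(got$amount, cells[[paste0("pp_", arm)]])
    # shares are carried over from the arm-level table, not recomputed
    expect_equal(round_half_up(got$share), cells[[paste0("share_", arm)]])
    got_sub <- dplyr::left_join(
      subs[, c("phase", "level")], p$subtotals,
      by = c("phase", "level")
    )
    expect_equal(got_sub$amount, subs[[paste0("pp_", arm)]])
    expect_equal(round_half_up(got_sub$share), subs[[paste0("share_", arm)]])
  }
})

test_that("summary structure is internally consistent", {
  for (arm in c("live", "sms", "ivr")) {
    s <- summarize_arm(load_observed_fixture(arm), arm)
    # cells sum to subtotals, subtotals to the total
    by_block <- dplyr::summarise(
      dplyr::group_by(s$cells, .data$phase, .data$level),
      amount = sum(.data$amount), .groups = "drop"
    )
    expect_equal(
      dplyr::arrange(by_block, .data$phase, .data$level)$amount,
      dplyr::arrange(s$subtotals, .data$phase, .data$level)$amount
    )
    expect_equal(sum(s$subtotals$amount), s$total)
    # rounded shares sum to 100 within rounding slack
    expect_lt(abs(sum(round_half_up(s$cells$share)) - 100), 0.05 + 1e-9)
    # per-participant total times n stays within half a cent per head
    n <- recipients(participant_flow(), arm)
    expect_lt(abs(per_participant(s, n)$total * n - s$total), n * 0.005)
  }
})

test_that("a single-item ledger is 100% of its arm", {
  one <- cost_items(
    category = "software", phase = "start_up", resource_class = "capital",
    level = "intervention", arm = "ivr", amount = 42
  )
  s <- summarize_arm(one, "ivr")
  expect_equal(s$total, 42)
  expect_equal(s$cells$share, 100)
  p1 <- per_participant(s, 1)
  expect_equal(p1$total, s$total)
  expect_equal(p1$cells$amount, s$cells$amount)
})

test_that("shared items are rejected with a pointer to allocation", {
  shared <- cost_items(
    category = "connectivity", phase = "implementation",
    resource_class = "recurring", level = "intervention",
    arm = "shared", amount = 10
  )
  expect_error(summarize_arm(shared, "live"), regexp = "allocate",
    class = "boostercost_validation_error"
  )
})

test_that("per-participant cost is undefined for n = 0 and non-integers", {
  s <- summarize_arm(tiny_ledger(), "live")
  expect_error(per_participant(s, 0), class = "boostercost_validation_error")
  expect_error(per_participant(s, 2.5), class = "boostercost_validation_error")
})

test_that("grouped aggregation matches naive item-by-item accumulation", {
  for (seed in 1:5) {
    gen <- generate_ledger(synthetic_spec(seed = seed, shared_fraction = 0))
    ledger <- gen$ledger
    for (arm in c("live", "sms", "ivr")) {
      s <- summarize_arm(ledger, arm)
      naive_total <- 0
      naive_cells <- list()
      for (i in seq_len(nrow(ledger))) {
        if (ledger$arm[i] != arm) next
        naive_total <- naive_total + ledger$amount[i]
        key <- paste(ledger$phase[i], ledger$level[i], ledger$category[i])
        prev <- if (is.null(naive_cells[[key]])) 0 else naive_cells[[key]]
        naive_cells[[key]] <- prev + ledger$amount[i]
      }
      expect_equal(s$total, naive_total)
      got <- stats::setNames(
        s$cells$amount,
        paste(s$cells$phase, s$cells$level, s$cells$category)
      )
      expect_mapequal(as.list(got), naive_cells)
    }
  }
})

test_that("adding a cost item never decreases the arm total", {
  base <- summarize_arm(tiny_ledger(), "live")$total
  for (amount in c(0, 0.01, 5, 1000)) {
    extra <- dplyr::bind_rows(
      tibble::as_tibble(tiny_ledger()),
      tibble::as_tibble(cost_items(
        category = "sms_charges", phase = "implementation",
        resource_class = "recurring", level = "participant",
        arm = "live", amount = amount
      ))
    )
    expect_gte(summarize_arm(extra, "live")$total, base)
  }
})

test_that("summary tables export to csv and json with optional rounding", {
  s <- summarize_arm(load_observed_fixture("sms"), "sms")
  tab <- summary_table(s, round = TRUE)
  expect_equal(tab$amount[tab$row_type == "total"], round_half_up(s$total))
  raw <- summary_table(s, round = FALSE)
  expect_equal(raw$amount[raw$row_type == "total"], s$total)

  csv <- withr::local_tempfile(fileext = ".csv")
  export_summary(s, csv, format = "csv")
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), nrow(tab))

  js <- withr::local_tempfile(fileext = ".json")
  export_summary(s, js, format = "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed), nrow(tab))
})
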