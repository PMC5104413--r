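test_that("image fields average over QC-passing fields only", {
  base <- tibble::tibble(
    plate_id = "P1", well = "B2", channel = "nuclei_count",
    replicate = 1L, field_index = 1:4, value = c(100, 110, 90, 100),
    qc_pass = TRUE)
  expect_equal(aggregate_image_fields(base)$value, 100)

  one_bad <- base
  one_bad$value[4] <- 500
  one_bad$qc_pass[4] <- FALSE
  agg <- aggregate_image_fields(one_bad)
  expect_equal(agg$value, 100)
  expect_false(agg$excluded)

  all_bad <- base
  all_bad$qc_pass <- FALSE
  agg <- aggregate_image_fields(all_bad)
  expect_true(agg$excluded)
  expect_true(is.na(agg$value))

  expect_error(aggregate_image_fields(base[0, ]),
               class = "nrf2screen_validation_error")
})

test_that("intra-plate normalization is percent of the negative-control mean", {
  layout <- make_screen_layout(n_test = 2)
  wells <- make_luci_wells(layout,
                           values = c(G001_pool = 232000, G002_pool = 200000),
                           default = 200000)
  nw <- intraplate_normalize(wells, layout)
  expect_equal(nw$value_pct[nw$entity_id == "G001_pool"], 116.0)
  # a negative-control well exactly at the control mean reads 100%
  expect_equal(nw$value_pct[nw$role == "neg_control"][1], 100)
  # negative-control mean is exactly 100% on every plate
  expect_equal(mean(nw$value_pct[nw$role == "neg_control"]), 100,
               tolerance = 1e-12)

  # PLK1-like well at half the control mean reads 50% on the nuclei channel
  nuc <- wells
  nuc$channel <- "nuclei_count"
  nuc$value <- ifelse(nuc$well %in% layout$well[layout$role == "plk1_control"],
                      600, 1200)
  nn <- intraplate_normalize(nuc, layout)
  expect_equal(unique(nn$value_pct[nn$role == "plk1_control"]), 50)
})

test_that("plates whose negative controls all fail QC are rejected", {
  layout <- make_screen_layout(n_test = 2)
  wells <- make_luci_wells(layout)
  wells$excluded[wells$well %in% layout$well[layout$role == "neg_control"]] <- TRUE
  expect_warning(nw <- intraplate_normalize(wells, layout),
                 class = "nrf2screen_plate_rejected")
  expect_equal(nrow(nw), 0L)
  expect_equal(nrow(attr(nw, "rejected")), 1L)

  qc <- plate_qc_report(wells, layout)
  expect_equal(qc$usable_neg_controls, 0L)
  expect_equal(qc$excluded_wells, 12L)
})

test_that("replicate aggregation uses sample statistics with n-1 denominator", {
  nw <- tibble::tibble(
    plate_id = "P1", well = "B2", role = "test",
    entity_id = "E1", gene_id = "G1", channel = "luminescence",
    replicate = 1:3, value_pct = c(100, 110, 120))
  s <- aggregate_replicates(nw)
  expect_equal(s$mean_pct, 110)
  expect_equal(s$sd_pct, 10)
  expect_equal(s$cv, 10 / 110)
  expect_equal(s$n_replicates, 3L)

  s0 <- aggregate_replicates(dplyr::mutate(nw, value_pct = 100))
  expect_equal(s0$sd_pct, 0)
  expect_equal(s0$cv, 0)

  s1 <- aggregate_replicates(nw[1, ] |> dplyr::mutate(value_pct = 130))
  expect_equal(s1$mean_pct, 130)
  expect_true(is.na(s1$sd_pct))
  expect_true(is.na(s1$cv))

  expect_warning(aggregate_replicates(nw, expected_entities = c("E1", "E2")),
                 class = "nrf2screen_missing_entity")
})

test_that("replicate aggregation is invariant to input order", {
  set.seed(41)
  nw <- tibble::tibble(
    plate_id = "P1",
    well = "A2",
    role = "test",
    entity_id = rep(sprintf("E%02d", 1:20), each = 3),
    gene_id = rep(sprintf("G%02d", 1:20), each = 3),
    channel = "luminescence",
    replicate = rep(1:3, 20),
    value_pct = runif(60, 80, 130))
  ordered <- aggregate_replicates(nw) |> dplyr::arrange(entity_id)
  shuffled <- aggregate_replicates(nw[sample(nrow(nw)), ]) |>
    dplyr::arrange(entity_id)
  expect_equal(ordered, shuffled)

  # brute-force per-entity loop agrees
  for (e in unique(nw$entity_id)) {
    v <- nw$value_pct[nw$entity_id == e]
    expect_equal(ordered$mean_pct[ordered$entity_id == e], mean(v))
    expect_equal(ordered$sd_pct[ordered$entity_id == e], sd(v))
  }
})

test_that("per-cell metric divides luciferase percent by nuclei percent", {
  mk <- function(luc, nuc) {
    tibble::tibble(
      entity_id = "E1", gene_id = "G1", role = "test",
      channel = c("luminescence", "nuclei_count"),
      mean_pct = c(luc, nuc), sd_pct = 1, cv = 0.01, n_replicates = 3L)
  }
  expect_equal(per_cell_normalize(mk(130, 100))$per_cell_pct, 130)
  expect_equal(per_cell_normalize(mk(100, 50))$per_cell_pct, 200)

  # identity at nuclei = 100% for arbitrary luciferase values
  for (x in c(25, 80, 100, 147.5, 310)) {
    expect_equal(per_cell_normalize(mk(x, 100))$per_cell_pct, x)
  }

  # missing denominator: flagged, no value
  luc_only <- mk(120, 100)[1, ]
  pc <- per_cell_normalize(luc_only)
  expect_true(is.na(pc$per_cell_pct))
  expect_true(pc$per_cell_flag)
})

test_that("CV profiling counts the fraction of entities below threshold", {
  s <- tibble::tibble(entity_id = paste0("E", 1:4), gene_id = paste0("G", 1:4),
                      role = "test", channel = "luminescence",
                      mean_pct = 100, sd_pct = 1,
                      cv = c(0.05, 0.08, 0.12, 0.20), n_replicates = 3L)
  expect_equal(cv_fraction_below(s, 0.10)$fraction_below, 0.5)
  expect_equal(cv_fraction_below(dplyr::mutate(s, cv = 0))$fraction_below, 1.0)
  expect_error(cv_fraction_below(dplyr::mutate(s, cv = NA_real_)),
               class = "nrf2screen_validation_error")
})
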