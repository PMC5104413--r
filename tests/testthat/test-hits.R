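test_that("the pass-1 threshold is mean + 2 SD of the test pools", {
  expect_equal(pass1_threshold(c(90, 100, 110)), 120)   # 100 + 2 * 10
  expect_equal(pass1_threshold(c(100, 100, 100)), 100)  # SD 0
  expect_equal(pass1_threshold(c(87, 100, 113)), 126)   # mean 100, SD 13
  expect_equal(pass1_threshold(c(90, 110), sd_mult = 1),
               100 + sd(c(90, 110)))
  expect_error(pass1_threshold(c(100)), class = "nrf2screen_validation_error")
})

test_that("pass-1 selection excludes controls and splits routes correctly", {
  luc <- c(rep(100, 20), 95, 105, 170, 100)
  pc <- c(rep(100, 20), 95, 105, 100, 180)
  et <- make_entity_tbl(luc, pc)
  # a KEAP1-like control well above every threshold must not become a hit
  et <- dplyr::bind_rows(
    et, make_entity_tbl(300, 300, role = "keap1_control",
                        gene_id = "KEAP1", entity_id = "KEAP1_pool"))
  hits <- select_pass1_hits(et)
  oracle <- brute_pass1(et)
  expect_setequal(hits$gene_id, oracle$union)
  expect_false("KEAP1" %in% hits$gene_id)
  expect_equal(hits$route[hits$gene_id == "G023"], "raw")
  expect_equal(hits$route[hits$gene_id == "G024"], "per_cell")
  expect_equal(attr(hits, "threshold_raw"), oracle$thr_raw)
  cts <- attr(hits, "counts")
  expect_equal(unname(cts["n_union"]),
               unname(cts["n_raw"] + cts["n_per_cell"] - cts["n_overlap"]))
})

test_that("pass-1 uses a strict greater-than boundary", {
  # degenerate population: every pool at 100, SD exactly 0, threshold
  # exactly 100 — every pool sits exactly at the threshold and none is a hit
  et <- make_entity_tbl(rep(100, 12))
  hits <- select_pass1_hits(et)
  expect_identical(attr(hits, "threshold_raw"), 100)
  expect_equal(nrow(hits), 0L)

  # one pool nudged above: threshold stays below it, strict > admits it
  et2 <- make_entity_tbl(c(rep(100, 5), 100.1))
  hits2 <- select_pass1_hits(et2)
  expect_lt(attr(hits2, "threshold_raw"), 100.1)
  expect_equal(hits2$gene_id, "G006")
})

test_that("deconvolution confirmation counts support with an inclusive 130% boundary", {
  tbl <- dplyr::bind_rows(
    make_entity_tbl(c(135, 110, 95), gene_id = rep("A", 3),
                    entity_id = paste0("A_si", 1:3)),
    make_entity_tbl(c(130.0, 131, 140), gene_id = rep("B", 3),
                    entity_id = paste0("B_si", 1:3)),
    make_entity_tbl(c(129, 128, 120), per_cell = c(140, 100, 100),
                    gene_id = rep("C", 3), entity_id = paste0("C_si", 1:3)),
    make_entity_tbl(c(99, 101, 100), gene_id = rep("D", 3),
                    entity_id = paste0("D_si", 1:3)))
  calls <- confirm_deconvolution(tbl, pass_number = 2)
  a <- calls[calls$gene_id == "A", ]
  expect_equal(a$support_count, 1L)
  expect_true(a$confirmed)
  b <- calls[calls$gene_id == "B", ]
  expect_equal(b$support_count, 3L)            # 130.0 counts (inclusive)
  cc <- calls[calls$gene_id == "C", ]
  expect_true(cc$confirmed)
  expect_equal(cc$route, "per_cell")           # rescued by the per-cell metric
  expect_equal(cc$support_raw, 0L)
  d <- calls[calls$gene_id == "D", ]
  expect_false(d$confirmed)

  expect_warning(
    confirm_deconvolution(tbl, genes = c("A", "B", "C", "D", "E")),
    class = "nrf2screen_missing_entity")
})

test_that("support stratification tallies confirmed genes at 1, 2 and 3 siRNAs", {
  calls <- tibble::tibble(gene_id = c("A", "B", "C", "D", "E"),
                          support_count = c(1L, 1L, 2L, 3L, 2L),
                          confirmed = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(stratify_support(calls), c("1" = 2L, "2" = 1L, "3" = 1L))
  expect_equal(stratify_support(calls[0, ]), c("1" = 0L, "2" = 0L, "3" = 0L))
})

test_that("hit sets are monotone in the threshold", {
  set.seed(97)
  for (i in 1:25) {
    tbl <- make_entity_tbl(runif(30, 80, 170), runif(30, 80, 170),
                           gene_id = rep(sprintf("g%02d", 1:10), each = 3),
                           entity_id = sprintf("s%02d", 1:30))
    lo <- confirm_deconvolution(tbl, threshold_pct = 120)
    hi <- confirm_deconvolution(tbl, threshold_pct = 140)
    expect_true(all(hi$gene_id[hi$confirmed] %in% lo$gene_id[lo$confirmed]))
    # per-route support counts never grow when the threshold rises (the
    # blended support_count may switch route, so it is compared per route)
    m <- match(hi$gene_id, lo$gene_id)
    expect_true(all(hi$support_raw <= lo$support_raw[m]))
    expect_true(all(hi$support_per_cell <= lo$support_per_cell[m]))
  }
})

test_that("pool-vs-single comparison matches a hand-computed Welch t-test", {
  pool <- c(300, 310, 305)
  singles <- tibble::tibble(
    sirna_id = rep(c("si1", "si2", "si3"), each = 3),
    value = c(150, 155, 145, 120, 118, 122, 90, 95, 100))
  res <- compare_pool_vs_single(pool, singles, gene_id = "G1")
  expect_equal(res$best_sirna_id, "si1")
  expect_equal(res$verdict, "pool_stronger")

  # independent oracle: Welch statistic from the closed form
  x <- pool; y <- c(150, 155, 145)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  tstat <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_oracle <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  weak <- compare_pool_vs_single(c(110, 112, 108), singles |>
    dplyr::mutate(value = value + 60))
  expect_equal(weak$verdict, "pool_weaker")

  same <- compare_pool_vs_single(c(100, 101, 99),
                                 tibble::tibble(sirna_id = "si1",
                                                value = c(100, 101, 99)))
  expect_equal(same$verdict, "indistinguishable")

  few <- compare_pool_vs_single(c(100), singles)
  expect_true(few$flagged)
  expect_equal(few$verdict, "indistinguishable")

  # tie on the mean: lower siRNA identifier wins
  tie <- compare_pool_vs_single(
    c(100, 100), tibble::tibble(sirna_id = rep(c("si9", "si2"), each = 2),
                                value = c(120, 121, 121, 120)))
  expect_equal(tie$best_sirna_id, "si2")
})
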