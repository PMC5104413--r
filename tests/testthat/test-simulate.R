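small_cfg <- function(n_genes = 120, n_source_plates = 1,
                      n_planted_activators = 8,
                      n_proliferation_effects = 4, ...) {
  sim_config(n_genes = n_genes, n_source_plates = n_source_plates,
             n_planted_activators = n_planted_activators,
             n_proliferation_effects = n_proliferation_effects, ...)
}

test_that("the generator is deterministic given a seed", {
  a <- simulate_primary_screen(small_cfg(), seed = 5)
  b <- simulate_primary_screen(small_cfg(), seed = 5)
  expect_identical(a$measurements, b$measurements)
  expect_identical(tibble::as_tibble(a$layout), tibble::as_tibble(b$layout))
  expect_identical(a$truth, b$truth)
  c <- simulate_primary_screen(small_cfg(), seed = 6)
  expect_false(identical(a$measurements$value, c$measurements$value))

  d1 <- simulate_deconvolution(small_cfg(), a$truth$gene$gene_id[1:10],
                               a$truth$sirna, seed = 5)
  d2 <- simulate_deconvolution(small_cfg(), a$truth$gene$gene_id[1:10],
                               a$truth$sirna, seed = 5)
  expect_identical(d1$measurements, d2$measurements)

  q1 <- simulate_qpcr(small_cfg(), tibble::tibble(sample_id = "s1",
                                                  expression_fold = 2), seed = 5)
  q2 <- simulate_qpcr(small_cfg(), tibble::tibble(sample_id = "s1",
                                                  expression_fold = 2), seed = 5)
  expect_identical(q1$cts, q2$cts)
})

test_that("a noise-free null screen normalizes every test well to exactly 100%", {
  cfg <- small_cfg(noise_cv = 0, field_cv = 0, condensation_cv = 0,
                   qc_fail_rate = 0,
                   n_planted_activators = 0, n_proliferation_effects = 0)
  sim <- simulate_primary_screen(cfg, seed = 2)
  nw <- intraplate_normalize(aggregate_image_fields(sim$measurements),
                             sim$layout)
  test_wells <- nw[nw$role == "test", ]
  expect_true(all(abs(test_wells$value_pct - 100) < 1e-9))

  # plate factors cancelled exactly even though raw plates differ in scale
  raw <- sim$measurements[sim$measurements$channel == "luminescence", ]
  scale_by_rep <- tapply(raw$value, raw$replicate, mean)
  expect_gt(diff(range(scale_by_rep)) / mean(scale_by_rep), 0.01)
})

test_that("planted effects pass through the pipeline exactly when noise is off", {
  cfg <- small_cfg(noise_cv = 0, field_cv = 0, qc_fail_rate = 0,
                   n_planted_activators = 5, activator_fold_range = c(3, 3),
                   n_proliferation_effects = 0)
  sim <- simulate_primary_screen(cfg, seed = 3)
  et <- summarise_screen(sim$measurements, sim$layout)
  planted <- sim$truth$gene$gene_id[sim$truth$gene$activation_fold > 1]
  vals <- et$luc_mean_pct[et$gene_id %in% planted]
  expect_true(all(abs(vals - 300) < 1e-9))

  # positive controls carry their written effects
  expect_equal(et$luc_mean_pct[et$entity_id == "KEAP1_pool"], 300)
  expect_equal(et$luc_mean_pct[et$entity_id == "CUL3_pool"], 116)
  expect_equal(et$nuc_mean_pct[et$entity_id == "PLK1_pool"], 50)
})

test_that("deconvolution ground truth drives support counts and off-target rates", {
  cfg <- small_cfg(noise_cv = 0, field_cv = 0, qc_fail_rate = 0,
                   off_target_rate = 0, n_planted_activators = 10,
                   n_effective_probs = c(0, 0, 1))  # all siRNAs effective
  sim <- simulate_primary_screen(cfg, seed = 4)
  truth <- sim$truth
  planted <- truth$gene$gene_id[truth$gene$activation_fold > 1]
  nulls <- setdiff(truth$gene$gene_id, planted)[1:20]

  deco <- simulate_deconvolution(cfg, c(planted, nulls), truth$sirna, seed = 4)
  tbl <- summarise_screen(deco$measurements, deco$layout)
  calls <- confirm_deconvolution(tbl, pass_number = 2)
  expect_true(all(calls$support_count[calls$gene_id %in% planted] == 3L))
  expect_true(all(calls$confirmed[calls$gene_id %in% planted]))
  # no off-target route: false positives stay at support 0, unconfirmed
  expect_true(all(!calls$confirmed[calls$gene_id %in% nulls]))
  expect_true(all(calls$support_count[calls$gene_id %in% nulls] == 0L))

  # off-target singles appear at the configured binomial rate
  cfg2 <- small_cfg(n_genes = 300, off_target_rate = 0.05,
                    n_planted_activators = 0, n_proliferation_effects = 0)
  sim2 <- simulate_primary_screen(cfg2, seed = 8)
  deco2 <- simulate_deconvolution(cfg2, sim2$truth$gene$gene_id[1:200],
                                  sim2$truth$sirna, seed = 8)
  n_off <- sum(deco2$truth$off_target)
  expect_gt(n_off, stats::qbinom(0.0005, 600, 0.05))
  expect_lt(n_off, stats::qbinom(0.9995, 600, 0.05))
})

test_that("qPCR simulation writes exact standards and recoverable folds", {
  cfg <- small_cfg()
  q <- simulate_qpcr(cfg, tibble::tibble(sample_id = "kd",
                                         expression_fold = 2.75), seed = 9)
  # standards on the exact 100%-efficiency line
  fit <- fit_standard_curve(q$standards)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(fit$efficiency, 1.0, tolerance = 1e-12)

  # doubling the input lowers Ct by one cycle on this line
  expect_equal(diff(q$standards$ct[1:2]),
               -1 / log10(2) * log10(10))  # one decade step
  ct_at <- function(qty) cfg$standard_intercept - log10(qty) / log10(2)
  expect_equal(ct_at(200) - ct_at(100), -1, tolerance = 1e-12)

  # noise-free fold recovery through the analysis path
  cfg0 <- small_cfg(ct_noise_sd = 0)
  q0 <- simulate_qpcr(cfg0, tibble::tibble(sample_id = "kd",
                                           expression_fold = 2.75), seed = 9)
  curve <- fit_standard_curve(q0$standards)
  quant <- q0$cts |>
    dplyr::mutate(quantity = suppressMessages(relative_quantity(ct, curve)))
  res <- normalized_fold_change(
    quant[quant$gene == "target", c("sample_id", "replicate", "quantity")],
    quant[quant$gene == "housekeeping", c("sample_id", "replicate", "quantity")],
    q0$control_samples)
  expect_equal(res$fold_vs_control[res$sample_id == "kd"], 2.75,
               tolerance = 1e-9)
})

test_that("survival simulation exercises the validity gate and repeat rule", {
  cfg <- small_cfg(survival_invalid_rate = 1,
                   survival_invalid_fold_range = c(2.5, 2.5),
                   survival_max_plates = 4, survival_noise_cv = 0.02)
  sv <- simulate_survival(cfg, tibble::tibble(sirna_id = "siA", gene_id = "gA",
                                              protection_fold = 1), seed = 3)
  v <- plate_validity(sv$atp, sv$layout)
  expect_true(all(!v$valid))  # keap1 planted at 2.5: every plate invalid

  cfg2 <- small_cfg(survival_invalid_rate = 0.5)
  sv2 <- simulate_survival(cfg2, tibble::tibble(sirna_id = "siA", gene_id = "gA",
                                                protection_fold = 1), seed = 31)
  v2 <- plate_validity(sv2$atp, sv2$layout)
  # plates were acquired until at least 4 passed (or the cap was hit)
  expect_true(sum(v2$valid) >= 4 || nrow(v2) == cfg2$survival_max_plates)
})
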