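## Synthetic screen generator with known ground truth.
##
## Emulates the screen's geometry (4995 gene pools randomly distributed
## over 19 source plates in 384-well format; intra-plate control
## quadruplicates; six replicate experimental plates per source plate,
## three lysed for luciferase and three imaged) and its noise profile
## (multiplicative log-normal well noise calibrated so ~80% of replicate
## CVs fall below 10%), plus deconvolution, qPCR and CSE-survival
## follow-ups.  Everything is deterministic given one seed; sub-simulations
## derive child seeds from it.

#' Simulation configuration
#'
#' Defaults encode the screen's study conditions; see the methods vignette
#' for the rationale behind values the screen itself does not pin down.
#'
#' @param n_genes number of test-siRNA pools (one gene each).
#' @param n_source_plates 384-well source plates the pools are spread over.
#' @param replicates_luciferase,replicates_imaging replicate experimental
#'   plates per source plate and assay arm.
#' @param noise_cv well-level multiplicative log-normal noise (CV as a
#'   fraction).  The default 0.0757 places ~80% of 3-replicate CVs below
#'   0.10 (`0.1 * sqrt(2 / qchisq(0.8, 2))`, corrected for the noise of the
#'   12-well negative-control mean).
#' @param n_planted_activators,activator_fold_range,n_effective_probs
#'   number of planted true activators, their fold-effect range (uniform)
#'   and the probabilities that 1, 2 or 3 of a gene's siRNAs carry the
#'   effect.
#' @param n_proliferation_effects,proliferation_fold_range planted
#'   proliferation suppressors (nuclei fold < 1); whole-well luciferase
#'   scales with the same factor, so per-cell confounding arises naturally.
#' @param off_target_rate probability that a non-effective single siRNA
#'   activates the reporter off-target.
#' @param off_target_fold_range fold range of off-target activation.
#' @param keap1_fold,cul3_fold,plk1_nuclei_fold positive-control effects:
#'   KEAP1 pool ~3x luciferase, CUL3 ~1.16x, PLK1 halves nuclei counts.
#' @param baseline_rlu,baseline_nuclei,baseline_condensation baseline
#'   luminescence per well, nuclei per image field and condensed-chromatin
#'   fraction.
#' @param condensation_cv multiplicative noise on the condensation
#'   fraction (apoptosis indicator; carried but not thresholded).
#' @param field_cv extra per-field log-normal jitter for imaging channels.
#' @param plate_factor_range multiplicative plate-to-plate factor range;
#'   intra-plate normalization must remove it.
#' @param qc_fail_rate probability an image field fails upstream QC.
#' @param ct_noise_sd,qpcr_replicates,standard_quantities,standard_intercept,
#'   qpcr_base_quantity qPCR follow-up: Gaussian Ct noise (cycles),
#'   replicate wells per sample, dilution series, curve intercept and the
#'   control sample's relative input on the exact 100%-efficiency line
#'   (slope `-1/log10(2)`).
#' @param survival_baseline_atp,survival_noise_cv,survival_keap1_fold,
#'   survival_invalid_rate,survival_invalid_fold_range,survival_n_plates,
#'   survival_min_valid,survival_max_plates,survival_tests_per_plate CSE
#'   survival follow-up: baseline ATP signal, well noise, planted KEAP1
#'   protection, the rate at which plates are drawn with a sub-threshold
#'   KEAP1 response (exercising the validity gate), initial biological
#'   replicate plates per batch, and the repeat-until rule: batches keep
#'   acquiring plates (up to `survival_max_plates`) until at least
#'   `survival_min_valid` pass the realized 3-fold KEAP1 gate, mirroring
#'   how underpowered experiments are re-run at the bench.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 4995,
                       n_source_plates = 19,
                       replicates_luciferase = 3,
                       replicates_imaging = 3,
                       noise_cv = 0.0757,
                       n_planted_activators = 50,
                       activator_fold_range = c(1.3, 3),
                       n_effective_probs = c(0.6, 0.3, 0.1),
                       n_proliferation_effects = 25,
                       proliferation_fold_range = c(0.5, 0.8),
                       off_target_rate = 0.05,
                       off_target_fold_range = c(1.3, 2),
                       keap1_fold = 3,
                       cul3_fold = 1.16,
                       plk1_nuclei_fold = 0.5,
                       baseline_rlu = 2e5,
                       baseline_nuclei = 800,
                       baseline_condensation = 0.04,
                       condensation_cv = 0.2,
                       field_cv = 0.035,
                       plate_factor_range = c(0.7, 1.3),
                       qc_fail_rate = 0.002,
                       ct_noise_sd = 0.1,
                       qpcr_replicates = 3,
                       standard_quantities = 10^(0:4),
                       standard_intercept = 35,
                       qpcr_base_quantity = 100,
                       survival_baseline_atp = 5e4,
                       survival_noise_cv = 0.10,
                       survival_keap1_fold = 4,
                       survival_invalid_rate = 0.2,
                       survival_invalid_fold_range = c(2, 2.9),
                       survival_n_plates = 6,
                       survival_min_valid = 4,
                       survival_max_plates = 12,
                       survival_tests_per_plate = 36) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$n_source_plates >= 1,
            cfg$noise_cv >= 0, cfg$off_target_rate >= 0,
            cfg$off_target_rate <= 1, cfg$keap1_fold > 0,
            all(cfg$activator_fold_range > 0),
            abs(sum(cfg$n_effective_probs) - 1) < 1e-9,
            cfg$survival_invalid_rate >= 0, cfg$survival_invalid_rate <= 1)
  structure(cfg, class = "sim_config")
}

## mean-one multiplicative log-normal noise: E[factor] = 1, CV = cv
lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

runif_range <- function(n, range) runif(n, range[1], range[2])

## fixed control architecture of a 384-well screening source plate:
## 3 negative pools x 4, KEAP1/CUL3/PLK1 x 4, 4 reagent-only wells
screen_control_wells <- function() {
  col1 <- paste0(LETTERS[1:16], 1)
  col24 <- paste0(LETTERS[1:16], 24)
  tibble::tibble(
    well = c(col1[1:12], col1[13:16], col24[1:4], col24[5:8], col24[9:12]),
    role = c(rep("neg_control", 12), rep("keap1_control", 4),
             rep("cul3_control", 4), rep("plk1_control", 4),
             rep("reagent_only", 4)),
    entity_id = c(paste0("negpool_", rep(1:3, each = 4)),
                  rep("KEAP1_pool", 4), rep("CUL3_pool", 4),
                  rep("PLK1_pool", 4), rep("reagent", 4)),
    gene_id = c(rep(NA_character_, 12), rep("KEAP1", 4), rep("CUL3", 4),
                rep("PLK1", 4), rep(NA_character_, 4)),
    pool_index = c(rep(1:3, each = 4), rep(NA_integer_, 16)))
}

## draw the planted ground truth for a primary screen
draw_truth <- function(config, seed) {
  set.seed(child_seed(seed, "truth"))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  act_idx <- sample(config$n_genes, min(config$n_planted_activators, config$n_genes))
  act_fold <- runif_range(length(act_idx), config$activator_fold_range)
  n_eff <- sample(1:3, length(act_idx), replace = TRUE,
                  prob = config$n_effective_probs)
  prolif_pool <- setdiff(seq_len(config$n_genes), act_idx)
  prol_idx <- sample(prolif_pool,
                     min(config$n_proliferation_effects, length(prolif_pool)))
  prol_fold <- runif_range(length(prol_idx), config$proliferation_fold_range)

  truth <- tibble::tibble(
    gene_id = genes,
    activation_fold = 1,
    n_effective_sirnas = 0L,
    proliferation_fold = 1)
  truth$activation_fold[act_idx] <- act_fold
  truth$n_effective_sirnas[act_idx] <- n_eff
  truth$proliferation_fold[prol_idx] <- prol_fold

  ## siRNA-level truth: which of the three constituents carries the effect
  sirna <- tidyr::expand_grid(gene_id = genes, sirna_index = 1:3) |>
    dplyr::mutate(sirna_id = paste0(.data$gene_id, "_si", .data$sirna_index))
  eff <- unlist(lapply(seq_len(config$n_genes), function(i) {
    k <- truth$n_effective_sirnas[i]
    out <- rep(FALSE, 3)
    if (k > 0) out[sample(3, k)] <- TRUE
    out
  }))
  sirna$effective <- eff
  sirna <- dplyr::left_join(
    sirna,
    truth[, c("gene_id", "activation_fold", "proliferation_fold")],
    by = "gene_id")
  list(gene = truth, sirna = sirna)
}

## distribute entities over test wells of source plates; returns layouts
place_entities <- function(entities, n_plates, format, seed, tag,
                           plate_prefix = "SP") {
  ctrl <- if (format == 384) {
    screen_control_wells()
  } else {
    ## 96-well follow-up plate: 8 negative-control and 4 KEAP1 wells
    w <- well_addresses(96)
    tibble::tibble(
      well = w[1:12],
      role = c(rep("neg_control", 8), rep("keap1_control", 4)),
      entity_id = c(paste0("negpool_", rep(1:3, length.out = 8)),
                    rep("KEAP1_pool", 4)),
      gene_id = c(rep(NA_character_, 8), rep("KEAP1", 4)),
      pool_index = c(rep(1:3, length.out = 8), rep(NA_integer_, 4)))
  }
  test_wells <- setdiff(well_addresses(format), ctrl$well)
  capacity <- n_plates * length(test_wells)
  if (nrow(entities) > capacity) {
    stop_validation(sprintf("%d entities exceed capacity %d of %d plate(s)",
                            nrow(entities), capacity, n_plates))
  }
  set.seed(child_seed(seed, tag))
  slot <- sample(capacity, nrow(entities))
  plate_no <- (slot - 1L) %/% length(test_wells) + 1L
  well_no <- (slot - 1L) %% length(test_wells) + 1L

  test_rows <- tibble::tibble(
    plate_id = sprintf("%s%02d", plate_prefix, plate_no),
    well = test_wells[well_no],
    role = "test",
    entity_id = entities$entity_id,
    gene_id = entities$gene_id,
    pool_index = NA_integer_)
  ctrl_rows <- tidyr::expand_grid(
    plate_id = sprintf("%s%02d", plate_prefix, seq_len(n_plates)),
    ctrl) |>
    dplyr::select("plate_id", "well", "role", "entity_id", "gene_id", "pool_index")
  all_wells <- tidyr::expand_grid(
    plate_id = sprintf("%s%02d", plate_prefix, seq_len(n_plates)),
    well = well_addresses(format))
  empty_rows <- all_wells |>
    dplyr::anti_join(dplyr::bind_rows(test_rows[, c("plate_id", "well")],
                                      ctrl_rows[, c("plate_id", "well")]),
                     by = c("plate_id", "well")) |>
    dplyr::mutate(role = "empty", entity_id = NA_character_,
                  gene_id = NA_character_, pool_index = NA_integer_)
  layout <- dplyr::bind_rows(test_rows, ctrl_rows, empty_rows) |>
    dplyr::arrange(.data$plate_id, .data$well)
  plate_layout(layout, format = format,
               screening = format == 384)
}

## per-entity expected effects on the two assay arms
effect_table <- function(layout, luci_fold_by_entity, nuclei_fold_by_entity) {
  occupied <- layout[layout$role != "empty", ]
  occupied$luci_fold <- luci_fold_by_entity[occupied$entity_id]
  occupied$nuclei_fold <- nuclei_fold_by_entity[occupied$entity_id]
  occupied$luci_fold[is.na(occupied$luci_fold)] <- 1
  occupied$nuclei_fold[is.na(occupied$nuclei_fold)] <- 1
  occupied
}

## emit luciferase + imaging measurement rows for a set of laid-out wells
emit_measurements <- function(wells, config, seed, tag) {
  plates <- unique(wells$plate_id)

  ## luciferase arm: whole-well luminescence scales with activation and
  ## with cell number, so the raw fold is activation x proliferation
  set.seed(child_seed(seed, paste0(tag, "_luci")))
  luci <- tidyr::expand_grid(replicate = seq_len(config$replicates_luciferase),
                             wells)
  pf <- runif_range(length(plates) * config$replicates_luciferase,
                    config$plate_factor_range)
  names(pf) <- paste0(rep(plates, times = config$replicates_luciferase), "_",
                      rep(seq_len(config$replicates_luciferase), each = length(plates)))
  luci$value <- config$baseline_rlu *
    pf[paste0(luci$plate_id, "_", luci$replicate)] *
    luci$luci_fold * luci$nuclei_fold *
    lnoise(nrow(luci), config$noise_cv)
  luci_rows <- tibble::tibble(
    plate_id = luci$plate_id, well = luci$well, channel = "luminescence",
    replicate = luci$replicate, field_index = NA_integer_,
    value = luci$value, qc_pass = TRUE)

  ## imaging arm: well-level latent nuclei count, then 4 jittered fields
  set.seed(child_seed(seed, paste0(tag, "_img")))
  img <- tidyr::expand_grid(replicate = seq_len(config$replicates_imaging),
                            wells)
  pf_i <- runif_range(length(plates) * config$replicates_imaging,
                      config$plate_factor_range)
  names(pf_i) <- paste0(rep(plates, times = config$replicates_imaging), "_",
                        rep(seq_len(config$replicates_imaging), each = length(plates)))
  img$latent <- config$baseline_nuclei *
    pf_i[paste0(img$plate_id, "_", img$replicate)] *
    img$nuclei_fold * lnoise(nrow(img), config$noise_cv)
  fields <- tidyr::expand_grid(img, field_index = 1:4)
  fields$nuclei <- fields$latent * lnoise(nrow(fields), config$field_cv)
  fields$condensation <- pmin(1, pmax(0, config$baseline_condensation *
                                        lnoise(nrow(fields),
                                               config$condensation_cv)))
  fields$qc_pass <- runif(nrow(fields)) >= config$qc_fail_rate
  img_rows <- dplyr::bind_rows(
    tibble::tibble(plate_id = fields$plate_id, well = fields$well,
                   channel = "nuclei_count", replicate = fields$replicate,
                   field_index = fields$field_index, value = fields$nuclei,
                   qc_pass = fields$qc_pass),
    tibble::tibble(plate_id = fields$plate_id, well = fields$well,
                   channel = "condensation_fraction", replicate = fields$replicate,
                   field_index = fields$field_index, value = fields$condensation,
                   qc_pass = fields$qc_pass))
  dplyr::bind_rows(luci_rows, img_rows)
}

#' Simulate the primary pooled-siRNA screen
#'
#' @param config a [sim_config()].
#' @param seed integer seed; all randomness derives from it.
#' @return List with `layout` (a [plate_layout()] covering all source
#'   plates), `measurements` (long measurement tibble, both assay arms) and
#'   `truth` (list of per-gene and per-siRNA ground-truth tibbles).
#' @export
simulate_primary_screen <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  truth <- draw_truth(config, seed)
  pools <- tibble::tibble(entity_id = paste0(truth$gene$gene_id, "_pool"),
                          gene_id = truth$gene$gene_id)
  layout <- place_entities(pools, config$n_source_plates, 384, seed,
                           "primary_layout")

  luci_fold <- c(stats::setNames(truth$gene$activation_fold, pools$entity_id),
                 KEAP1_pool = config$keap1_fold, CUL3_pool = config$cul3_fold,
                 PLK1_pool = 1, reagent = 1,
                 negpool_1 = 1, negpool_2 = 1, negpool_3 = 1)
  nuc_fold <- c(stats::setNames(truth$gene$proliferation_fold, pools$entity_id),
                KEAP1_pool = 1, CUL3_pool = 1,
                PLK1_pool = config$plk1_nuclei_fold, reagent = 1,
                negpool_1 = 1, negpool_2 = 1, negpool_3 = 1)
  wells <- effect_table(layout, luci_fold, nuc_fold)
  measurements <- emit_measurements(wells, config, seed, "primary")
  list(layout = layout, measurements = measurements, truth = truth)
}

#' Simulate the single-siRNA deconvolution follow-up
#'
#' Each candidate gene contributes its three constituent siRNAs; effective
#' siRNAs (per the primary ground truth) carry the gene's activation fold,
#' non-effective siRNAs activate off-target with probability
#' `off_target_rate`.  The same generator serves the 384-well pass 2 and
#' the 96-well pass 3 via `format`.
#'
#' @param config a [sim_config()].
#' @param candidates character vector of candidate gene ids.
#' @param truth_sirna per-siRNA ground-truth tibble from
#'   [simulate_primary_screen()] (`$truth$sirna`).
#' @param seed integer seed.
#' @param format 384 (pass 2) or 96 (pass 3).
#' @return List with `layout`, `measurements` and `truth` (per-siRNA tibble
#'   with realized folds, including off-target draws).
#' @export
simulate_deconvolution <- function(config, candidates, truth_sirna, seed = 1,
                                   format = 384) {
  dat <- truth_sirna[truth_sirna$gene_id %in% candidates, ]
  if (nrow(dat) == 0) stop_validation("no candidate siRNAs to simulate")
  set.seed(child_seed(seed, paste0("deconv_offtarget_", format)))
  off <- !dat$effective &
    runif(nrow(dat)) < config$off_target_rate
  dat$realized_fold <- ifelse(dat$effective, dat$activation_fold, 1)
  dat$realized_fold[off] <- runif_range(sum(off), config$off_target_fold_range)
  dat$off_target <- off
  dat$realized_nuclei_fold <- ifelse(dat$effective, dat$proliferation_fold, 1)

  singles <- tibble::tibble(entity_id = dat$sirna_id, gene_id = dat$gene_id)
  n_ctrl_wells <- if (format == 384) 28L else 12L
  capacity_per_plate <- (if (format == 384) 384L else 96L) - n_ctrl_wells
  n_plates <- ceiling(nrow(singles) / capacity_per_plate)
  layout <- place_entities(singles, n_plates, format, seed,
                           paste0("deconv_layout_", format),
                           plate_prefix = if (format == 384) "DP" else "TP")

  luci_fold <- c(stats::setNames(dat$realized_fold, dat$sirna_id),
                 KEAP1_pool = config$keap1_fold, CUL3_pool = config$cul3_fold,
                 PLK1_pool = 1, reagent = 1,
                 negpool_1 = 1, negpool_2 = 1, negpool_3 = 1)
  nuc_fold <- c(stats::setNames(dat$realized_nuclei_fold, dat$sirna_id),
                KEAP1_pool = 1, CUL3_pool = 1,
                PLK1_pool = config$plk1_nuclei_fold, reagent = 1,
                negpool_1 = 1, negpool_2 = 1, negpool_3 = 1)
  wells <- effect_table(layout, luci_fold, nuc_fold)
  measurements <- emit_measurements(wells, config, seed,
                                    paste0("deconv_", format))
  list(layout = layout, measurements = measurements, truth = dat)
}

#' Simulate a qPCR confirmation experiment
#'
#' Standards lie on an exact 100%-efficiency line (slope `-1/log10(2)`);
#' sample Cts are back-computed from planted normalized-expression folds
#' plus Gaussian Ct noise, and housekeeping Cts are constant up to noise.
#'
#' @param config a [sim_config()].
#' @param samples tibble `sample_id, expression_fold` (planted fold versus
#'   control); control samples `ctrl_1..ctrl_3` at fold 1 are added
#'   automatically.
#' @param seed integer seed.
#' @return List with `standards` (`quantity, ct`), `cts`
#'   (`sample_id, gene, replicate, ct`), `control_samples` and `truth`.
#' @export
simulate_qpcr <- function(config, samples, seed = 1) {
  slope <- -1 / log10(2)
  controls <- tibble::tibble(sample_id = paste0("ctrl_", 1:3),
                             expression_fold = 1)
  all_samples <- dplyr::bind_rows(controls, samples)
  standards <- tibble::tibble(
    quantity = config$standard_quantities,
    ct = config$standard_intercept + slope * log10(config$standard_quantities))

  set.seed(child_seed(seed, "qpcr"))
  grid <- tidyr::expand_grid(all_samples,
                             replicate = seq_len(config$qpcr_replicates))
  n <- nrow(grid)
  cts <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = grid$sample_id, gene = "target", replicate = grid$replicate,
      ct = config$standard_intercept +
        slope * log10(config$qpcr_base_quantity * grid$expression_fold) +
        rnorm(n, 0, config$ct_noise_sd)),
    tibble::tibble(
      sample_id = grid$sample_id, gene = "housekeeping", replicate = grid$replicate,
      ct = config$standard_intercept +
        slope * log10(config$qpcr_base_quantity) +
        rnorm(n, 0, config$ct_noise_sd)))
  list(standards = standards, cts = cts,
       control_samples = controls$sample_id, truth = all_samples)
}

#' Simulate CSE-survival follow-up plates
#'
#' 96-well plates with 16 siControl, 4 siKEAP1 and duplicate reagent-only
#' wells plus intra-plate duplicates of each test siRNA; `survival_n_plates`
#' biological replicate plates per batch.  A fraction of plates is drawn
#' with a sub-threshold KEAP1 response to exercise the validity gate.
#'
#' @param config a [sim_config()].
#' @param sirnas tibble `sirna_id, gene_id, protection_fold`.
#' @param seed integer seed.
#' @return List with `layout`, `atp` (well-level ATP tibble: `plate_id,
#'   well, value`), `truth` and `plate_truth` (per-plate planted KEAP1
#'   fold).
#' @export
simulate_survival <- function(config, sirnas, seed = 1) {
  per_plate <- config$survival_tests_per_plate
  batches <- split(seq_len(nrow(sirnas)),
                   (seq_len(nrow(sirnas)) - 1) %/% per_plate)
  w96 <- well_addresses(96)
  set.seed(child_seed(seed, "survival"))

  layouts <- list(); atps <- list(); plate_truths <- list()
  for (b in seq_along(batches)) {
    batch <- sirnas[batches[[b]], ]
    n_test_wells <- 2L * nrow(batch)
    ctrl <- tibble::tibble(
      well = w96[1:22],
      role = c(rep("neg_control", 16), rep("keap1_control", 4),
               rep("reagent_only", 2)),
      entity_id = c(rep("siControl", 16), rep("siKEAP1", 4), rep("reagent", 2)),
      gene_id = c(rep(NA_character_, 16), rep("KEAP1", 4), rep(NA_character_, 2)))
    test <- tibble::tibble(
      well = w96[22 + seq_len(n_test_wells)],
      role = "test",
      entity_id = rep(batch$sirna_id, each = 2),
      gene_id = rep(batch$gene_id, each = 2))
    empty <- tibble::tibble(
      well = setdiff(w96, c(ctrl$well, test$well)),
      role = "empty", entity_id = NA_character_, gene_id = NA_character_)
    base_layout <- dplyr::bind_rows(ctrl, test, empty)

    ## acquire plates until enough pass the realized 3-fold KEAP1 gate
    ## (experiments are repeated until >= survival_min_valid replicates)
    p <- 0L; n_valid <- 0L
    while (p < config$survival_max_plates &&
           (p < config$survival_n_plates ||
            n_valid < config$survival_min_valid)) {
      p <- p + 1L
      pid <- sprintf("CSE_B%02d_P%02d", b, p)
      keap1_eff <- if (runif(1) < config$survival_invalid_rate) {
        runif_range(1, config$survival_invalid_fold_range)
      } else {
        config$survival_keap1_fold
      }
      lay <- base_layout |>
        dplyr::mutate(plate_id = pid, pool_index = NA_integer_)
      fold <- c(siControl = 1, siKEAP1 = keap1_eff, reagent = 1,
                stats::setNames(batch$protection_fold, batch$sirna_id))
      occ <- lay[lay$role != "empty", ]
      pf <- runif_range(1, config$plate_factor_range)
      occ$value <- config$survival_baseline_atp * pf *
        fold[occ$entity_id] * lnoise(nrow(occ), config$survival_noise_cv)
      realized <- mean(occ$value[occ$role == "keap1_control"]) /
        mean(occ$value[occ$role == "neg_control"])
      if (realized >= 3) n_valid <- n_valid + 1L
      layouts[[pid]] <- lay
      atps[[pid]] <- occ[, c("plate_id", "well", "value")]
      plate_truths[[pid]] <- tibble::tibble(plate_id = pid,
                                            planted_keap1_fold = keap1_eff)
    }
  }
  layout <- plate_layout(dplyr::bind_rows(layouts), format = 96,
                         screening = FALSE)
  list(layout = layout,
       atp = dplyr::bind_rows(atps),
       truth = sirnas,
       plate_truth = dplyr::bind_rows(plate_truths))
}
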