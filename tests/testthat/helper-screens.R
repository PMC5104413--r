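# Fixture builders: small screening plates assembled in code.

# control block of a 384-well screening plate (12 neg + 3 x 4 positive + 4
# reagent-only wells), same architecture the simulator uses
ctrl_block_384 <- function() {
  tibble::tibble(
    well = c(paste0(LETTERS[1:16], 1), paste0(LETTERS[1:12], 24)),
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

# full valid 384-well screening layout with n_test test pools
make_screen_layout <- function(n_test = 8, plate_id = "P1") {
  ctrl <- ctrl_block_384()
  test_wells <- setdiff(well_addresses(384), ctrl$well)
  stopifnot(n_test <= length(test_wells))
  test <- tibble::tibble(
    well = test_wells[seq_len(n_test)],
    role = "test",
    entity_id = sprintf("G%03d_pool", seq_len(n_test)),
    gene_id = sprintf("G%03d", seq_len(n_test)),
    pool_index = NA_integer_)
  empty <- tibble::tibble(
    well = setdiff(test_wells, test$well),
    role = "empty", entity_id = NA_character_, gene_id = NA_character_,
    pool_index = NA_integer_)
  df <- dplyr::bind_rows(ctrl, test, empty)
  df$plate_id <- plate_id
  plate_layout(df, format = 384)
}

# well-level luminescence rows for a layout; values named by entity_id,
# unnamed entities get `default`
make_luci_wells <- function(layout, values = c(), default = 1000,
                            replicate = 1L) {
  occ <- layout[layout$role != "empty", ]
  v <- if (length(values) > 0) unname(values[occ$entity_id]) else
    rep(NA_real_, nrow(occ))
  v[is.na(v)] <- default
  tibble::tibble(plate_id = occ$plate_id, well = occ$well,
                 channel = "luminescence", replicate = replicate,
                 value = unname(v), excluded = FALSE)
}

# entity summary table in the wide (per-cell) form used by hit selection
make_entity_tbl <- function(luc, per_cell = luc, role = "test",
                            gene_id = sprintf("G%03d", seq_along(luc)),
                            entity_id = paste0(gene_id, "_e")) {
  tibble::tibble(
    entity_id = entity_id, gene_id = gene_id, role = role,
    luc_mean_pct = luc, luc_sd_pct = NA_real_, luc_cv = NA_real_,
    luc_n = 3L, nuc_mean_pct = 100, nuc_sd_pct = NA_real_,
    nuc_cv = NA_real_, nuc_n = 3L,
    per_cell_pct = per_cell, per_cell_flag = is.na(per_cell))
}

# brute-force pass-1 filter: explicit loops, the independent oracle
brute_pass1 <- function(entity_tbl, sd_mult = 2) {
  pools <- entity_tbl[entity_tbl$role == "test", ]
  thr_raw <- mean(pools$luc_mean_pct) + sd_mult * sd(pools$luc_mean_pct)
  pc <- pools$per_cell_pct[!is.na(pools$per_cell_pct)]
  thr_pc <- mean(pc) + sd_mult * sd(pc)
  raw <- character(0); pcell <- character(0)
  for (i in seq_len(nrow(pools))) {
    if (!is.na(pools$luc_mean_pct[i]) && pools$luc_mean_pct[i] > thr_raw) {
      raw <- c(raw, pools$gene_id[i])
    }
    if (!is.na(pools$per_cell_pct[i]) && pools$per_cell_pct[i] > thr_pc) {
      pcell <- c(pcell, pools$gene_id[i])
    }
  }
  list(raw = raw, per_cell = pcell, union = union(raw, pcell),
       overlap = intersect(raw, pcell), thr_raw = thr_raw, thr_pc = thr_pc)
}

# brute-force deconvolution confirmation, one gene at a time
brute_deconv <- function(single_tbl, threshold = 130) {
  genes <- unique(single_tbl$gene_id[single_tbl$role == "test"])
  out <- list()
  for (g in genes) {
    rows <- single_tbl[single_tbl$gene_id == g & single_tbl$role == "test", ]
    s_raw <- 0L; s_pc <- 0L
    for (i in seq_len(nrow(rows))) {
      if (!is.na(rows$luc_mean_pct[i]) && rows$luc_mean_pct[i] >= threshold) {
        s_raw <- s_raw + 1L
      }
      if (!is.na(rows$per_cell_pct[i]) && rows$per_cell_pct[i] >= threshold) {
        s_pc <- s_pc + 1L
      }
    }
    out[[g]] <- data.frame(gene_id = g, support_raw = s_raw,
                           support_per_cell = s_pc,
                           confirmed = s_raw >= 1 || s_pc >= 1)
  }
  do.call(rbind, out)
}
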