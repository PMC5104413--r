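## qPCR standard-curve relative quantification, housekeeping normalization,
## expression hit calling, reporter/expression concordance and Western-blot
## densitometry statistics.

#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = slope * log10(quantity) + intercept` over a
#' dilution series, with amplification efficiency
#' `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle).
#'
#' @param standards data frame with columns `quantity` (relative input
#'   amount) and `ct`.
#' @return Object of class `standard_curve`: list with `slope`,
#'   `intercept`, `efficiency`, `points`.
#' @export
fit_standard_curve <- function(standards) {
  if (!all(c("quantity", "ct") %in% names(standards))) {
    stop_parse("standards need columns 'quantity' and 'ct'")
  }
  dat <- standards[!is.na(standards$quantity) & !is.na(standards$ct), ]
  if (length(unique(dat$quantity)) < 3) {
    stop_validation("a standard curve needs at least 3 distinct dilution points")
  }
  if (any(dat$quantity <= 0)) stop_validation("standard quantities must be > 0")
  lg <- log10(dat$quantity)
  fit <- lm(ct ~ lg, data = data.frame(ct = dat$ct, lg = lg))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ## slopes at numerical zero (flat dilution series) are as unusable as
  ## positive ones
  if (!is.finite(slope) || slope >= -1e-9) {
    stop_validation(sprintf(
      "rejected standard curve: slope %.3g is not negative (Ct must fall as input rises)",
      slope))
  }
  ## mean Ct per dilution should decrease monotonically with quantity
  ord <- tapply(dat$ct, lg, mean)
  if (any(diff(ord[order(as.numeric(names(ord)))]) > 0)) {
    warn("standard Cts are not monotone in dilution",
         class = "nrf2screen_nonmonotone_standards")
  }
  structure(
    list(slope = slope, intercept = intercept,
         efficiency = 10^(-1 / slope) - 1,
         points = tibble::tibble(log10_quantity = lg, ct = dat$ct)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.3f, efficiency %.1f%%\n",
              x$slope, x$intercept, 100 * x$efficiency))
  invisible(x)
}

#' Relative quantity from a Ct value
#'
#' Inverts the fitted standard curve: `q = 10^((ct - intercept) / slope)`.
#' Cts outside the dilution range are extrapolated (message emitted).
#'
#' @param ct numeric Ct value(s).
#' @param curve a [fit_standard_curve()] result.
#' @return Relative quantity (same length as `ct`).
#' @export
relative_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  rng <- range(curve$points$ct)
  outside <- ct < rng[1] | ct > rng[2]
  if (any(outside, na.rm = TRUE)) {
    message(sprintf("%d Ct value(s) outside the standard range [%.2f, %.2f]; extrapolating",
                    sum(outside, na.rm = TRUE), rng[1], rng[2]))
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Housekeeping-normalized expression and fold change versus control
#'
#' Per replicate well, target quantity is divided by the housekeeping
#' quantity of the same sample; per sample, the fold change is the mean
#' normalized expression divided by the mean over all control-sample
#' replicates, with a two-sided t-test (Welch) of the sample's replicate
#' values against the pooled control replicates.
#'
#' @param target data frame `sample_id, replicate, quantity` for the target
#'   gene.
#' @param housekeeping same schema for the housekeeping gene.
#' @param control_samples character vector of `sample_id`s that constitute
#'   the reference (e.g. control-siRNA wells).
#' @return Tibble: `sample_id, normalized_expression, fold_vs_control,
#'   p_value, n_replicates`.
#' @export
normalized_fold_change <- function(target, housekeeping, control_samples) {
  joined <- dplyr::inner_join(
    target |> dplyr::rename(q_target = "quantity"),
    housekeeping |> dplyr::rename(q_hk = "quantity"),
    by = c("sample_id", "replicate"))
  drop <- joined$q_hk <= 0 | is.na(joined$q_hk)
  if (any(drop)) {
    warn(sprintf("dropping %d replicate(s) with zero/missing housekeeping quantity",
                 sum(drop)), class = "nrf2screen_missing_entity")
    joined <- joined[!drop, ]
  }
  joined$norm_expr <- joined$q_target / joined$q_hk
  ctrl <- joined$norm_expr[joined$sample_id %in% control_samples]
  if (length(ctrl) == 0) stop_validation("no control-sample replicates found")
  ctrl_mean <- mean(ctrl)

  joined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      normalized_expression = mean(.data$norm_expr),
      n_replicates = dplyr::n(),
      p_value = if (dplyr::n() >= 2 && length(ctrl) >= 2 &&
                    (sd(.data$norm_expr) > 0 || sd(ctrl) > 0))
        t.test(.data$norm_expr, ctrl)$p.value else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(fold_vs_control = .data$normalized_expression / ctrl_mean) |>
    dplyr::select("sample_id", "normalized_expression", "fold_vs_control",
                  "p_value", "n_replicates")
}

#' qPCR expression hit call
#'
#' A sample (siRNA) is a hit when its fold change is greater than or equal
#' to `fold_threshold` (inclusive) AND the t-test against controls is
#' significant at `alpha`.
#'
#' @param expression_results tibble from [normalized_fold_change()].
#' @param fold_threshold inclusive fold boundary (default 1.30).
#' @param alpha significance level (default 0.05).
#' @return Input with a logical `hit` column added.
#' @export
qpcr_hit_call <- function(expression_results, fold_threshold = 1.30,
                          alpha = 0.05) {
  expression_results |>
    dplyr::mutate(hit = !is.na(.data$fold_vs_control) &
                    !is.na(.data$p_value) &
                    .data$fold_vs_control >= fold_threshold &
                    .data$p_value < alpha)
}

#' Concordance between reporter induction and endogenous expression
#'
#' Pearson correlation of paired log2 ratios (reporter luciferase induction
#' versus normalized target-gene expression), with Spearman reported
#' alongside as a rank-based robustness check.
#'
#' @param luciferase_ratio positive numeric vector (fold or percent scale).
#' @param expression_ratio positive numeric vector, same length/pairing.
#' @return Tibble: `r, p_value, spearman_rho, spearman_p, n`.
#' @export
concordance <- function(luciferase_ratio, expression_ratio) {
  if (length(luciferase_ratio) != length(expression_ratio)) {
    stop_validation("paired vectors must have the same length")
  }
  keep <- is.finite(luciferase_ratio) & is.finite(expression_ratio) &
    luciferase_ratio > 0 & expression_ratio > 0
  x <- log2(luciferase_ratio[keep])
  y <- log2(expression_ratio[keep])
  if (length(x) < 3) stop_validation("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_validation("correlation undefined: one vector is constant")
  }
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(r = unname(pe$estimate), p_value = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n = length(x))
}

#' Western-blot densitometry statistics
#'
#' Band intensities of the protein of interest are normalized to the
#' loading control (actin) within each replicate, expressed relative to the
#' control condition of the same replicate, and tested with a paired
#' two-sided t-test (condition ratios vs control ratios across replicates).
#'
#' @param intensities data frame `condition, replicate, nrf2_intensity,
#'   actin_intensity`.
#' @param control condition label serving as reference.
#' @param alpha significance level (default 0.05).
#' @return Tibble per condition: `condition, relative_to_control, p_value,
#'   significant, n` (control row has relative 1 and `p_value = NA`).
#' @export
densitometry_stats <- function(intensities, control = "control", alpha = 0.05) {
  dat <- intensities |>
    dplyr::mutate(ratio = .data$nrf2_intensity / .data$actin_intensity)
  ctrl <- dat |>
    dplyr::filter(.data$condition == control) |>
    dplyr::select("replicate", ctrl_ratio = "ratio")
  if (nrow(ctrl) == 0) stop_validation("control condition not found")
  merged <- dplyr::inner_join(dat, ctrl, by = "replicate")
  unmatched <- dat |>
    dplyr::anti_join(ctrl, by = "replicate")
  if (nrow(unmatched) > 0) {
    stop_validation(sprintf(
      "%d replicate(s) have no matching control measurement", nrow(unmatched)))
  }
  merged |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      relative_to_control = mean(.data$ratio / .data$ctrl_ratio),
      p_value = if (dplyr::cur_group()$condition == control) NA_real_
        else if (dplyr::n() >= 2 && sd(.data$ratio - .data$ctrl_ratio) > 0)
          t.test(.data$ratio, .data$ctrl_ratio, paired = TRUE)$p.value
        else NA_real_,
      n = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)
}
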