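#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification: per (gene, sample), `dCt` is the mean
#' target Ct minus the mean reference-gene Ct over replicates; `ddCt` is
#' `dCt(sample) - dCt(calibrator)` within each gene; relative expression is
#' `2^-ddCt` (amplification efficiency fixed at 100%). The replicate
#' standard deviation is propagated to `sd_dct = sqrt(sd_target^2 +
#' sd_reference^2)`.
#'
#' @param records Tibble with columns `gene_id`, `sample_id`, `replicate`,
#'   `ct_target`, `ct_reference` (Ct values in (0, 40]).
#' @param calibrator_sample The calibrator `sample_id` (fold 1 by
#'   construction).
#' @return A tibble per (gene, sample): `dct`, `sd_dct`, `ddct`,
#'   `rel_expression`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   gene_id = "g", sample_id = rep(c("ctl", "trt"), each = 3),
#'   replicate = rep(1:3, 2),
#'   ct_target = c(26, 26, 26, 24, 24, 24),
#'   ct_reference = rep(20, 6))
#' delta_delta_ct(rec, "ctl")   # treated fold 4
delta_delta_ct <- function(records, calibrator_sample) {
  stopifnot(all(c("gene_id", "sample_id", "ct_target", "ct_reference")
                %in% names(records)))
  if (any(is.na(records$ct_reference))) {
    bad <- records[is.na(records$ct_reference), ]
    abort(paste0("missing reference Ct for gene ", bad$gene_id[1],
                 ", sample ", bad$sample_id[1]))
  }
  if (any(records$ct_target <= 0 | records$ct_target > 40) ||
      any(records$ct_reference <= 0 | records$ct_reference > 40)) {
    abort("Ct values must lie in (0, 40]")
  }
  if (!calibrator_sample %in% records$sample_id) {
    abort(paste0("calibrator sample not present: ", calibrator_sample))
  }
  per <- records |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(
      dct = mean(.data$ct_target) - mean(.data$ct_reference),
      sd_dct = sqrt((if (dplyr::n() > 1) sd(.data$ct_target)^2 else 0) +
                      (if (dplyr::n() > 1) sd(.data$ct_reference)^2 else 0)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  cal <- per |>
    filter(.data$sample_id == calibrator_sample) |>
    select("gene_id", cal_dct = "dct")
  missing_cal <- setdiff(per$gene_id, cal$gene_id)
  if (length(missing_cal) > 0) {
    abort(paste0("no calibrator measurement for gene ",
                 missing_cal[1]))
  }
  per |>
    left_join(cal, by = "gene_id") |>
    mutate(ddct = .data$dct - .data$cal_dct,
           rel_expression = 2^(-.data$ddct)) |>
    select("gene_id", "sample_id", "n_replicates", "dct", "sd_dct",
           "ddct", "rel_expression")
}

#' One-way ANOVA over replicate groups
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within` with
#' `(k - 1, N - k)` degrees of freedom and p-value from the F distribution.
#' Degenerate inputs follow the method's limits: zero within-group variance
#' with unequal group means gives `F = Inf`, `p = 0`; all values identical
#' gives `F = 0`, `p = 1`.
#'
#' @param groups List (length >= 2) of numeric replicate vectors (each of
#'   length >= 2).
#' @return One-row tibble: `f`, `p`, `df_between`, `df_within`.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))   # F = 1.5
anova_oneway <- function(groups) {
  if (length(groups) < 2) abort("at least two groups required")
  if (any(lengths(groups) < 2)) abort("each group needs at least two values")
  k <- length(groups)
  n_tot <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- k - 1
  df_w <- n_tot - k
  if (ssw == 0) {
    if (ssb == 0) {
      return(tibble(f = 0, p = 1, df_between = df_b, df_within = df_w))
    }
    return(tibble(f = Inf, p = 0, df_between = df_b, df_within = df_w))
  }
  f <- (ssb / df_b) / (ssw / df_w)
  tibble(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE),
         df_between = df_b, df_within = df_w)
}

#' Per-gene treated-vs-control ANOVA on ddCt input
#'
#' Convenience wrapper running [anova_oneway()] per gene on replicate
#' `dCt` values grouped by sample.
#'
#' @param records As in [delta_delta_ct()], with a `condition` or
#'   `sample_id` grouping.
#' @param group_col Column defining the groups (default `"sample_id"`).
#' @return Tibble with one row per gene: `gene_id`, `f`, `p`.
#' @export
qpcr_anova <- function(records, group_col = "sample_id") {
  records |>
    mutate(dct_rep = .data$ct_target - .data$ct_reference) |>
    group_by(.data$gene_id) |>
    summarise(res = {
      gs <- split(.data$dct_rep, .data[[group_col]])
      list(anova_oneway(gs)[, c("f", "p")])
    }, .groups = "drop") |>
    tidyr::unnest("res")
}
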