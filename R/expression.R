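#' Log2(FPKM + 1) normalization
#'
#' @param matrix An `fpkm_matrix` of raw FPKM values (see
#'   [read_expression_matrix()] / [as_fpkm_matrix()]).
#' @return The matrix with every value transformed to `log2(v + 1)` and the
#'   `normalized` flag set. Re-normalizing is an error.
#' @export
#' @examples
#' m <- as_fpkm_matrix(tibble::tibble(gene_id = "g", s1 = 7))
#' normalize_log2(m)$s1   # 3
normalize_log2 <- function(matrix) {
  if (is_normalized(matrix)) abort("matrix is already log2(FPKM+1)-normalized")
  samples <- setdiff(names(matrix), "gene_id")
  out <- mutate(matrix, across(all_of(samples), function(v) log2(v + 1)))
  new_fpkm_matrix(out, normalized = TRUE)
}

#' Hierarchical clustering of expression rows
#'
#' Agglomerative clustering of gene rows with average linkage on a
#' correlation distance (`1 - Pearson`) or euclidean distance. Rows with
#' zero variance, for which correlation is undefined, are placed at the
#' maximum correlation distance (2) from every other row. Leaf order is
#' deterministic (ties resolved toward the smaller original row index by
#' [stats::hclust()]'s ordering).
#'
#' @param matrix An `fpkm_matrix`.
#' @param metric `"correlation"` or `"euclidean"`.
#' @param linkage Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return A list with `order` (gene ids in leaf order), `hclust` (the
#'   dendrogram, `NULL` for a single gene) and `k_cut` helper-ready
#'   `merge` structure.
#' @export
hierarchical_cluster <- function(matrix, metric = c("correlation", "euclidean"),
                                 linkage = "average") {
  metric <- match.arg(metric)
  vals <- as.matrix(matrix[, setdiff(names(matrix), "gene_id"), drop = FALSE])
  rownames(vals) <- matrix$gene_id
  if (nrow(vals) < 2) {
    return(list(order = matrix$gene_id, hclust = NULL))
  }
  d <- if (metric == "euclidean") {
    stats::dist(vals)
  } else {
    v <- apply(vals, 1, stats::var)
    cc <- suppressWarnings(cor(t(vals)))
    dd <- 1 - cc
    dd[v == 0, ] <- 2
    dd[, v == 0] <- 2
    diag(dd) <- 0
    as.dist(dd)
  }
  hc <- hclust(d, method = linkage)
  list(order = rownames(vals)[hc$order], hclust = hc)
}

#' Cut a clustering into k groups
#'
#' @param clustering Result of [hierarchical_cluster()].
#' @param k Number of groups.
#' @return Tibble with `gene_id` and `cluster`.
#' @export
cut_clusters <- function(clustering, k) {
  if (is.null(clustering$hclust)) {
    return(tibble(gene_id = clustering$order, cluster = 1L))
  }
  ct <- stats::cutree(clustering$hclust, k = k)
  tibble(gene_id = names(ct), cluster = unname(ct))
}

#' Flag per-gene tissue expression breadth
#'
#' On a raw FPKM matrix over tissue samples: `high_all_tissues` when every
#' sample is at or above the threshold; `low_all` when every sample is
#' below it; `tissue_specific` when at least one sample reaches the
#' threshold but no more than 30% of samples do (rounded up); `mixed`
#' otherwise.
#'
#' @param matrix A raw `fpkm_matrix`.
#' @param high_threshold FPKM threshold (default 5).
#' @param breadth_cutoff Maximum fraction of samples at/above threshold for
#'   a tissue-specific call (default 0.3).
#' @return Tibble with `gene_id`, `n_high`, `class`.
#' @export
flag_expression_class <- function(matrix, high_threshold = 5,
                                  breadth_cutoff = 0.3) {
  vals <- as.matrix(matrix[, setdiff(names(matrix), "gene_id"), drop = FALSE])
  n <- ncol(vals)
  n_high <- rowSums(vals >= high_threshold)
  tibble(
    gene_id = matrix$gene_id,
    n_high = as.integer(n_high),
    class = dplyr::case_when(
      n_high == n ~ "high_all_tissues",
      n_high == 0 ~ "low_all",
      n_high <= ceiling(breadth_cutoff * n) ~ "tissue_specific",
      TRUE ~ "mixed"
    )
  )
}

#' Classify salt-stress response profiles
#'
#' Per gene and over a shared timepoint grid: `low_expression` when the
#' whole profile (treated and control) stays below `low_threshold`;
#' `induced` when some timepoint has treated at least `fold` times its
#' control (or, without a control series, `fold` times the first-timepoint
#' baseline) and that treated value reaches `low_threshold`; `repressed`
#' symmetrically; `unchanged` otherwise. A gene qualifying as both keeps
#' the direction with the larger maximal fold change. `peak_time` is the
#' timepoint of maximal treated expression, earliest on ties.
#'
#' @param profiles Long tibble with columns `gene_id`, `timepoint`,
#'   `treated` and optionally `control` (FPKM).
#' @param fold Fold-change threshold (default 2).
#' @param low_threshold FPKM floor (default 5).
#' @return Tibble with one row per gene: `gene_id`, `direction`,
#'   `peak_time` (`NA` for low-expression genes).
#' @export
classify_salt_response <- function(profiles, fold = 2, low_threshold = 5) {
  has_control <- "control" %in% names(profiles)
  profiles |>
    group_by(.data$gene_id) |>
    arrange(.data$timepoint, .by_group = TRUE) |>
    summarise(res = {
      tp <- .data$timepoint
      tr <- .data$treated
      if (length(tp) < 2) abort("at least two timepoints required")
      ref <- if (has_control) .data$control else rep(tr[1], length(tr))
      peak <- tp[which.max(tr)]
      hi <- max(tr, if (has_control) ref else numeric())
      up <- tr >= fold * ref & tr >= low_threshold
      dn <- tr <= ref / fold & ref >= low_threshold
      dir <- if (hi < low_threshold) {
        "low_expression"
      } else if (any(up) && any(dn)) {
        if (max(tr / pmax(ref, .Machine$double.eps)) >=
              max(ref / pmax(tr, .Machine$double.eps))) "induced" else "repressed"
      } else if (any(up)) {
        "induced"
      } else if (any(dn)) {
        "repressed"
      } else {
        "unchanged"
      }
      list(tibble(direction = dir,
                  peak_time = if (dir == "low_expression") NA_real_ else peak))
    }, .groups = "drop") |>
    tidyr::unnest("res")
}

#' Peak-time bias between two species' response profiles
#'
#' For each ortholog pair, the difference in time-to-peak
#' (`peak_time(B) - peak_time(A)`), plus a summary: the median difference
#' and the number of pairs with opposite early-phase behaviour (A falling
#' while B rises over the first two timepoints).
#'
#' @param profilesA,profilesB Long profile tibbles as in
#'   [classify_salt_response()] (species A and B).
#' @param ortholog_pairs Tibble with `gene_a`, `gene_b` columns (ids in A
#'   and B respectively).
#' @param fold,low_threshold Passed to [classify_salt_response()].
#' @return A list: `pairs` (per-pair tibble with `delta_peak`,
#'   `opposite_early`), `summary` (tibble with `median_delta_peak`,
#'   `n_opposite_early`, `n_pairs_used`, `n_pairs_excluded`).
#' @export
peak_time_bias <- function(profilesA, profilesB, ortholog_pairs,
                           fold = 2, low_threshold = 5) {
  clsA <- classify_salt_response(profilesA, fold, low_threshold)
  clsB <- classify_salt_response(profilesB, fold, low_threshold)
  early_slope <- function(profiles, gene) {
    p <- profiles |> filter(.data$gene_id == gene) |> arrange(.data$timepoint)
    p$treated[2] - p$treated[1]
  }
  per <- ortholog_pairs |>
    mutate(
      peak_a = clsA$peak_time[match(.data$gene_a, clsA$gene_id)],
      peak_b = clsB$peak_time[match(.data$gene_b, clsB$gene_id)],
      delta_peak = .data$peak_b - .data$peak_a,
      opposite_early = map2_lgl(.data$gene_a, .data$gene_b, function(a, b) {
        sa <- early_slope(profilesA, a)
        sb <- early_slope(profilesB, b)
        isTRUE(sa < 0 && sb > 0)
      })
    )
  used <- filter(per, !is.na(.data$delta_peak))
  list(
    pairs = per,
    summary = tibble(
      median_delta_peak = if (nrow(used)) median(used$delta_peak) else NA_real_,
      n_opposite_early = sum(used$opposite_early),
      n_pairs_used = nrow(used),
      n_pairs_excluded = nrow(per) - nrow(used)
    )
  )
}

#' @importFrom purrr map2_lgl
NULL
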