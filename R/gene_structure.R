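#' Exon/intron structure per gene
#'
#' Introns are the gaps between consecutive exons of the representative
#' transcript; an intron's length is `next_start - prev_end - 1` (1-based
#' inclusive coordinates). Exons are re-sorted internally, so input order
#' does not matter.
#'
#' @param models Gene models from [read_gff3()] (tibble with `gene_id` and
#'   an `exons` list-column).
#' @return A tibble with `gene_id`, `n_exons`, `n_introns` and a
#'   list-column `intron_lengths`.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = "g1",
#'   exons = list(tibble::tibble(start = c(1, 201), end = c(100, 300))))
#' count_introns(m)
count_introns <- function(models) {
  tibble(
    gene_id = models$gene_id,
    n_exons = map_int(models$exons, nrow),
    intron_lengths = map(models$exons, function(ex) {
      ex <- ex[order(ex$start), ]
      if (nrow(ex) < 2) return(integer())
      lens <- ex$start[-1] - ex$end[-nrow(ex)] - 1L
      if (any(lens <= 0)) abort("non-positive intron length; exons overlap or abut")
      lens
    })
  ) |>
    mutate(n_introns = .data$n_exons - 1L) |>
    select("gene_id", "n_exons", "n_introns", "intron_lengths")
}

#' Subfamily-by-intron-count contingency table
#'
#' Joins structure summaries to subfamily assignments and tallies genes per
#' (subfamily, intron count); genes without an assignment are tallied under
#' `unassigned`. The per-subfamily modal intron count is attached.
#'
#' @param summaries Output of [count_introns()].
#' @param assignments Tibble with `query_id` and `subfamily` columns (e.g.
#'   from [screen_candidates()]).
#' @return A list with `table` (tibble `subfamily`, `n_introns`, `n_genes`)
#'   and `modal` (tibble `subfamily`, `modal_introns`).
#' @export
intron_pattern_table <- function(summaries, assignments) {
  if (nrow(summaries) == 0) {
    return(list(table = tibble(subfamily = character(), n_introns = integer(),
                               n_genes = integer()),
                modal = tibble(subfamily = character(),
                               modal_introns = integer())))
  }
  joined <- summaries |>
    left_join(select(assignments, gene_id = "query_id", "subfamily"),
              by = "gene_id") |>
    mutate(subfamily = dplyr::coalesce(.data$subfamily, "unassigned"))
  tab <- joined |>
    count(.data$subfamily, .data$n_introns, name = "n_genes") |>
    arrange(.data$subfamily, .data$n_introns)
  modal <- tab |>
    group_by(.data$subfamily) |>
    arrange(dplyr::desc(.data$n_genes), .data$n_introns, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("subfamily", modal_introns = "n_introns")
  list(table = tab, modal = modal)
}
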