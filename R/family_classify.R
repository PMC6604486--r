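#' Optimal global pairwise alignment statistics
#'
#' Aligns a query against one or more references by Needleman-Wunsch with
#' affine gaps (BLOSUM62, gap open 10, gap extend 0.5 by default) and returns
#' per-pair statistics. Identity is counted over all alignment columns,
#' including gap columns; query coverage is the fraction of query residues
#' aligned against a reference residue (columns where both sequences are
#' non-gap, over query length).
#'
#' @param query A single protein sequence (character) or one-row tibble with
#'   `id`/`sequence` columns.
#' @param refs Character vector of protein sequences (optionally named), or a
#'   tibble with `id`/`sequence` columns.
#' @param substitution_matrix,gap_opening,gap_extension Alignment scoring
#'   parameters.
#' @return A tibble with one row per reference: `query_id`, `ref_id`,
#'   `identity_pct`, `query_coverage_pct`, `aligned_length`, `score`.
#' @export
#' @examples
#' pairwise_global_align("MKVLH", c(self = "MKVLH"))
pairwise_global_align <- function(query, refs,
                                  substitution_matrix = "BLOSUM62",
                                  gap_opening = 10, gap_extension = 0.5) {
  q <- as_seq_vector(query, "query")
  r <- as_seq_vector(refs, "ref")
  if (length(q) != 1) abort("exactly one query sequence expected")
  if (!nzchar(q)) abort("empty query sequence")
  if (any(!nzchar(r))) abort("empty reference sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(r)), Biostrings::AAString(unname(q)),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  aln_len <- Biostrings::nchar(pa)
  ident <- Biostrings::nmatch(pa)
  ref_aln <- as.character(Biostrings::pattern(pa))
  qry_aln <- as.character(Biostrings::subject(pa))
  gaps_ref <- stringr::str_count(ref_aln, stringr::fixed("-"))
  gaps_qry <- stringr::str_count(qry_aln, stringr::fixed("-"))
  both <- aln_len - gaps_ref - gaps_qry
  tibble(
    query_id = unname(names(q)), ref_id = unname(names(r)),
    identity_pct = unname(100 * ident / aln_len),
    query_coverage_pct = unname(100 * both / nchar(q)[[1]]),
    aligned_length = as.integer(aln_len),
    score = Biostrings::score(pa)
  )
}

#' @noRd
as_seq_vector <- function(x, role) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(setNames(x$sequence, x$id))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0(role, seq_along(x))
    return(x)
  }
  abort(paste0("cannot interpret ", role, " sequences"))
}

#' Aligned query/reference strings of a global alignment
#'
#' @inheritParams pairwise_global_align
#' @return A list with elements `query` and `ref`: equal-length aligned
#'   strings with `-` for gaps.
#' @export
aligned_strings <- function(query, refs, substitution_matrix = "BLOSUM62",
                            gap_opening = 10, gap_extension = 0.5) {
  q <- as_seq_vector(query, "query")
  r <- as_seq_vector(refs, "ref")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(r)), Biostrings::AAString(unname(q[1])),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  list(query = as.character(Biostrings::subject(pa)),
       ref = as.character(Biostrings::pattern(pa)),
       score = Biostrings::score(pa))
}

#' Screen a proteome for aquaporin candidates
#'
#' Every proteome entry is aligned globally against every reference
#' aquaporin. An entry is retained when its best hit passes both the
#' identity and coverage thresholds; the family ladder is then applied:
#' best identity > 40% calls the protein an aquaporin, retained entries at
#' or below 40% are flagged as candidate members of a new MIP-like family,
#' and the subfamily (parsed from the best reference's name) is assigned
#' only above 60% identity. Ties for the best reference are broken by higher
#' alignment score, then lexicographic reference id.
#'
#' @param proteome Tibble of protein records (`id`, `sequence`).
#' @param refset Tibble of reference aquaporins (`id`, `sequence`); ids
#'   should embed the subfamily and group, e.g. `"AtPIP1;2"`.
#' @param min_identity_pct Screening floor on best identity (retain if
#'   `>=`, default 30).
#' @param min_coverage_pct Screening floor on query coverage (retain if
#'   `>`, default 50).
#' @return A tibble with one row per proteome entry: `query_id`,
#'   `best_ref_id`, `best_identity_pct`, `best_coverage_pct`, `retained`,
#'   `family_call` (`AQP`, `new_family_candidate`, `non_AQP`) and
#'   `subfamily` (`PIP`, `TIP`, ... or `unassigned`).
#' @export
screen_candidates <- function(proteome, refset,
                              min_identity_pct = 30, min_coverage_pct = 50) {
  if (nrow(refset) == 0) abort("reference set must be non-empty")
  if (nrow(proteome) == 0) {
    return(tibble(query_id = character(), best_ref_id = character(),
                  best_identity_pct = double(), best_coverage_pct = double(),
                  retained = logical(), family_call = character(),
                  subfamily = character()))
  }
  best <- purrr::map_dfr(seq_len(nrow(proteome)), function(i) {
    hits <- pairwise_global_align(proteome[i, ], refset)
    hits |>
      arrange(dplyr::desc(.data$identity_pct), dplyr::desc(.data$score),
              .data$ref_id) |>
      dplyr::slice(1)
  })
  best |>
    mutate(
      retained = .data$identity_pct >= min_identity_pct &
        .data$query_coverage_pct > min_coverage_pct,
      family_call = dplyr::case_when(
        !retained ~ "non_AQP",
        identity_pct > 40 ~ "AQP",
        TRUE ~ "new_family_candidate"
      ),
      subfamily = ifelse(.data$retained & .data$identity_pct > 60,
                         parse_subfamily(.data$ref_id), "unassigned")
    ) |>
    select(query_id = "query_id", best_ref_id = "ref_id",
           best_identity_pct = "identity_pct",
           best_coverage_pct = "query_coverage_pct",
           "retained", "family_call", "subfamily")
}

#' @noRd
parse_subfamily <- function(ref_id) {
  m <- stringr::str_match(ref_id, "(PIP|TIP|NIP|SIP|XIP|HIP|LIP|GIP)")[, 2]
  ifelse(is.na(m), "unassigned", m)
}

#' Assign standardized aquaporin names with paralog suffixes
#'
#' Queries sharing a best reference ortholog (e.g. `AtPIP1;4`) receive the
#' ortholog's subfamily/group name with paralog suffixes `a`, `b`, `c`, ...
#' ordered by chromosome (lexicographic) then start coordinate; singletons
#' get no suffix (`NIP4;1` vs `PIP1;4a`..`PIP1;4j`). More than ten paralogs
#' continue `k`, `l`, ... with a warning.
#'
#' @param assignments Output of [screen_candidates()] (retained rows are
#'   named; others get `NA`).
#' @param models Gene models from [read_gff3()]; matched to queries by
#'   `gene_id`.
#' @param prefix Optional species prefix prepended to every name (e.g.
#'   `"Gr"`).
#' @return `assignments` with a `standardized_name` column.
#' @export
assign_nomenclature <- function(assignments, models, prefix = "") {
  base <- stringr::str_match(
    assignments$best_ref_id,
    "((?:PIP|TIP|NIP|SIP|XIP|HIP|LIP|GIP)\\d+;\\d+)")[, 2]
  pos <- models[match(assignments$query_id, models$gene_id),
                c("chrom", "start")]
  out <- assignments
  out$ortholog_name <- ifelse(out$retained, base, NA_character_)
  out$.chrom <- pos$chrom
  out$.start <- pos$start
  out <- out |>
    group_by(.data$ortholog_name) |>
    mutate(.n_para = dplyr::n()) |>
    arrange(.data$.chrom, .data$.start, .by_group = TRUE) |>
    mutate(.rank = row_number()) |>
    ungroup()
  if (any(out$.n_para > 10 & !is.na(out$ortholog_name))) {
    warn("more than 10 paralogs for an ortholog; suffixes continue k, l, ...")
  }
  if (any(out$.n_para > 26 & !is.na(out$ortholog_name))) {
    abort("more than 26 paralogs of one ortholog; suffix alphabet exhausted")
  }
  out$standardized_name <- ifelse(
    is.na(out$ortholog_name), NA_character_,
    paste0(prefix, out$ortholog_name,
           ifelse(out$.n_para > 1, letters[out$.rank], "")))
  out |>
    select(-".chrom", -".start", -".n_para", -".rank") |>
    arrange(match(.data$query_id, assignments$query_id))
}
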