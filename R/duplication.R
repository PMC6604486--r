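# --- Nei-Gojobori (1986) Ka/Ks -------------------------------------------

#' @noRd
codon_table <- function() Biostrings::GENETIC_CODE

#' @noRd
is_stop <- function(codon) unname(codon_table()[codon] == "*")

# per-codon synonymous site count: for each position, the fraction of the
# three single-nucleotide changes that preserve the amino acid; mutations
# creating a stop codon count as nonsynonymous (classic NG86 convention)
#' @noRd
syn_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    nts <- c("A", "C", "G", "T")
    vals <- vapply(sense, function(cod) {
      aa <- gc[[cod]]
      s <- 0
      for (pos in 1:3) {
        for (nt in setdiff(nts, substr(cod, pos, pos))) {
          alt <- cod
          substr(alt, pos, pos) <- nt
          if (gc[[alt]] == aa) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    tab <<- vals
    tab
  }
})

# average syn/nonsyn differences between two codons over all minimal
# mutation paths; paths through stop codons are excluded unless every path
# is blocked
#' @noRd
codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  gc <- Biostrings::GENETIC_CODE
  perms <- if (k == 1) list(pos) else if (k == 2) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  walk_path <- function(ord) {
    cur <- c1
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (gc[[nxt]] == gc[[cur]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk_path, numeric(3))
  ok <- res["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(syn = mean(res["syn", ok]), nonsyn = mean(res["nonsyn", ok]))
}

#' @noRd
split_codons <- function(s) {
  n <- nchar(s) %/% 3
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# protein-guided codon alignment: translate, align proteins globally,
# back-thread codons; columns where either side is a gap become gap codons
#' @noRd
codon_align <- function(a, b) {
  trim <- function(s) substr(s, 1, 3 * (nchar(s) %/% 3))
  a <- trim(a); b <- trim(b)
  if (nchar(a) == nchar(b)) {
    return(list(a = split_codons(a), b = split_codons(b)))
  }
  pa <- as.character(Biostrings::translate(Biostrings::DNAString(a),
                                           if.fuzzy.codon = "solve"))
  pb <- as.character(Biostrings::translate(Biostrings::DNAString(b),
                                           if.fuzzy.codon = "solve"))
  pa <- sub("\\*$", "", pa); pb <- sub("\\*$", "", pb)
  aln <- aligned_strings(pa, pb)
  qa <- strsplit(aln$query[1], "")[[1]]   # pa
  ra <- strsplit(aln$ref[1], "")[[1]]     # pb
  ca <- split_codons(a); cb <- split_codons(b)
  ia <- 0; ib <- 0
  out_a <- character(length(qa)); out_b <- character(length(qa))
  for (j in seq_along(qa)) {
    if (qa[j] != "-") { ia <- ia + 1; out_a[j] <- ca[ia] } else out_a[j] <- "---"
    if (ra[j] != "-") { ib <- ib + 1; out_b[j] <- cb[ib] } else out_b[j] <- "---"
  }
  list(a = out_a, b = out_b)
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Classic codon-counting estimator: per-codon synonymous site fractions
#' averaged over both sequences; observed synonymous/nonsynonymous
#' differences by equal-weight averaging over all minimal mutation paths per
#' codon (paths through stop codons excluded when avoidable); Jukes-Cantor
#' correction `d = -(3/4) ln(1 - 4p/3)` applied to both proportions. Codons
#' containing gaps, `N`/ambiguity characters or stop codons (in either
#' sequence) are excluded from site and difference counts. Sequences of
#' unequal length are codon-aligned via a protein-guided global alignment;
#' incomplete terminal codons are trimmed.
#'
#' @param cds_a,cds_b Coding sequences (character strings or one-row tibbles
#'   with a `sequence` column).
#' @return A one-row tibble: `ka`, `ks`, `omega` (`NA` when `ks` is 0 or a
#'   proportion reaches the correction's domain boundary), plus `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `n_codons_used`.
#' @export
#' @examples
#' ng86_kaks("ATGAAACCC", "ATGAAACCC")   # identical: ka = ks = 0
ng86_kaks <- function(cds_a, cds_b) {
  a <- if (is.data.frame(cds_a)) cds_a$sequence[1] else cds_a
  b <- if (is.data.frame(cds_b)) cds_b$sequence[1] else cds_b
  if (!nzchar(a) || !nzchar(b)) abort("empty coding sequence")
  al <- codon_align(toupper(a), toupper(b))
  gc <- Biostrings::GENETIC_CODE
  sst <- syn_site_table()
  usable <- map_lgl(seq_along(al$a), function(i) {
    ca <- al$a[i]; cb <- al$b[i]
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) return(FALSE)
    gc[[ca]] != "*" && gc[[cb]] != "*"
  })
  ca <- al$a[usable]; cb <- al$b[usable]
  n_used <- length(ca)
  if (n_used == 0) {
    return(tibble(ka = NA_real_, ks = NA_real_, omega = NA_real_,
                  syn_sites = 0, nonsyn_sites = 0, syn_diffs = 0,
                  nonsyn_diffs = 0, n_codons_used = 0L))
  }
  S <- (sum(sst[ca]) + sum(sst[cb])) / 2
  N <- 3 * n_used - S
  diffs <- vapply(seq_len(n_used), function(i) codon_diffs(ca[i], cb[i]),
                  numeric(2))
  Sd <- sum(diffs["syn", ]); Nd <- sum(diffs["nonsyn", ])
  jc <- function(p) {
    if (is.nan(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(Sd / S)
  ka <- jc(Nd / N)
  omega <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  tibble(ka = ka, ks = ks, omega = omega,
         syn_sites = S, nonsyn_sites = N,
         syn_diffs = Sd, nonsyn_diffs = Nd, n_codons_used = n_used)
}

#' Ka/Ks over a table of gene pairs
#'
#' @param pairs Tibble with `gene_a`, `gene_b` columns.
#' @param cds Tibble of coding sequences (`id`, `sequence`).
#' @return `pairs` with `ka`, `ks`, `omega` and `selection` columns; pairs
#'   whose sequences are missing get `NA` with a warning.
#' @export
kaks_pairs <- function(pairs, cds) {
  seqs <- setNames(cds$sequence, cds$id)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- seqs[pairs$gene_a[i]]; b <- seqs[pairs$gene_b[i]]
    if (is.na(a) || is.na(b)) {
      warn(paste0("missing CDS for pair ", pairs$gene_a[i], "/",
                  pairs$gene_b[i]))
      return(tibble(ka = NA_real_, ks = NA_real_, omega = NA_real_))
    }
    ng86_kaks(a, b)[, c("ka", "ks", "omega")]
  })
  dplyr::bind_cols(pairs, res) |>
    mutate(selection = classify_selection(.data$omega))
}

#' Classify selection pressure from omega
#'
#' @param omega Ka/Ks ratios (may contain `NA`).
#' @param neutral_band Half-width of the neutrality band around 1.
#' @return Character vector: `purifying` (omega < 1), `positive`
#'   (omega > 1), `neutral~1` (within the band) or `NA`.
#' @export
#' @examples
#' classify_selection(c(0.023, 1, 1.8, NA))
classify_selection <- function(omega, neutral_band = 0.05) {
  dplyr::case_when(
    is.na(omega) ~ NA_character_,
    abs(omega - 1) <= neutral_band ~ "neutral~1",
    omega < 1 ~ "purifying",
    TRUE ~ "positive"
  )
}

# --- tandem duplication ---------------------------------------------------

#' Detect tandemly duplicated gene pairs
#'
#' A same-chromosome gene pair is tandem when at most `max_intervening`
#' annotated genes lie between the two (counted strand-agnostically over
#' the full annotation), the distance between their nearest boundaries
#' (`b.start - a.end`) is at most `max_span_bp`, and their protein
#' global-alignment identity exceeds `min_identity_pct`. Pairs are reported
#' with `gene_a` upstream of `gene_b`.
#'
#' @param models Gene models (tibble with `gene_id`, `chrom`, `start`,
#'   `end`).
#' @param proteins Tibble of protein records (`id`, `sequence`).
#' @param max_intervening Maximum annotated genes between the pair.
#' @param max_span_bp Maximum boundary distance in bp.
#' @param min_identity_pct Identity threshold (strictly greater-than).
#' @return A tibble of pairs: `gene_a`, `gene_b`, `chrom`, `dup_type`
#'   (`"tandem"`), `protein_identity_pct`, `intervening_genes`, `span_bp`.
#' @export
find_tandem_pairs <- function(models, proteins, max_intervening = 5,
                              max_span_bp = 100000, min_identity_pct = 70) {
  seqs <- setNames(proteins$sequence, proteins$id)
  empty <- tibble(gene_a = character(), gene_b = character(),
                  chrom = character(), dup_type = character(),
                  protein_identity_pct = double(),
                  intervening_genes = integer(), span_bp = double())
  if (nrow(models) == 0) return(empty)
  out <- models |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      rows <- list()
      for (j in seq_len(n)) {
        is <- seq_len(j - 1)
        is <- is[(j - is - 1) <= max_intervening &
                   (g$start[j] - g$end[is]) <= max_span_bp]
        if (length(is) == 0) next
        have <- !is.na(seqs[g$gene_id[is]]) & !is.na(seqs[g$gene_id[j]])
        if (any(!have)) {
          warn(paste0("no protein sequence for gene(s) near ", g$gene_id[j],
                      "; pair(s) skipped"))
          is <- is[have]
          if (length(is) == 0) next
        }
        hits <- pairwise_global_align(
          setNames(seqs[g$gene_id[j]], g$gene_id[j]),
          setNames(seqs[g$gene_id[is]], g$gene_id[is]))
        keep <- hits$identity_pct > min_identity_pct
        if (!any(keep)) next
        rows[[length(rows) + 1]] <- tibble(
          gene_a = g$gene_id[is[keep]], gene_b = g$gene_id[j],
          chrom = key$chrom, dup_type = "tandem",
          protein_identity_pct = hits$identity_pct[keep],
          intervening_genes = as.integer(j - is[keep] - 1),
          span_bp = g$start[j] - g$end[is[keep]]
        )
      }
      bind_rows(rows)
    }) |>
    bind_rows()
  if (nrow(out) == 0) empty else out
}

#' Load precomputed segmental-duplication pairs
#'
#' Reads a PGDD-style TSV with columns `gene_a`, `gene_b` and optional
#' `ka`, `ks`. When coding sequences are supplied Ka/Ks are recomputed with
#' [ng86_kaks()]; otherwise the file's values are used. When gene models
#' are supplied, rows naming unknown genes are skipped with a warning.
#'
#' @param path Path to the TSV.
#' @param models Optional gene models for id validation.
#' @param cds Optional tibble of coding sequences (`id`, `sequence`).
#' @return Tibble of pairs tagged `dup_type = "segmental"` with `ka`, `ks`,
#'   `omega`, `selection` columns (NA when unavailable).
#' @export
load_segmental_pairs <- function(path, models = NULL, cds = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  dup_type = character(), ka = double(), ks = double(),
                  omega = double(), selection = character()))
  }
  stopifnot(all(c("gene_a", "gene_b") %in% names(x)))
  if (!is.null(models)) {
    known <- x$gene_a %in% models$gene_id & x$gene_b %in% models$gene_id
    if (any(!known)) {
      warn(paste0(sum(!known), " segmental pair(s) with unknown gene ids skipped"))
      x <- x[known, ]
    }
  }
  x$dup_type <- "segmental"
  if (!is.null(cds)) {
    x <- kaks_pairs(select(x, "gene_a", "gene_b", "dup_type"), cds)
  } else {
    x$ka <- if ("ka" %in% names(x)) as.numeric(x$ka) else NA_real_
    x$ks <- if ("ks" %in% names(x)) as.numeric(x$ks) else NA_real_
    x$omega <- ifelse(!is.na(x$ks) & x$ks > 0, x$ka / x$ks, NA_real_)
    x$selection <- classify_selection(x$omega)
  }
  as_tibble(x[, c("gene_a", "gene_b", "dup_type", "ka", "ks", "omega",
                  "selection")])
}
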