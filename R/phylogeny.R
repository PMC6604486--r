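#' Pairwise distances from a multiple alignment
#'
#' Computes p-distances (mismatches over valid columns) or Poisson-corrected
#' distances (`d = -ln(1 - p)`) with pairwise deletion: for each pair, only
#' columns where neither sequence has a gap or ambiguity character are
#' compared.
#'
#' @param msa Tibble of aligned records (`id`, `sequence`), all the same
#'   length.
#' @param model `"p-distance"` or `"poisson"`.
#' @return A symmetric labelled distance matrix.
#' @export
distance_from_alignment <- function(msa, model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  lens <- nchar(msa$sequence)
  if (length(unique(lens)) != 1) abort("alignment rows differ in length")
  m <- do.call(rbind, strsplit(msa$sequence, ""))
  rownames(m) <- msa$id
  n <- nrow(m)
  valid <- !(m == "-" | m == "X" | m == "N" | m == ".")
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) {
        abort(paste0("no valid columns between ", msa$id[i], " and ",
                     msa$id[j]))
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (model == "poisson") {
        if (p >= 1) abort(paste0("poisson distance undefined for ",
                                 msa$id[i], "/", msa$id[j]))
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); exact on additive
#' matrices. Negative branch-length estimates are clamped to zero and the
#' number of clamped edges recorded in the `"clamped_edges"` attribute.
#'
#' @param dm Symmetric labelled distance matrix (>= 3 labels).
#' @param midpoint_root Root the tree at its midpoint (the presentation used
#'   for "rooted" NJ figures when no outgroup is named).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm, midpoint_root = FALSE) {
  if (nrow(dm) < 3) abort("neighbor joining needs at least 3 labels")
  tr <- ape::nj(as.dist(dm))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped_edges") <- sum(neg)
  if (midpoint_root) tr <- phangorn::midpoint(tr)
  tr
}

#' @noRd
tree_from_char_matrix <- function(m, model) {
  msa <- tibble(id = rownames(m),
                sequence = apply(m, 1, paste, collapse = ""))
  nj_tree(distance_from_alignment(msa, model))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the point-estimate NJ tree from the alignment, then resamples
#' alignment columns with replacement `n_reps` times and scores each
#' internal bipartition of the point-estimate tree by the percentage of
#' replicate trees containing it. Reproducible given `seed`; the
#' point-estimate topology does not depend on the seed.
#'
#' @param msa Tibble of aligned records (`id`, `sequence`).
#' @param n_reps Number of bootstrap replicates (0 returns the tree without
#'   supports).
#' @param seed Integer seed for the resampling.
#' @param model Distance model, see [distance_from_alignment()].
#' @return An [ape::phylo] tree; supports (integer percentages) are stored
#'   in `node.label` (root label empty).
#' @export
bootstrap_supports <- function(msa, n_reps = 1000, seed = 1,
                               model = "p-distance") {
  m <- do.call(rbind, strsplit(msa$sequence, ""))
  rownames(m) <- msa$id
  tr <- tree_from_char_matrix(m, model)
  if (n_reps == 0) return(tr)
  counts <- with_seed(seed, {
    ape::boot.phylo(tr, m, function(x) tree_from_char_matrix(x, model),
                    B = n_reps, quiet = TRUE, rooted = FALSE)
  })
  supp <- as.integer(round(100 * counts / n_reps))
  tr$node.label <- as.character(supp)
  tr$node.label[1] <- ""   # root bipartition is trivial
  tr
}

#' Bootstrap support of a specific clade
#'
#' @param tree Tree with `node.label` supports from [bootstrap_supports()].
#' @param tips Leaf labels of the clade of interest.
#' @return Integer support (percent), or `NA` when the clade is not an
#'   internal bipartition of the tree.
#' @export
clade_support <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label)) abort("tip label absent from tree")
  ntip <- length(tree$tip.label)
  other <- setdiff(tree$tip.label, tips)
  for (node in (ntip + 2):(ntip + tree$Nnode)) {
    desc <- ape::extract.clade(tree, node)$tip.label
    # an unrooted bipartition may appear as the clade or its complement
    if (setequal(desc, tips) || setequal(desc, other)) {
      lbl <- tree$node.label[node - ntip]
      return(if (is.null(lbl) || !nzchar(lbl)) NA_integer_ else
               as.integer(lbl))
    }
  }
  NA_integer_
}

#' Check subfamily monophyly on a tree
#'
#' Each group is monophyletic when its leaves form a clade on the
#' midpoint-rooted tree.
#'
#' @param tree An [ape::phylo] tree.
#' @param label_groups Named list of leaf-label vectors.
#' @return A tibble with `group` and `monophyletic` columns.
#' @export
check_monophyly <- function(tree, label_groups) {
  missing <- setdiff(unlist(label_groups), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("label(s) absent from tree: ",
                 paste(missing, collapse = ", ")))
  }
  rooted <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  tibble(
    group = names(label_groups),
    monophyletic = map_lgl(label_groups, function(tips) {
      if (length(tips) == 1) return(TRUE)
      ape::is.monophyletic(rooted, tips)
    })
  )
}
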