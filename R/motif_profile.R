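# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Sliding-window hydropathy profile
#'
#' Kyte-Doolittle hydropathy averaged over a centered window. Sequence ends
#' are padded by truncated windows (the mean runs over the residues that
#' fall inside the sequence).
#'
#' @param sequence A protein sequence (single string).
#' @param window Odd window width, at most the sequence length.
#' @return A tibble with `position`, `residue`, `hydropathy`.
#' @export
#' @examples
#' hydropathy_profile(strrep("I", 25))$hydropathy[1]
hydropathy_profile <- function(sequence, window = 19) {
  if (window %% 2 == 0) abort("window must be odd")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (window > n) abort("window exceeds sequence length")
  h <- unname(KD_SCALE[chars])
  if (anyNA(h)) abort("sequence contains residues outside the hydropathy scale")
  half <- (window - 1) / 2
  cs <- cumsum(c(0, h))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  tibble(position = seq_len(n), residue = chars,
         hydropathy = (cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of windowed hydropathy at or above `threshold`, of length at
#' least `min_len`. Segments are non-overlapping and sorted.
#'
#' @param profile Output of [hydropathy_profile()].
#' @param threshold Hydropathy cutoff (default 1.6).
#' @param min_len Minimum run length in residues (default 15).
#' @return A tibble with `start`, `end`, `length`, `mean_hydropathy`
#'   (possibly zero rows).
#' @export
predict_tm_segments <- function(profile, threshold = 1.6, min_len = 15) {
  above <- profile$hydropathy >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  tibble(
    start = profile$position[starts[keep]],
    end = profile$position[ends[keep]],
    length = r$lengths[keep],
    mean_hydropathy = map_dbl(which(keep), function(i) {
      mean(profile$hydropathy[starts[i]:ends[i]])
    })
  )
}

#' Map annotated template positions onto query proteins
#'
#' Each query is aligned globally against its subfamily's reference template
#' (or against every template, best alignment score wins, when no subfamily
#' is given). Each annotated template column is read off at the aligned
#' query residue; a gap at an annotated column yields `-`. The NPA triplets
#' are read as three consecutive query residues starting at the mapped NPA
#' column; `canonical` means the triplet is exactly `NPA`.
#'
#' @param proteins Tibble of protein records (`id`, `sequence`), optionally
#'   with a `subfamily` column.
#' @param templates Templates from [aqp_templates()].
#' @param subfamily Optional single subfamily applied to all queries
#'   (overrides a `subfamily` column).
#' @param score_floor Alignment score below which the profile is reported as
#'   unresolved (all `-`) with a warning.
#' @return A tibble with one row per query: `query_id`, `subfamily`,
#'   `score`, `npa1_pos`, `npa1`, `npa1_canonical`, `npa2_*`, `H2`, `H5`,
#'   `LE1`, `LE2`, `P1`..`P5`.
#' @export
map_positions <- function(proteins, templates = aqp_templates(),
                          subfamily = NULL, score_floor = 0) {
  fam_col <- if (!is.null(subfamily)) {
    rep(subfamily, nrow(proteins))
  } else if ("subfamily" %in% names(proteins)) {
    proteins$subfamily
  } else {
    rep(NA_character_, nrow(proteins))
  }
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    map_positions_one(proteins$id[i], proteins$sequence[i], fam_col[i],
                      templates, score_floor)
  })
}

#' @noRd
map_positions_one <- function(id, sequence, fam, templates, score_floor) {
  cand <- if (!is.na(fam) && fam %in% templates$subfamily) {
    templates[templates$subfamily == fam, ]
  } else {
    templates
  }
  aln <- aligned_strings(sequence, setNames(cand$sequence, cand$subfamily))
  best <- which.max(aln$score)
  score <- aln$score[best]
  tmpl <- cand[best, ]
  sites <- tmpl$sites[[1]]
  blank <- function() {
    tibble(query_id = id, subfamily = tmpl$subfamily, score = score,
           npa1_pos = NA_integer_, npa1 = "---", npa1_canonical = FALSE,
           npa2_pos = NA_integer_, npa2 = "---", npa2_canonical = FALSE,
           H2 = "-", H5 = "-", LE1 = "-", LE2 = "-",
           P1 = "-", P2 = "-", P3 = "-", P4 = "-", P5 = "-")
  }
  if (score < score_floor) {
    warn(paste0("alignment score below floor for ", id,
                "; motif profile unresolved"))
    return(blank())
  }
  qa <- strsplit(aln$query[best], "")[[1]]
  ra <- strsplit(aln$ref[best], "")[[1]]
  # template position -> alignment column, then -> query position (NA on gap)
  tpos_col <- which(ra != "-")
  qpos_at_col <- ifelse(qa == "-", NA_integer_, cumsum(qa != "-"))

  site_residue <- function(tp) {
    qp <- qpos_at_col[tpos_col[tp]]
    if (is.na(qp)) "-" else substr(sequence, qp, qp)
  }
  npa_read <- function(tp) {
    qp <- qpos_at_col[tpos_col[tp]]
    if (!is.na(qp) && qp + 2 <= nchar(sequence)) {
      list(pos = qp, triplet = substr(sequence, qp, qp + 2))
    } else {
      trip <- paste(vapply(tp + 0:2, function(p) {
        if (p > length(tpos_col)) return("-")
        site_residue(p)
      }, ""), collapse = "")
      qp2 <- qpos_at_col[tpos_col[tp + 1]]  # fall back to P column anchor
      list(pos = if (!is.na(qp2)) qp2 - 1L else NA_integer_, triplet = trip)
    }
  }
  box1 <- npa_read(sites[["NPA1"]])
  box2 <- npa_read(sites[["NPA2"]])
  tibble(
    query_id = id, subfamily = tmpl$subfamily, score = score,
    npa1_pos = as.integer(box1$pos), npa1 = box1$triplet,
    npa1_canonical = identical(box1$triplet, "NPA"),
    npa2_pos = as.integer(box2$pos), npa2 = box2$triplet,
    npa2_canonical = identical(box2$triplet, "NPA"),
    H2 = site_residue(sites[["H2"]]), H5 = site_residue(sites[["H5"]]),
    LE1 = site_residue(sites[["LE1"]]), LE2 = site_residue(sites[["LE2"]]),
    P1 = site_residue(sites[["P1"]]), P2 = site_residue(sites[["P2"]]),
    P3 = site_residue(sites[["P3"]]), P4 = site_residue(sites[["P4"]]),
    P5 = site_residue(sites[["P5"]])
  )
}

#' Detect NPA boxes by pattern scan (template-free fallback)
#'
#' Regex scan for `NP[A-Z]` triplets; lower-confidence than template
#' mapping, intended for sequences without an assignable template.
#'
#' @param sequence Protein sequence.
#' @return Tibble of `position`, `triplet`, `canonical`.
#' @export
scan_npa <- function(sequence) {
  m <- stringr::str_locate_all(sequence, "NP[A-Z]")[[1]]
  tibble(position = m[, 1],
         triplet = stringr::str_sub(sequence, m[, 1], m[, 2]),
         canonical = stringr::str_sub(sequence, m[, 1], m[, 2]) == "NPA")
}

# ordered ar/R group rule table; "-" in a tetrad acts as a wildcard
ARR_RULES <- list(
  list(group = "PIP",     fam = NULL,  h2 = c("F", "V"), h5 = "H", le1 = "T", le2 = "R"),
  list(group = "TIP-I",   fam = NULL,  h2 = "H", h5 = "I", le1 = "A", le2 = "V"),
  list(group = "TIP-IIa", fam = NULL,  h2 = "H", h5 = "I", le1 = "G", le2 = "R"),
  list(group = "TIP-IIb", fam = NULL,  h2 = "H", h5 = "I", le1 = "A", le2 = "R"),
  list(group = "TIP-III", fam = "TIP", h2 = "N", h5 = "V", le1 = NULL, le2 = NULL),
  list(group = "NIP-I",   fam = NULL,  h2 = "W", h5 = "V", le1 = "A", le2 = "R"),
  list(group = "NIP-I",   fam = NULL,  h2 = "G", h5 = "S", le1 = "G", le2 = "R"),
  list(group = "NIP-II",  fam = NULL,  h2 = c("A", "T"), h5 = c("I", "V"),
       le1 = c("G", "A"), le2 = "R"),
  list(group = "SIP-I",   fam = NULL,  h2 = c("P", "G", "A"), h5 = c("F", "S", "N"),
       le1 = c("V", "I", "F"), le2 = c("H", "V")),
  list(group = "SIP-II",  fam = NULL,  h2 = c("S", "G"), h5 = c("H", "S"),
       le1 = c("G", "P"), le2 = c("A", "S")),
  list(group = "XIP",     fam = NULL,  h2 = c("I", "V"), h5 = c("I", "T"),
       le1 = c("V", "R"), le2 = "R")
)

#' Assign an ar/R selectivity-filter group
#'
#' First-matching rule in an ordered table covering the nine groups
#' observed across the five subfamilies: PIP; TIP-I/IIa/IIb/III; NIP-I
#' (including the silicon-channel GSGR tetrad) and NIP-II; SIP-I/II; XIP.
#' Unresolved positions (`-`) act as wildcards; tetrads with fewer than
#' three resolved positions return `unclassified`.
#'
#' @param h2,h5,le1,le2 Single amino-acid letters (or `-`), vectorized.
#' @param subfamily Optional subfamily context, used by rules that need it
#'   (e.g. the TIP-III asparagine/valine tetrad).
#' @return Character vector of group labels.
#' @export
#' @examples
#' assign_arR_group("F", "H", "T", "R")            # "PIP"
#' assign_arR_group("G", "S", "G", "R", "NIP")      # "NIP-I"
assign_arR_group <- function(h2, h5, le1, le2, subfamily = NA_character_) {
  n <- max(length(h2), length(h5), length(le1), length(le2))
  h2 <- rep_len(h2, n); h5 <- rep_len(h5, n)
  le1 <- rep_len(le1, n); le2 <- rep_len(le2, n)
  subfamily <- rep_len(subfamily, n)
  vapply(seq_len(n), function(i) {
    tet <- c(h2[i], h5[i], le1[i], le2[i])
    if (sum(tet != "-") < 3) return("unclassified")
    for (rule in ARR_RULES) {
      if (!is.null(rule$fam) && (is.na(subfamily[i]) || subfamily[i] != rule$fam)) next
      ok <- map_lgl(seq_len(4), function(k) {
        allowed <- rule[[c("h2", "h5", "le1", "le2")[k]]]
        is.null(allowed) || tet[k] == "-" || tet[k] %in% allowed
      })
      if (all(ok)) return(rule$group)
    }
    "unclassified"
  }, "")
}

#' Full motif profile with ar/R group
#'
#' Convenience wrapper: [map_positions()] followed by [assign_arR_group()].
#'
#' @inheritParams map_positions
#' @return The [map_positions()] tibble with an added `arR_group` column.
#' @export
profile_motifs <- function(proteins, templates = aqp_templates(),
                           subfamily = NULL, score_floor = 0) {
  prof <- map_positions(proteins, templates, subfamily, score_floor)
  prof$arR_group <- assign_arR_group(prof$H2, prof$H5, prof$LE1, prof$LE2,
                                     prof$subfamily)
  prof
}
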