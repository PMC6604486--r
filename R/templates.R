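# Synthetic reference templates, one per subfamily, built in code.
#
# Each template is an idealized aquaporin: six hydrophobic transmembrane
# stretches, NPA boxes in loops B and E, the subfamily's ar/R tetrad
# (H2, H5, LE1, LE2) and Froger's P1-P5 residues at fixed, annotated
# columns. They anchor position mapping (align query to template, read the
# annotated columns) in place of a de-novo multiple alignment.

# segment lengths of the template scaffold, in order
TEMPLATE_LAYOUT <- c(nterm = 12, tm1 = 21, loopA = 8, tm2 = 21, loopB = 14,
                     tm3 = 21, loopC = 10, tm4 = 21, loopD = 8, tm5 = 21,
                     loopE = 16, tm6 = 21, cterm = 14)

HYDROPHOBIC_AA <- c("L", "I", "V", "F", "M")
HYDROPHILIC_AA <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "P")

# subfamily-specific annotated residues: ar/R tetrad and Froger P1-P5
TEMPLATE_RESIDUES <- list(
  PIP = list(arR = c(H2 = "F", H5 = "H", LE1 = "T", LE2 = "R"),
             froger = c(P1 = "Q", P2 = "S", P3 = "A", P4 = "F", P5 = "W")),
  TIP = list(arR = c(H2 = "H", H5 = "I", LE1 = "A", LE2 = "V"),
             froger = c(P1 = "T", P2 = "S", P3 = "A", P4 = "Y", P5 = "W")),
  NIP = list(arR = c(H2 = "W", H5 = "V", LE1 = "A", LE2 = "R"),
             froger = c(P1 = "F", P2 = "S", P3 = "A", P4 = "Y", P5 = "L")),
  SIP = list(arR = c(H2 = "A", H5 = "N", LE1 = "V", LE2 = "H"),
             froger = c(P1 = "M", P2 = "A", P3 = "A", P4 = "Y", P5 = "W")),
  XIP = list(arR = c(H2 = "I", H5 = "T", LE1 = "V", LE2 = "R"),
             froger = c(P1 = "V", P2 = "C", P3 = "A", P4 = "F", P5 = "W"))
)

#' Evaluate an expression with a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' @noRd
build_template <- function(subfamily, seed) {
  lay <- TEMPLATE_LAYOUT
  res <- TEMPLATE_RESIDUES[[subfamily]]
  seg <- with_seed(seed, {
    map(names(lay), function(nm) {
      pool <- if (grepl("^tm", nm)) HYDROPHOBIC_AA else HYDROPHILIC_AA
      sample(pool, lay[[nm]], replace = TRUE)
    })
  })
  names(seg) <- names(lay)
  offs <- cumsum(c(0, head(unname(lay), -1)))
  names(offs) <- names(lay)
  at <- function(segment, offset) unname(offs[segment] + offset)

  sites <- c(
    NPA1 = at("loopB", 6), NPA2 = at("loopE", 5),
    H2 = at("tm2", 15), H5 = at("tm5", 10),
    LE1 = at("loopE", 10), LE2 = at("loopE", 12),
    P1 = at("loopE", 14),
    P2 = at("cterm", 3), P3 = at("cterm", 5),
    P4 = at("cterm", 7), P5 = at("cterm", 9)
  )
  chars <- unlist(seg, use.names = FALSE)
  chars[sites[["NPA1"]] + 0:2] <- c("N", "P", "A")
  chars[sites[["NPA2"]] + 0:2] <- c("N", "P", "A")
  for (p in c("H2", "H5", "LE1", "LE2")) chars[sites[[p]]] <- res$arR[[p]]
  for (p in paste0("P", 1:5)) chars[sites[[p]]] <- res$froger[[p]]

  tm <- tibble(
    segment = paste0("TM", 1:6),
    start = unname(offs[paste0("tm", 1:6)] + 1),
    end = unname(offs[paste0("tm", 1:6)] + lay[paste0("tm", 1:6)])
  )
  list(subfamily = subfamily, sequence = paste(chars, collapse = ""),
       sites = sites, tm = tm)
}

#' Reference aquaporin templates
#'
#' Returns the package's synthetic per-subfamily reference templates:
#' idealized aquaporin sequences with annotated columns for the two NPA
#' boxes, the ar/R tetrad (H2, H5, LE1, LE2), Froger's positions P1-P5 and
#' the six transmembrane stretches. Templates are built deterministically in
#' code; they are synthetic anchors for position mapping, not biological
#' sequences.
#'
#' @return A tibble with columns `subfamily`, `sequence`, and list-columns
#'   `sites` (named integer vector of annotated 1-based columns) and `tm`
#'   (tibble of TM1-TM6 ranges).
#' @export
#' @examples
#' aqp_templates()$subfamily
aqp_templates <- function() {
  fams <- names(TEMPLATE_RESIDUES)
  built <- map2(fams, seq_along(fams) + 100L, build_template)
  tibble(
    subfamily = fams,
    sequence = map_chr(built, "sequence"),
    sites = map(built, "sites"),
    tm = map(built, "tm")
  )
}
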