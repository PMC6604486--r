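# Independent oracles used to compute expected values. These deliberately
# re-derive results by brute force / direct arithmetic, not by calling the
# implementation under test.

random_protein <- function(len, seed = NULL) {
  draw <- function() paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G",
                                    "H", "I", "L", "K", "M", "F", "P", "S",
                                    "T", "W", "Y", "V"), len, TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# all-pairs tandem filter: the O(n^2) definition, organized differently from
# the implementation (pair enumeration over the raw table, intervening genes
# counted by an explicit coordinate scan)
brute_tandem_oracle <- function(models, proteins, max_intervening = 5,
                                max_span_bp = 1e5, min_identity_pct = 70) {
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  out <- list()
  for (i in seq_len(nrow(models))) {
    for (j in seq_len(nrow(models))) {
      a <- models[i, ]; b <- models[j, ]
      if (a$chrom != b$chrom) next
      if (!(a$start < b$start)) next
      n_between <- sum(models$chrom == a$chrom &
                         models$start > a$start & models$start < b$start)
      if (n_between > max_intervening) next
      if (b$start - a$end > max_span_bp) next
      sa <- seqs[a$gene_id]; sb <- seqs[b$gene_id]
      if (is.na(sa) || is.na(sb)) next
      idp <- pairwise_global_align(stats::setNames(sa, a$gene_id),
                                   stats::setNames(sb, b$gene_id))$identity_pct
      if (idp > min_identity_pct) {
        out[[length(out) + 1]] <- data.frame(gene_a = a$gene_id,
                                             gene_b = b$gene_id)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  do.call(rbind, out)
}

pair_key <- function(df) sort(paste(df$gene_a, df$gene_b))

# independent Nei-Gojobori oracle: explicit per-position site loop, recursive
# path enumeration, same published conventions (stop-codon mutations are
# nonsynonymous sites; paths through stops dropped when avoidable)
ng86_oracle <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  cods_a <- substring(a, seq(1, nchar(a) - 2, 3), seq(3, nchar(a), 3))
  cods_b <- substring(b, seq(1, nchar(b) - 2, 3), seq(3, nchar(b), 3))
  stopifnot(length(cods_a) == length(cods_b))
  keep <- !grepl("[^ACGT]", cods_a) & !grepl("[^ACGT]", cods_b) &
    gc[cods_a] != "*" & gc[cods_b] != "*"
  cods_a <- cods_a[keep]; cods_b <- cods_b[keep]
  site_count <- function(cod) {
    s <- 0
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      for (nt in c("A", "C", "G", "T")) {
        if (nt == ref) next
        alt <- cod
        substr(alt, p, p) <- nt
        if (gc[[alt]] == gc[[cod]]) s <- s + 1 / 3
      }
    }
    s
  }
  paths <- function(from, to) {
    dif <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (length(dif) == 0) return(list(list(syn = 0, nonsyn = 0, stop = FALSE)))
    res <- list()
    for (p in dif) {
      mid <- from
      substr(mid, p, p) <- substr(to, p, p)
      step_syn <- gc[[mid]] == gc[[from]]
      hit_stop <- gc[[mid]] == "*" && mid != to
      for (rest in paths(mid, to)) {
        res[[length(res) + 1]] <- list(
          syn = rest$syn + as.numeric(step_syn),
          nonsyn = rest$nonsyn + as.numeric(!step_syn),
          stop = rest$stop || hit_stop)
      }
    }
    res
  }
  S <- mean(c(sum(vapply(cods_a, site_count, 0)),
              sum(vapply(cods_b, site_count, 0))))
  N <- 3 * length(cods_a) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(cods_a)) {
    ps <- paths(cods_a[k], cods_b[k])
    ok <- !vapply(ps, `[[`, TRUE, "stop")
    if (!any(ok)) ok <- rep(TRUE, length(ps))
    Sd <- Sd + mean(vapply(ps[ok], `[[`, 0, "syn"))
    Nd <- Nd + mean(vapply(ps[ok], `[[`, 0, "nonsyn"))
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

# file fixtures
write_tmp_lines <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext,
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# minimal single-transcript GFF3 text for a set of gene tibble rows
gff3_lines <- function(genes) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=%s",
              g$chrom, g$start, g$end, g$gene_id),
      sprintf("%s\tsrc\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
              g$chrom, g$start, g$end, tx, g$gene_id))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
        sprintf("%s\tsrc\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                g$chrom, ex$start[j], ex$end[j], tx))
    }
  }
  lines
}
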