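# Ground-truth generators for every pipeline stage. Everything is a pure
# function of its arguments and `seed` (the global RNG stream is left
# untouched), so regenerated outputs are identical.

#' @noRd
mutate_positions <- function(sequence, positions, alphabet = AA_ALPHABET20) {
  chars <- strsplit(sequence, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' @noRd
template_annotated_positions <- function(tmpl) {
  sites <- tmpl$sites[[1]]
  sort(unique(c(sites, sites[["NPA1"]] + 0:2, sites[["NPA2"]] + 0:2)))
}

#' Simulate aquaporin-like proteins with planted motif truth
#'
#' Copies the subfamily template and mutates background positions (never the
#' annotated NPA/ar-R/Froger columns) so that expected identity to the
#' template is `100 - divergence_pct`. Optionally perturbs one NPA box to
#' plant a non-canonical member.
#'
#' @param n_per_subfamily Named integer vector of gene counts, e.g.
#'   `c(PIP = 3, TIP = 2)`.
#' @param divergence_pct Expected percent divergence from the template
#'   (refused above 60, where the identity ladder loses meaning).
#' @param seed Integer seed.
#' @param perturb_npa2 Optional named character, e.g. `c(PIP = "NLA")`:
#'   genes of that subfamily get the given second-NPA triplet.
#' @return A list: `proteins` (tibble `id`, `sequence`, `subfamily`) and
#'   `truth` (planted motif values per gene: NPA triplets, ar/R tetrad,
#'   Froger residues, TM ranges).
#' @export
sim_proteins <- function(n_per_subfamily, divergence_pct = 10, seed = 1,
                         perturb_npa2 = NULL) {
  if (divergence_pct > 60) {
    abort("divergence above 60% refused: identity ladder becomes meaningless")
  }
  templates <- aqp_templates()
  with_seed(seed, {
    rows <- list(); truths <- list()
    for (fam in names(n_per_subfamily)) {
      tmpl <- templates[templates$subfamily == fam, ]
      if (nrow(tmpl) == 0) abort(paste0("no template for subfamily ", fam))
      sites <- tmpl$sites[[1]]
      anno <- template_annotated_positions(tmpl)
      L <- nchar(tmpl$sequence)
      bg <- setdiff(seq_len(L), anno)
      p_mut <- min(1, (divergence_pct / 100) * L / length(bg))
      for (i in seq_len(n_per_subfamily[[fam]])) {
        id <- sprintf("%s_sim%03d", fam, i)
        hit <- bg[stats::runif(length(bg)) < p_mut]
        s <- mutate_positions(tmpl$sequence, hit)
        npa2 <- "NPA"
        if (!is.null(perturb_npa2) && fam %in% names(perturb_npa2)) {
          trip <- strsplit(perturb_npa2[[fam]], "")[[1]]
          chars <- strsplit(s, "")[[1]]
          chars[sites[["NPA2"]] + 0:2] <- trip
          s <- paste(chars, collapse = "")
          npa2 <- perturb_npa2[[fam]]
        }
        rows[[id]] <- tibble(id = id, sequence = s, subfamily = fam)
        truths[[id]] <- tibble(
          id = id, subfamily = fam, npa1 = "NPA", npa2 = npa2,
          H2 = substr(tmpl$sequence, sites[["H2"]], sites[["H2"]]),
          H5 = substr(tmpl$sequence, sites[["H5"]], sites[["H5"]]),
          LE1 = substr(tmpl$sequence, sites[["LE1"]], sites[["LE1"]]),
          LE2 = substr(tmpl$sequence, sites[["LE2"]], sites[["LE2"]]),
          tm = tmpl$tm
        )
      }
    }
    list(proteins = bind_rows(rows), truth = bind_rows(truths))
  })
}

#' Simulate a protein at an exact planted identity to its template
#'
#' Mutates exactly `round(L * (1 - identity_pct/100))` positions (spread
#' over background columns first, then annotated ones if needed), so the
#' gapless identity to the template is planted to within rounding.
#'
#' @param subfamily Template subfamily.
#' @param identity_pct Target percent identity.
#' @param seed Integer seed.
#' @return A one-row tibble (`id`, `sequence`, `subfamily`) with the
#'   template sequence in the `template` attribute.
#' @export
sim_protein_at_identity <- function(subfamily, identity_pct, seed = 1) {
  templates <- aqp_templates()
  tmpl <- templates[templates$subfamily == subfamily, ]
  L <- nchar(tmpl$sequence)
  n_mut <- round(L * (1 - identity_pct / 100))
  anno <- template_annotated_positions(tmpl)
  bg <- setdiff(seq_len(L), anno)
  with_seed(seed, {
    pos <- if (n_mut <= length(bg)) {
      sample(bg, n_mut)
    } else {
      c(bg, sample(anno, n_mut - length(bg)))
    }
    s <- mutate_positions(tmpl$sequence, pos)
    out <- tibble(id = paste0(subfamily, "_id", identity_pct),
                  sequence = s, subfamily = subfamily)
    attr(out, "template") <- tmpl$sequence
    out
  })
}

#' Simulate a codon-sequence pair under a planted omega
#'
#' Samples an ancestor uniformly over sense codons, then evolves a
#' descendant by proposing uniform single-nucleotide changes (never
#' creating a stop codon): synonymous proposals are always accepted,
#' nonsynonymous ones with probability `omega`, until the accepted
#' synonymous changes reach the count implied by `ks_target` on the
#' ancestor's synonymous sites.
#'
#' @param n_codons Number of codons.
#' @param omega Planted Ka/Ks (> 0).
#' @param ks_target Target synonymous divergence (substitutions per
#'   synonymous site, before correction removal; must satisfy the
#'   Jukes-Cantor domain).
#' @param seed Integer seed.
#' @return A list: `cds_a`, `cds_b` (character), and `truth` with planted
#'   `omega`, realized accepted synonymous/nonsynonymous change counts and
#'   the ancestor's synonymous site count.
#' @export
sim_cds_pair <- function(n_codons, omega, ks_target = 0.3, seed = 1) {
  if (omega <= 0) abort("omega must be positive")
  p_s <- 0.75 * (1 - exp(-4 * ks_target / 3))
  if (p_s >= 0.7) {
    abort("ks_target outside the reliably correctable range at this length")
  }
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  sst <- syn_site_table()
  with_seed(seed, {
    anc <- sample(sense, n_codons, replace = TRUE)
    S <- sum(sst[anc])
    target_syn <- max(1, round(p_s * S))
    cur <- anc
    n_syn <- 0; n_nonsyn <- 0
    max_iter <- 4000 * n_codons
    iter <- 0
    nts <- c("A", "C", "G", "T")
    while (n_syn < target_syn) {
      iter <- iter + 1
      if (iter > max_iter) abort("ks_target unreachable at this length")
      ci <- sample.int(n_codons, 1)
      pos <- sample.int(3, 1)
      old <- cur[ci]
      nt <- sample(setdiff(nts, substr(old, pos, pos)), 1)
      new <- old
      substr(new, pos, pos) <- nt
      if (gc[[new]] == "*") next
      if (gc[[new]] == gc[[old]]) {
        cur[ci] <- new
        n_syn <- n_syn + 1
      } else if (stats::runif(1) < omega) {
        cur[ci] <- new
        n_nonsyn <- n_nonsyn + 1
      }
    }
    list(cds_a = paste(anc, collapse = ""),
         cds_b = paste(cur, collapse = ""),
         truth = tibble(omega = omega, ks_target = ks_target,
                        n_syn_changes = n_syn, n_nonsyn_changes = n_nonsyn,
                        syn_sites_ancestor = S))
  })
}

#' Simulate an annotated chromosome set with planted tandem arrays
#'
#' Lays genes along chromosomes with random spacing, gives every gene a
#' random protein, then plants tandem arrays of near-identical proteins in
#' adjacent genes. Planted negatives each violate exactly one clause of the
#' tandem rule: a `span` negative is an identical pair placed beyond the
#' 100 kb window, an `intervening` negative has too many genes between the
#' copies, and an `identity` negative is an adjacent pair mutated below the
#' identity threshold.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome.
#' @param tandem_arrays Tibble with columns `chrom` (1-based index) and
#'   `n_copies`; each array is planted at a random location.
#' @param negatives Character vector drawn from
#'   `c("span", "intervening", "identity")`.
#' @param protein_len Length of the simulated proteins.
#' @param mean_gap_bp Mean intergenic gap.
#' @param gene_span_bp Genomic span of each gene.
#' @return A list: `models` (gene-model tibble), `proteins`, and
#'   `truth_pairs` (tibble `gene_a`, `gene_b`, `kind` in
#'   `c("tandem", negatives)`).
#' @export
sim_annotation <- function(seed = 1, n_chrom = 2, genes_per_chrom = 40,
                           tandem_arrays = tibble(chrom = 1, n_copies = 3),
                           negatives = character(),
                           protein_len = 120, mean_gap_bp = 15000,
                           gene_span_bp = 3000) {
  with_seed(seed, {
    models <- list(); prot <- list(); truth <- list()
    gid <- function(c, i) sprintf("chr%02d_g%03d", c, i)
    for (c in seq_len(n_chrom)) {
      gaps <- pmax(200, round(stats::rexp(genes_per_chrom, 1 / mean_gap_bp)))
      starts <- cumsum(gaps + gene_span_bp) - gene_span_bp
      for (i in seq_len(genes_per_chrom)) {
        id <- gid(c, i)
        models[[id]] <- tibble(
          gene_id = id, chrom = sprintf("Chr%02d", c),
          start = starts[i], end = starts[i] + gene_span_bp - 1,
          strand = sample(c("+", "-"), 1),
          transcript_id = paste0(id, ".1"),
          exons = list(tibble(start = starts[i],
                              end = starts[i] + gene_span_bp - 1))
        )
        prot[[id]] <- tibble(
          id = id,
          sequence = paste(sample(AA_ALPHABET20, protein_len, TRUE),
                           collapse = ""))
      }
    }
    # plant positive arrays: consecutive genes share a protein (~96% id)
    if (nrow(tandem_arrays) > 0) {
      for (a in seq_len(nrow(tandem_arrays))) {
        c <- tandem_arrays$chrom[a]
        k <- tandem_arrays$n_copies[a]
        at <- sample(seq_len(genes_per_chrom - k + 1), 1)
        base <- paste(sample(AA_ALPHABET20, protein_len, TRUE), collapse = "")
        ids <- gid(c, at:(at + k - 1))
        for (id in ids) {
          nm <- max(1, round(0.04 * protein_len))
          prot[[id]]$sequence <- mutate_positions(
            base, sample.int(protein_len, nm))
        }
        cmb <- utils::combn(ids, 2)
        for (p in seq_len(ncol(cmb))) {
          truth[[length(truth) + 1]] <- tibble(
            gene_a = cmb[1, p], gene_b = cmb[2, p], kind = "tandem")
        }
      }
    }
    models <- bind_rows(models)
    # planted negatives, one rule clause violated each
    for (neg in negatives) {
      base <- paste(sample(AA_ALPHABET20, protein_len, TRUE), collapse = "")
      if (neg == "span") {
        c <- n_chrom + 1
        m <- tibble(
          gene_id = c(gid(c, 1), gid(c, 2)), chrom = sprintf("Chr%02d", c),
          start = c(1000, 1000 + gene_span_bp + 150000),
          end = c(1000, 1000 + gene_span_bp + 150000) + gene_span_bp - 1,
          strand = "+", transcript_id = paste0(gid(c, 1:2), ".1"),
          exons = map2(c(1000, 1000 + gene_span_bp + 150000),
                       c(1000, 1000 + gene_span_bp + 150000) + gene_span_bp - 1,
                       function(s, e) tibble(start = s, end = e)))
        models <- bind_rows(models, m)
        for (id in m$gene_id) prot[[id]] <- tibble(id = id, sequence = base)
        truth[[length(truth) + 1]] <- tibble(
          gene_a = m$gene_id[1], gene_b = m$gene_id[2], kind = "span")
      } else if (neg == "intervening") {
        c <- n_chrom + 2
        n <- 8  # copies at the ends, 6 unrelated genes between
        starts <- 1000 + (seq_len(n) - 1) * (gene_span_bp + 2000)
        ids <- gid(c, seq_len(n))
        m <- tibble(
          gene_id = ids, chrom = sprintf("Chr%02d", c),
          start = starts, end = starts + gene_span_bp - 1,
          strand = "+", transcript_id = paste0(ids, ".1"),
          exons = map2(starts, starts + gene_span_bp - 1,
                       function(s, e) tibble(start = s, end = e)))
        models <- bind_rows(models, m)
        for (i in seq_len(n)) {
          s <- if (i %in% c(1, n)) base else
            paste(sample(AA_ALPHABET20, protein_len, TRUE), collapse = "")
          prot[[ids[i]]] <- tibble(id = ids[i], sequence = s)
        }
        truth[[length(truth) + 1]] <- tibble(
          gene_a = ids[1], gene_b = ids[n], kind = "intervening")
      } else if (neg == "identity") {
        c <- n_chrom + 3
        starts <- c(1000, 1000 + gene_span_bp + 2000)
        ids <- gid(c, 1:2)
        m <- tibble(
          gene_id = ids, chrom = sprintf("Chr%02d", c),
          start = starts, end = starts + gene_span_bp - 1,
          strand = "+", transcript_id = paste0(ids, ".1"),
          exons = map2(starts, starts + gene_span_bp - 1,
                       function(s, e) tibble(start = s, end = e)))
        models <- bind_rows(models, m)
        prot[[ids[1]]] <- tibble(id = ids[1], sequence = base)
        prot[[ids[2]]] <- tibble(
          id = ids[2],
          sequence = mutate_positions(
            base, sample.int(protein_len, round(0.45 * protein_len))))
        truth[[length(truth) + 1]] <- tibble(
          gene_a = ids[1], gene_b = ids[2], kind = "identity")
      }
    }
    list(models = arrange(models, .data$chrom, .data$start),
         proteins = bind_rows(prot),
         truth_pairs = bind_rows(truth))
  })
}

#' Simulate expression matrices with planted classes
#'
#' Tissue panel: genes planted as `high_all_tissues` (20-100 FPKM
#' everywhere), `tissue_specific` (high in one sample, near-zero
#' elsewhere) or `low_all` (< 5 everywhere), under multiplicative
#' log-normal noise. Salt time course: planted `induced` (fold reached at a
#' planted peak time), `repressed`, `unchanged` and `low_expression` genes
#' against a flat control series.
#'
#' @param seed Integer seed.
#' @param n_per_class Named counts for the tissue panel, e.g.
#'   `c(high_all_tissues = 5, tissue_specific = 5, low_all = 5)`.
#' @param n_samples Number of tissue samples.
#' @param salt_classes Named counts for the time course, e.g.
#'   `c(induced = 5, repressed = 3, unchanged = 3, low_expression = 2)`.
#' @param timepoints Hours of the salt time course.
#' @param fold Planted fold change for induced/repressed genes.
#' @param peak_time Planted peak hour for induced genes (drawn from
#'   `timepoints` when `NULL`).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @return A list: `tissue` (`fpkm_matrix`), `tissue_truth`, `salt`
#'   (long profile tibble with `control`), `salt_truth`.
#' @export
sim_expression <- function(seed = 1,
                           n_per_class = c(high_all_tissues = 5,
                                           tissue_specific = 5, low_all = 5),
                           n_samples = 7,
                           salt_classes = c(induced = 5, repressed = 3,
                                            unchanged = 3, low_expression = 2),
                           timepoints = c(12, 24, 48),
                           fold = 8, peak_time = NULL, noise_cv = 0.1) {
  sigma <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    noisy <- function(x) x * exp(stats::rnorm(length(x), 0, sigma))
    rows <- list(); ttruth <- list()
    g <- 0
    for (cls in names(n_per_class)) {
      for (i in seq_len(n_per_class[[cls]])) {
        g <- g + 1
        id <- sprintf("tg%03d", g)
        base <- switch(cls,
          high_all_tissues = stats::runif(n_samples, 20, 100),
          tissue_specific = {
            v <- stats::runif(n_samples, 0, 0.5)
            v[sample.int(n_samples, 1)] <- stats::runif(1, 40, 90)
            v
          },
          low_all = stats::runif(n_samples, 0, 2))
        rows[[id]] <- c(gene_id = id, setNames(noisy(base),
                                               paste0("s", seq_len(n_samples))))
        ttruth[[id]] <- tibble(gene_id = id, class = cls)
      }
    }
    tissue <- as_tibble(do.call(rbind, rows))
    tissue <- mutate(tissue, across(-"gene_id", as.numeric))
    tissue <- as_fpkm_matrix(tissue)

    srows <- list(); struth <- list()
    g <- 0
    for (cls in names(salt_classes)) {
      for (i in seq_len(salt_classes[[cls]])) {
        g <- g + 1
        id <- sprintf("sg%03d", g)
        ctl <- rep(10, length(timepoints))
        pk <- if (!is.null(peak_time)) peak_time else sample(timepoints, 1)
        tr <- switch(cls,
          induced = ifelse(timepoints == pk, 10 * fold, 10 * 1.2),
          repressed = ifelse(timepoints == pk, 10 / fold, 10 / 1.1),
          unchanged = rep(10 * 1.05, length(timepoints)),
          low_expression = {
            ctl <- rep(1, length(timepoints))
            rep(1.5, length(timepoints))
          })
        srows[[id]] <- tibble(gene_id = id, timepoint = timepoints,
                              treated = noisy(tr), control = noisy(ctl))
        struth[[id]] <- tibble(
          gene_id = id, class = cls,
          peak_time = if (cls == "induced") pk else NA_real_)
      }
    }
    list(tissue = tissue, tissue_truth = bind_rows(ttruth),
         salt = bind_rows(srows), salt_truth = bind_rows(struth))
  })
}

#' Simulate a replicated qPCR Ct table with planted fold changes
#'
#' The reference gene sits at a constant Ct; the target's treated Ct is
#' shifted by `-log2(fold)` relative to the control sample, so the planted
#' 2^-ddCt fold is exact up to replicate noise (normal, `sd_ct` cycles).
#'
#' @param seed Integer seed.
#' @param folds Named numeric vector of planted folds per gene.
#' @param n_replicates Replicates per (gene, sample).
#' @param sd_ct Replicate noise SD in cycles.
#' @return A list: `records` (tibble for [delta_delta_ct()] with samples
#'   `control` and `treated`) and `truth` (planted folds).
#' @export
sim_ct <- function(seed = 1, folds = c(gene1 = 4), n_replicates = 3,
                   sd_ct = 0.15) {
  with_seed(seed, {
    rows <- list()
    for (gn in names(folds)) {
      for (smp in c("control", "treated")) {
        mu_t <- if (smp == "control") 24 else 24 - log2(folds[[gn]])
        rows[[paste(gn, smp)]] <- tibble(
          gene_id = gn, sample_id = smp, condition = smp,
          replicate = seq_len(n_replicates),
          ct_target = mu_t + stats::rnorm(n_replicates, 0, sd_ct),
          ct_reference = 20 + stats::rnorm(n_replicates, 0, sd_ct))
      }
    }
    list(records = bind_rows(rows),
         truth = tibble(gene_id = names(folds), fold = unname(folds)))
  })
}

#' Simulate an alignment with planted clades
#'
#' A root sequence is mutated into one ancestor per group
#' (`between_divergence`), then into each group member
#' (`within_divergence`), producing an ungapped alignment whose true
#' groups are recoverable as clades.
#'
#' @param seed Integer seed.
#' @param groups Named integer vector of taxa per group.
#' @param length Alignment length (columns).
#' @param between_divergence,within_divergence Fraction of positions
#'   mutated on the corresponding branches.
#' @return A list: `msa` (tibble `id`, `sequence`, `group`) and `groups`
#'   (named list of tip labels per group).
#' @export
sim_alignment <- function(seed = 1, groups = c(A = 3, B = 3), length = 300,
                          between_divergence = 0.3,
                          within_divergence = 0.05) {
  with_seed(seed, {
    root <- paste(sample(AA_ALPHABET20, length, TRUE), collapse = "")
    rows <- list(); glist <- list()
    for (gname in names(groups)) {
      anc <- mutate_positions(
        root, sample.int(length, round(between_divergence * length)))
      tips <- sprintf("%s_t%02d", gname, seq_len(groups[[gname]]))
      for (tp in tips) {
        rows[[tp]] <- tibble(
          id = tp,
          sequence = mutate_positions(
            anc, sample.int(length, round(within_divergence * length))),
          group = gname)
      }
      glist[[gname]] <- tips
    }
    list(msa = bind_rows(rows), groups = glist)
  })
}
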