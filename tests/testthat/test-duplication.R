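make_two_gene_chrom <- function(gap_bp, protein_b = NULL, len = 80) {
  base <- random_protein(len, seed = 11)
  models <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "Chr1",
    start = c(1000, 1000 + 2000 + gap_bp),
    end = c(1000 + 1999, 1000 + 2000 + gap_bp + 1999))
  proteins <- tibble::tibble(
    id = c("gA", "gB"),
    sequence = c(base, if (is.null(protein_b)) base else protein_b))
  list(models = models, proteins = proteins)
}

test_that("tandem rule: adjacent identical genes pair, distant ones do not", {
  near <- make_two_gene_chrom(gap_bp = 5000)
  p <- find_tandem_pairs(near$models, near$proteins)
  expect_equal(nrow(p), 1)
  expect_equal(p$gene_a, "gA")
  expect_equal(p$dup_type, "tandem")

  far <- make_two_gene_chrom(gap_bp = 150000)
  expect_equal(nrow(find_tandem_pairs(far$models, far$proteins)), 0)
})

test_that("planted negatives each fail exactly one clause of the tandem rule", {
  ann <- sim_annotation(seed = 21, n_chrom = 1, genes_per_chrom = 15,
                        tandem_arrays = tibble::tibble(chrom = 1, n_copies = 2),
                        negatives = c("span", "intervening", "identity"))
  found <- suppressWarnings(find_tandem_pairs(ann$models, ann$proteins))
  truth <- ann$truth_pairs
  pos <- truth[truth$kind == "tandem", ]
  neg <- truth[truth$kind != "tandem", ]
  found_keys <- pair_key(found)
  expect_true(all(pair_key(pos) %in% found_keys))
  expect_false(any(pair_key(neg) %in% found_keys))
})

test_that("tandem detection equals the brute-force all-pairs filter", {
  for (seed in 1:5) {
    ann <- sim_annotation(seed = 300 + seed, n_chrom = 2,
                          genes_per_chrom = 20,
                          tandem_arrays = tibble::tibble(chrom = 1:2,
                                                         n_copies = c(3, 2)),
                          negatives = c("span", "identity"))
    fast <- suppressWarnings(find_tandem_pairs(ann$models, ann$proteins))
    slow <- brute_tandem_oracle(ann$models, ann$proteins)
    expect_equal(pair_key(fast), pair_key(slow))
  }
})

test_that("missing protein sequences skip the pair with a warning", {
  near <- make_two_gene_chrom(gap_bp = 5000)
  expect_warning(
    p <- find_tandem_pairs(near$models, near$proteins[1, ]),
    "skipped")
  expect_equal(nrow(p), 0)
})

test_that("NG86 on identical sequences gives zero rates and undefined omega", {
  pr <- sim_cds_pair(50, omega = 0.5, ks_target = 0.2, seed = 1)
  r <- ng86_kaks(pr$cds_a, pr$cds_a)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$omega))
})

test_that("synonymous-only differences give Ka = 0 and Ks > 0", {
  # third-position changes at four-fold degenerate codons; the enumeration
  # oracle confirms every difference is synonymous
  a <- "CCTGGAACTGTACAT"
  b <- "CCCGGGACTGTACAT"
  orc <- ng86_oracle(a, b)
  expect_equal(orc$Nd, 0)
  expect_gt(orc$Sd, 0)
  r <- ng86_kaks(a, b)
  expect_equal(r$ka, 0)
  expect_gt(r$ks, 0)
  expect_equal(r$omega, 0)
  expect_equal(r$ks, orc$ks, tolerance = 1e-12)
})

test_that("NG86 matches the path-enumeration oracle on simulated pairs", {
  for (seed in c(5, 6, 7)) {
    pr <- sim_cds_pair(40, omega = 0.6, ks_target = 0.4, seed = seed)
    r <- ng86_kaks(pr$cds_a, pr$cds_b)
    orc <- ng86_oracle(pr$cds_a, pr$cds_b)
    expect_equal(r$ka, orc$ka, tolerance = 1e-10)
    expect_equal(r$ks, orc$ks, tolerance = 1e-10)
  }
})

test_that("NG86 is symmetric in its arguments", {
  for (seed in c(2, 3)) {
    pr <- sim_cds_pair(60, omega = 0.4, ks_target = 0.3, seed = seed)
    ab <- ng86_kaks(pr$cds_a, pr$cds_b)
    ba <- ng86_kaks(pr$cds_b, pr$cds_a)
    expect_equal(ab$ka, ba$ka, tolerance = 1e-12)
    expect_equal(ab$ks, ba$ks, tolerance = 1e-12)
  }
})

test_that("adding synonymous-only mutations never increases Ka", {
  # glycine GGA -> GGG changes keep each codon's synonymous site count, so
  # only Sd moves
  a <- "ATGGGAGGACCTACTGTACGTAAACAT"
  b1 <- sub("AAACAT$", "AGACAT", a)          # one nonsynonymous change
  b2 <- gsub("GGA", "GGG", b1)               # plus two synonymous changes
  r1 <- ng86_kaks(a, b1)
  r2 <- ng86_kaks(a, b2)
  expect_equal(r2$ka, r1$ka, tolerance = 1e-12)
  expect_gt(r2$ks, r1$ks)
})

test_that("codons with gaps or ambiguity are excluded from the counts", {
  r <- ng86_kaks("ATGNAACCC", "ATGAAACCC")
  expect_equal(r$n_codons_used, 2L)
  # stop codons excluded entirely
  r2 <- ng86_kaks("ATGTAACCC", "ATGTAACCC")
  expect_equal(r2$n_codons_used, 2L)
})

test_that("protein-guided codon alignment handles unequal lengths", {
  a <- "ATGAAATTTGGGCCC"
  b <- "ATGAAAGGGCCC"  # codon 2 (AAA->) with TTT deleted
  r <- ng86_kaks(a, b)
  expect_equal(r$n_codons_used, 4L)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
})

test_that("selection classification follows the omega bands", {
  expect_equal(classify_selection(c(0.023, 0.685, 1, 1.2, NA)),
               c("purifying", "purifying", "neutral~1", "positive", NA))
  expect_equal(classify_selection(0.97), "neutral~1")
  expect_equal(classify_selection(0.97, neutral_band = 0.01), "purifying")
})

test_that("segmental pair loading validates ids and recomputes Ka/Ks", {
  f <- write_tmp_lines(c("gene_a\tgene_b\tka\tks",
                         "g1\tg2\t0.1\t0.5",
                         "g1\tg3\t0.2\t0.4"), ".tsv")
  pairs <- load_segmental_pairs(f)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$dup_type, rep("segmental", 2))
  expect_equal(pairs$omega, c(0.2, 0.5))
  expect_equal(pairs$selection, c("purifying", "purifying"))

  models <- tibble::tibble(gene_id = c("g1", "g2"))
  expect_warning(known <- load_segmental_pairs(f, models = models),
                 "unknown gene ids")
  expect_equal(nrow(known), 1)

  empty <- write_tmp_lines("gene_a\tgene_b", ".tsv")
  expect_equal(nrow(load_segmental_pairs(empty)), 0)

  pr <- sim_cds_pair(40, omega = 0.3, ks_target = 0.3, seed = 2)
  cds <- tibble::tibble(id = c("g1", "g2"),
                        sequence = c(pr$cds_a, pr$cds_b))
  f2 <- write_tmp_lines(c("gene_a\tgene_b", "g1\tg2"), ".tsv")
  rec <- load_segmental_pairs(f2, cds = cds)
  expect_equal(rec$ka, ng86_kaks(pr$cds_a, pr$cds_b)$ka)
})

test_that("planted purifying pairs are recovered as omega < 1", {
  est <- vapply(1:10, function(i) {
    pr <- sim_cds_pair(300, omega = 0.3, ks_target = 0.3, seed = 400 + i)
    ng86_kaks(pr$cds_a, pr$cds_b)$omega
  }, numeric(1))
  expect_equal(mean(est), 0.3, tolerance = 0.15)
  expect_true(all(classify_selection(est) == "purifying"))
})
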