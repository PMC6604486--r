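test_that("read_fasta parses records, preserves order and uppercases", {
  f <- write_tmp_lines(c(">a water channel", "npa", ">b", "MKV"), ".fa")
  recs <- read_fasta(f, "protein")
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$sequence, c("NPA", "MKV"))
  expect_equal(recs$description, c("water channel", ""))

  empty <- write_tmp_lines(character(), ".fa")
  expect_equal(nrow(read_fasta(empty, "protein")), 0)
})

test_that("read_fasta rejects duplicate ids and illegal characters", {
  f <- write_tmp_lines(c(">a", "MKV", ">a", "MKL"), ".fa")
  expect_error(read_fasta(f, "protein"), "duplicate.*a")

  g <- write_tmp_lines(c(">z", "MKB"), ".fa")
  expect_error(read_fasta(g, "protein"), "illegal.*position 3")

  d <- write_tmp_lines(c(">z", "ACGU"), ".fa")
  expect_error(read_fasta(d, "dna"), "illegal")
})

test_that("FASTA write/read round-trips simulated proteins losslessly", {
  sp <- sim_proteins(c(PIP = 3, NIP = 2), divergence_pct = 10, seed = 5)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(dplyr::mutate(sp$proteins, description = ""), f)
  back <- read_fasta(f, "protein")
  expect_equal(back$id, sp$proteins$id)
  expect_equal(back$sequence, sp$proteins$sequence)
})

test_that("read_gff3 builds gene models from the gene/mRNA/exon hierarchy", {
  g <- tibble::tibble(
    gene_id = "g1", chrom = "Chr1", start = 1L, end = 300L,
    exons = list(tibble::tibble(start = c(1L, 201L), end = c(100L, 300L))))
  f <- write_tmp_lines(gff3_lines(g), ".gff3")
  models <- read_gff3(f)
  expect_equal(nrow(models), 1)
  expect_equal(nrow(models$exons[[1]]), 2)
  expect_equal(models$exons[[1]]$start, c(1, 201))
})

test_that("representative transcript is the longest-spliced isoform", {
  lines <- c(
    "##gff-version 3",
    "Chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "Chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=t.short;Parent=g1",
    "Chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t.short",
    "Chr1\tsrc\texon\t201\t250\t.\t+\t.\tParent=t.short",
    "Chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=t.long;Parent=g1",
    "Chr1\tsrc\texon\t1\t150\t.\t+\t.\tParent=t.long",
    "Chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t.long",
    "Chr1\tsrc\texon\t501\t600\t.\t+\t.\tParent=t.long")
  f <- write_tmp_lines(lines, ".gff3")
  models <- read_gff3(f)
  expect_equal(models$transcript_id, "t.long")
  expect_equal(nrow(models$exons[[1]]), 3)
})

test_that("read_gff3 reports malformed lines and broken hierarchy", {
  bad <- c("##gff-version 3",
           "Chr1\tsrc\tgene\t1\t100\t.\t+\tID=g1")  # 8 columns
  f <- write_tmp_lines(bad, ".gff3")
  expect_error(read_gff3(f), "line 2.*9")

  rev_coord <- c("##gff-version 3",
                 "Chr1\tsrc\tgene\t100\t1\t.\t+\t.\tID=g1")
  f2 <- write_tmp_lines(rev_coord, ".gff3")
  expect_error(read_gff3(f2), "end < start")

  orphan <- c("##gff-version 3",
              "Chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
              "Chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=nowhere")
  f3 <- write_tmp_lines(orphan, ".gff3")
  expect_error(read_gff3(f3), "nowhere")
})

test_that("GFF3 parsing is insensitive to feature-line order", {
  g <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "Chr1",
    start = c(1L, 1000L), end = c(500L, 1600L),
    exons = list(tibble::tibble(start = c(1L, 301L), end = c(100L, 500L)),
                 tibble::tibble(start = 1000L, end = 1600L)))
  lines <- gff3_lines(g)
  body <- lines[-1]
  shuffled <- c(lines[1], withr::with_seed(42, sample(body)))
  m1 <- read_gff3(write_tmp_lines(lines, ".gff3"))
  m2 <- read_gff3(write_tmp_lines(shuffled, ".gff3"))
  expect_equal(m1, m2)
})

test_that("expression matrix reader validates shape and sign", {
  f <- write_tmp_lines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), ".tsv")
  m <- read_expression_matrix(f)
  expect_s3_class(m, "fpkm_matrix")
  expect_equal(m$gene_id, c("g1", "g2"))
  expect_false(is_normalized(m))

  neg <- write_tmp_lines(c("gene\ts1", "g1\t-1"), ".tsv")
  expect_error(read_expression_matrix(neg), "negative")

  ragged <- write_tmp_lines(c("gene\ts1\ts2", "g1\t1"), ".tsv")
  expect_error(read_expression_matrix(ragged), "ragged")
})

test_that("expression matrix TSV round-trip is stable", {
  ex <- sim_expression(seed = 2)$tissue
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(ex, f)
  back <- read_expression_matrix(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ex),
               tolerance = 1e-12)
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  tr <- ape::read.tree(text = "((a:1,b:2)90:0.5,(c:1.5,d:0.25)80:0.75);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  expect_equal(back$node.label, tr$node.label)
})

test_that("GFF3 writer round-trips canonical gene models", {
  ann <- sim_annotation(seed = 8, n_chrom = 1, genes_per_chrom = 6,
                        tandem_arrays = tibble::tibble(chrom = integer(),
                                                       n_copies = integer()))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann$models, f)
  back <- read_gff3(f)
  expect_equal(back$gene_id, ann$models$gene_id)
  expect_equal(back$start, ann$models$start)
  expect_equal(purrr::map(back$exons, "start"),
               purrr::map(ann$models$exons, "start"))
})
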