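test_that("log2(FPKM+1) follows its closed form and refuses double transforms", {
  m <- as_fpkm_matrix(tibble::tibble(gene_id = c("a", "b", "c"),
                                     s1 = c(0, 7, 1023)))
  n <- normalize_log2(m)
  expect_equal(n$s1, c(0, 3, 10))
  expect_true(is_normalized(n))
  expect_error(normalize_log2(n), "already")
})

test_that("normalization is strictly monotone per gene", {
  vals <- withr::with_seed(1, sort(stats::runif(20, 0, 500)))
  m <- as_fpkm_matrix(tibble::tibble(gene_id = "g",
                                     !!!setNames(as.list(vals),
                                                 paste0("s", 1:20))))
  n <- unlist(normalize_log2(m)[1, -1])
  expect_true(all(diff(n) > 0))
})

test_that("identical rows merge first and clustering is order-invariant", {
  m <- as_fpkm_matrix(tibble::tibble(
    gene_id = c("twin1", "twin2", "far"),
    s1 = c(1, 1, 50), s2 = c(2, 2, 1), s3 = c(3, 3, 80)))
  cl <- hierarchical_cluster(m, metric = "euclidean")
  first_merge <- cl$hclust$merge[1, ]
  expect_equal(sort(cl$hclust$labels[-first_merge]), c("twin1", "twin2"))

  perm <- c(3, 1, 2)
  cl2 <- hierarchical_cluster(m[perm, ], metric = "euclidean")
  co1 <- stats::cophenetic(cl$hclust)
  co2 <- stats::cophenetic(cl2$hclust)
  ids <- c("twin1", "twin2", "far")
  expect_equal(as.matrix(co1)[ids, ids], as.matrix(co2)[ids, ids])
})

test_that("planted co-expression blocks are recovered at k = 2", {
  blockA <- c(10, 10, 1, 1)
  blockB <- c(1, 1, 10, 10)
  noisy <- function(base, seed) {
    withr::with_seed(seed, base * exp(stats::rnorm(4, 0, 0.05)))
  }
  rows <- rbind(t(sapply(1:5, function(i) noisy(blockA, i))),
                t(sapply(6:10, function(i) noisy(blockB, i))))
  m <- as_fpkm_matrix(tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    s1 = rows[, 1], s2 = rows[, 2], s3 = rows[, 3], s4 = rows[, 4]))
  cl <- hierarchical_cluster(m, metric = "correlation")
  cut <- cut_clusters(cl, 2)
  expect_equal(dplyr::n_distinct(cut$cluster[1:5]), 1)
  expect_equal(dplyr::n_distinct(cut$cluster[6:10]), 1)
  expect_false(cut$cluster[1] == cut$cluster[6])
})

test_that("zero-variance rows get maximal correlation distance, not NaN", {
  m <- as_fpkm_matrix(tibble::tibble(gene_id = c("flat", "var1", "var2"),
                                     s1 = c(5, 1, 2), s2 = c(5, 2, 4),
                                     s3 = c(5, 3, 6)))
  cl <- hierarchical_cluster(m)
  expect_false(any(is.na(stats::cophenetic(cl$hclust))))
  # the correlated pair merges first; the flat gene joins last
  expect_equal(sort(cl$hclust$merge[1, ]), c(-3, -2))
})

test_that("expression breadth classes follow the threshold rules", {
  m <- as_fpkm_matrix(tibble::tibble(
    gene_id = c("ubiq", "silent", "specific", "broad"),
    !!!setNames(as.list(rep(0, 10)), paste0("s", 1:10))))
  vals <- rbind(rep(10, 10), rep(0, 10),
                c(50, rep(0, 9)), c(rep(20, 6), rep(0, 4)))
  for (j in 1:10) m[[paste0("s", j)]] <- vals[, j]
  fl <- flag_expression_class(m)
  expect_equal(fl$class,
               c("high_all_tissues", "low_all", "tissue_specific", "mixed"))
})

test_that("breadth flags are invariant under sample-column permutation", {
  ex <- sim_expression(seed = 14)$tissue
  f1 <- flag_expression_class(ex)
  perm <- c("gene_id", withr::with_seed(2, sample(setdiff(names(ex),
                                                          "gene_id"))))
  f2 <- flag_expression_class(as_fpkm_matrix(ex[, perm]))
  expect_equal(f1, f2)
})

test_that("salt-response rules: induction, repression, floors and peaks", {
  p <- tibble::tibble(gene_id = "g", timepoint = c(12, 24, 48),
                      treated = c(5, 40, 20), control = c(5, 5, 5))
  r <- classify_salt_response(p)
  expect_equal(r$direction, "induced")
  expect_equal(r$peak_time, 24)

  flat <- tibble::tibble(gene_id = "g", timepoint = c(12, 24),
                         treated = c(8, 8), control = c(8, 8))
  expect_equal(classify_salt_response(flat)$direction, "unchanged")

  low <- tibble::tibble(gene_id = "g", timepoint = c(12, 24),
                        treated = c(1, 2), control = c(1, 1))
  expect_equal(classify_salt_response(low)$direction, "low_expression")
  expect_true(is.na(classify_salt_response(low)$peak_time))

  single <- tibble::tibble(gene_id = "g", timepoint = 12,
                           treated = 5, control = 5)
  expect_error(classify_salt_response(single), "two timepoints")
})

test_that("peak ties resolve to the earliest timepoint", {
  p <- tibble::tibble(gene_id = "g", timepoint = c(12, 24, 48),
                      treated = c(40, 40, 10), control = c(5, 5, 5))
  expect_equal(classify_salt_response(p)$peak_time, 12)
})

test_that("raising the fold threshold never grows the induced set", {
  ex <- sim_expression(seed = 25, salt_classes = c(induced = 6,
                                                   repressed = 4,
                                                   unchanged = 4,
                                                   low_expression = 2))
  n_induced <- vapply(c(1.5, 2, 4, 8, 16), function(f) {
    sum(classify_salt_response(ex$salt, fold = f)$direction == "induced")
  }, integer(1))
  expect_true(all(diff(n_induced) <= 0))
})

test_that("planted salt classes and peak times are recovered", {
  ex <- sim_expression(seed = 31, peak_time = 24)
  r <- classify_salt_response(ex$salt)
  joined <- dplyr::left_join(ex$salt_truth, r, by = "gene_id")
  expect_equal(joined$direction, joined$class)
  ind <- joined[joined$class == "induced", ]
  expect_true(all(ind$peak_time.y == 24))
})

test_that("peak-time bias summarizes ortholog shifts", {
  mkprof <- function(ids, peak) {
    tidyr::crossing(gene_id = ids, timepoint = c(12, 24, 48)) |>
      dplyr::mutate(control = 10,
                    treated = ifelse(timepoint == peak, 80, 12))
  }
  a <- mkprof(c("a1", "a2"), 24)
  b <- mkprof(c("b1", "b2"), 48)
  pairs <- tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  res <- peak_time_bias(a, b, pairs)
  expect_equal(res$pairs$delta_peak, c(24, 24))
  expect_equal(res$summary$median_delta_peak, 24)

  res0 <- peak_time_bias(a, a, tibble::tibble(gene_a = "a1", gene_b = "a2"))
  expect_equal(res0$pairs$delta_peak, 0)

  # A falling 12->24 while B rising: opposite early-phase sign
  a_fall <- tibble::tibble(gene_id = "af", timepoint = c(12, 24, 48),
                           treated = c(30, 10, 40), control = 10)
  b_rise <- tibble::tibble(gene_id = "br", timepoint = c(12, 24, 48),
                           treated = c(10, 30, 15), control = 10)
  res2 <- peak_time_bias(a_fall, b_rise,
                         tibble::tibble(gene_a = "af", gene_b = "br"))
  expect_equal(res2$summary$n_opposite_early, 1)
})
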