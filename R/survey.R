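#' Run the full aquaporin family survey
#'
#' Orchestrates the pipeline over a declarative configuration: candidate
#' screening, nomenclature, motif profiling, exon/intron structure, tandem
#' duplication and Ka/Ks, optionally a bootstrapped NJ tree and expression
#' classification. All thresholds surface as configuration keys with the
#' survey's standard values as defaults. Any missing input file aborts
#' before computation; a stage failure aborts with the stage name. The
#' result is reproducible bit-identically from (config, seed).
#'
#' @param config Named list (or path to a `key = value` text file) with
#'   input paths `proteome`, `refs`, `gff` (required), `cds`,
#'   `expression`, `salt`, `segmental_pairs`, `msa` (optional), and
#'   thresholds `min_identity` (30), `min_coverage` (50),
#'   `family_identity` (40), `subfamily_identity` (60),
#'   `tandem_max_intervening` (5), `tandem_max_span` (1e5),
#'   `tandem_min_identity` (70), `fpkm_threshold` (5), `fold` (2),
#'   `bootstrap` (1000), `name_prefix` ("").
#' @param seed Integer seed for the bootstrap stage.
#' @param out_dir Optional directory; when given, the report tables are
#'   written there as TSV + JSON via [write_report()].
#' @return A `mip_survey` object: list with `genes` (the per-gene report
#'   tibble), `tables` (stage outputs) and `metadata`.
#' @export
run_survey <- function(config, seed = 1, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_survey_config(config)
  }
  defaults <- list(min_identity = 30, min_coverage = 50,
                   family_identity = 40, subfamily_identity = 60,
                   tandem_max_intervening = 5, tandem_max_span = 1e5,
                   tandem_min_identity = 70, fpkm_threshold = 5, fold = 2,
                   bootstrap = 1000, name_prefix = "")
  cfg <- utils::modifyList(defaults, config)
  required <- c("proteome", "refs", "gff")
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0) {
    abort(paste0("configuration missing required key(s): ",
                 paste(miss, collapse = ", ")))
  }
  paths <- cfg[intersect(names(cfg),
                         c("proteome", "refs", "gff", "cds", "expression",
                           "salt", "segmental_pairs", "msa"))]
  absent <- unlist(paths)[!file.exists(unlist(paths))]
  if (length(absent) > 0) {
    abort(paste0("input file(s) not found: ", paste(absent, collapse = ", ")))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("survey stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  proteome <- stage("read", read_fasta(cfg$proteome, "protein"))
  refs <- stage("read", read_fasta(cfg$refs, "protein"))
  models <- stage("read", read_gff3(cfg$gff))

  screened <- stage("screen", screen_candidates(
    proteome, refs, cfg$min_identity, cfg$min_coverage))
  named <- stage("nomenclature", assign_nomenclature(
    screened, models, prefix = cfg$name_prefix))
  kept_ids <- named$query_id[named$retained]

  motifs <- stage("motifs", profile_motifs(
    proteome[proteome$id %in% kept_ids, ] |>
      left_join(select(named, id = "query_id", "subfamily"), by = "id")))

  struct_tbl <- stage("structure", count_introns(
    models[models$gene_id %in% kept_ids, ]))
  patterns <- stage("structure", intron_pattern_table(struct_tbl, named))

  tandem <- stage("tandem", find_tandem_pairs(
    models, proteome,
    max_intervening = cfg$tandem_max_intervening,
    max_span_bp = cfg$tandem_max_span,
    min_identity_pct = cfg$tandem_min_identity))
  tandem <- tandem[tandem$gene_a %in% kept_ids & tandem$gene_b %in% kept_ids, ]

  cds <- if (!is.null(cfg$cds)) stage("read", read_fasta(cfg$cds, "dna"))
  if (!is.null(cds) && nrow(tandem) > 0) {
    tandem <- stage("kaks", kaks_pairs(tandem, cds))
  }
  segmental <- if (!is.null(cfg$segmental_pairs)) {
    stage("segmental", load_segmental_pairs(cfg$segmental_pairs, models, cds))
  }

  tree <- if (!is.null(cfg$msa)) {
    msa <- stage("read", read_fasta(cfg$msa, "protein"))
    stage("tree", bootstrap_supports(msa, n_reps = cfg$bootstrap, seed = seed))
  }

  expr_class <- if (!is.null(cfg$expression)) {
    m <- stage("read", read_expression_matrix(cfg$expression))
    stage("expression", flag_expression_class(m, cfg$fpkm_threshold))
  }
  salt_class <- if (!is.null(cfg$salt)) {
    s <- stage("read", readr::read_tsv(cfg$salt, show_col_types = FALSE,
                                       progress = FALSE))
    stage("expression", classify_salt_response(s, cfg$fold,
                                               cfg$fpkm_threshold))
  }

  genes <- named |>
    filter(.data$retained) |>
    left_join(select(motifs, query_id = "query_id", "npa1", "npa1_canonical",
                     "npa2", "npa2_canonical", "H2", "H5", "LE1", "LE2",
                     "arR_group"), by = "query_id") |>
    left_join(select(struct_tbl, query_id = "gene_id", "n_introns"),
              by = "query_id") |>
    mutate(tandem_member = .data$query_id %in%
             c(tandem$gene_a, tandem$gene_b))
  if ("omega" %in% names(tandem) && nrow(tandem) > 0) {
    omega_by_gene <- bind_rows(
      select(tandem, gene = "gene_a", "omega"),
      select(tandem, gene = "gene_b", "omega")) |>
      group_by(.data$gene) |>
      summarise(omega = mean(.data$omega, na.rm = TRUE), .groups = "drop")
    genes <- left_join(genes, omega_by_gene,
                       by = c(query_id = "gene"))
  }
  if (!is.null(expr_class)) {
    genes <- left_join(genes,
                       select(expr_class, query_id = "gene_id",
                              expression_class = "class"),
                       by = "query_id")
  }
  if (!is.null(salt_class)) {
    genes <- left_join(genes,
                       select(salt_class, query_id = "gene_id",
                              salt_direction = "direction",
                              salt_peak_time = "peak_time"),
                       by = "query_id")
  }

  res <- structure(
    list(
      genes = genes,
      tables = list(screen = named, motifs = motifs, structure = struct_tbl,
                    intron_patterns = patterns$table,
                    intron_modal = patterns$modal, tandem = tandem,
                    segmental = segmental, expression = expr_class,
                    salt = salt_class),
      tree = tree,
      metadata = list(seed = seed, thresholds = cfg[setdiff(names(cfg),
                                                            names(paths))],
                      inputs = paths,
                      n_screened = nrow(proteome),
                      n_retained = length(kept_ids))
    ),
    class = "mip_survey"
  )
  if (!is.null(out_dir)) {
    tabs <- c(list(genes = genes),
              purrr::compact(res$tables))
    write_report(tabs, out_dir, metadata = res$metadata)
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "tree.nwk"))
  }
  res
}

#' @noRd
read_survey_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- stringr::str_match(lines, "^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*?)\\s*$")
  if (anyNA(kv[, 1])) abort("malformed config line (expected key = value)")
  vals <- as.list(kv[, 3])
  names(vals) <- kv[, 2]
  map(vals, function(v) {
    suppressWarnings(n <- as.numeric(v))
    if (!is.na(n)) n else v
  })
}

#' @export
print.mip_survey <- function(x, ...) {
  cat("<mip_survey>\n")
  cat("  proteins screened:", x$metadata$n_screened, "\n")
  cat("  retained as AQP/candidate:", x$metadata$n_retained, "\n")
  sub <- table(x$genes$subfamily)
  cat("  subfamilies:", paste(names(sub), sub, sep = "=", collapse = ", "),
      "\n")
  cat("  tandem pairs:", nrow(x$tables$tandem), "\n")
  invisible(x)
}

#' Tidy the per-gene survey table
#'
#' @param x A `mip_survey` object.
#' @param ... Unused.
#' @return The per-gene tibble (one row per retained gene).
#' @export
tidy.mip_survey <- function(x, ...) x$genes

#' One-row survey summary
#'
#' @param x A `mip_survey` object.
#' @param ... Unused.
#' @return A one-row tibble with screening and family counts.
#' @export
glance.mip_survey <- function(x, ...) {
  tibble(
    n_screened = x$metadata$n_screened,
    n_retained = x$metadata$n_retained,
    n_subfamilies = dplyr::n_distinct(
      x$genes$subfamily[x$genes$subfamily != "unassigned"]),
    n_tandem_pairs = nrow(x$tables$tandem),
    n_canonical_npa = sum(x$genes$npa1_canonical & x$genes$npa2_canonical,
                          na.rm = TRUE)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
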