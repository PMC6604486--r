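#' Read sequences from a FASTA file
#'
#' Reads protein or nucleotide FASTA into a tibble with one row per record.
#' Sequences are uppercased; record order is preserved. Protein records may
#' contain only the 20 amino-acid letters plus `X`; DNA records only `ACGTN`.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @return A tibble with columns `id`, `sequence`, `moltype`, `description`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a water channel", "NPA"), f)
#' read_fasta(f, "protein")
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  # read as raw strings so illegal characters reach our validator instead of
  # being silently dropped by the typed readers
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(tibble(id = character(), sequence = character(),
                  moltype = character(), description = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  validate_alphabet(seqs, ids, moltype)
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for id: ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  tibble(id = ids, sequence = seqs, moltype = moltype, description = desc)
}

#' @noRd
validate_alphabet <- function(seqs, ids, moltype) {
  allowed <- if (moltype == "protein") c(AA_ALPHABET20, "X") else
    c(DNA_ALPHABET, "N")
  bad <- stringr::str_locate(seqs, paste0("[^", paste(allowed, collapse = ""), "]"))[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("illegal %s character '%s' in sequence '%s' at position %d",
                  moltype, substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param records Tibble as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(nzchar(records$description %||% ""),
                paste(records$id, records$description),
                records$id)
  writeLines(paste0(">", hdr, "\n", records$sequence), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses the gene -> mRNA -> exon hierarchy (via `Parent` attributes) and
#' returns one row per gene, using its longest-spliced transcript (largest
#' summed exon length; ties broken by lexicographically smallest transcript
#' id) as the representative. Coordinates are kept 1-based inclusive, the
#' GFF3 convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `transcript_id` and a list-column `exons` of tibbles with
#'   sorted, non-overlapping `start`/`end` pairs.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  transcript_id = character(), exons = list()))
  }
  nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns, found %d",
                  which(keep)[nfield != 9][1], nfield[nfield != 9][1]))
  }
  fields <- do.call(rbind, strsplit(lines[keep], "\t", fixed = TRUE))
  feat <- tibble(
    chrom = fields[, 1], type = fields[, 3],
    start = suppressWarnings(as.integer(fields[, 4])),
    end = suppressWarnings(as.integer(fields[, 5])),
    strand = fields[, 7], attrs = fields[, 9],
    line = which(keep)
  )
  if (any(is.na(feat$start) | is.na(feat$end))) {
    abort(sprintf("malformed GFF3 line %d: non-numeric coordinates",
                  feat$line[is.na(feat$start) | is.na(feat$end)][1]))
  }
  if (any(feat$end < feat$start)) {
    abort(sprintf("malformed GFF3 line %d: end < start",
                  feat$line[feat$end < feat$start][1]))
  }
  feat <- feat |>
    mutate(id = gff3_attr(.data$attrs, "ID"),
           parent = gff3_attr(.data$attrs, "Parent"))

  genes <- filter(feat, .data$type == "gene")
  mrnas <- filter(feat, .data$type %in% c("mRNA", "transcript"))
  exons <- filter(feat, .data$type == "exon")
  if (nrow(exons) > 0) {
    orphan <- !(exons$parent %in% mrnas$id)
    if (any(orphan)) {
      abort(sprintf("GFF3 line %d: exon parent '%s' does not resolve to an mRNA",
                    exons$line[orphan][1], exons$parent[orphan][1]))
    }
  }
  if (nrow(mrnas) > 0) {
    orphan <- !(mrnas$parent %in% genes$id)
    if (any(orphan)) {
      abort(sprintf("GFF3 line %d: mRNA parent '%s' does not resolve to a gene",
                    mrnas$line[orphan][1], mrnas$parent[orphan][1]))
    }
  }

  # representative transcript: longest summed exon length, ties by smallest id
  tx <- mrnas |>
    mutate(exlen = map_dbl(.data$id, function(t) {
      sum(exons$end[exons$parent == t] - exons$start[exons$parent == t] + 1)
    })) |>
    arrange(.data$parent, dplyr::desc(.data$exlen), .data$id) |>
    group_by(.data$parent) |>
    dplyr::slice(1) |>
    ungroup()

  out <- genes |>
    arrange(.data$chrom, .data$start) |>
    mutate(rep_tx = tx$id[match(.data$id, tx$parent)])
  ex_list <- map(out$rep_tx, function(t) {
    if (is.na(t)) return(tibble(start = integer(), end = integer()))
    ex <- exons[exons$parent == t, c("start", "end")] |> arrange(.data$start)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(paste0("overlapping exons in transcript ", t))
    }
    as_tibble(ex)
  })
  if (any(lengths(map(ex_list, "start")) == 0)) {
    abort(paste0("gene without any exon: ",
                 out$id[lengths(map(ex_list, "start")) == 0][1]))
  }
  tibble(gene_id = out$id, chrom = out$chrom,
         start = out$start, end = out$end, strand = out$strand,
         transcript_id = out$rep_tx, exons = ex_list)
}

#' @noRd
gff3_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]+)"))[, 2]
  m
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' non-negative FPKM values.
#'
#' @param path Path to a tab-delimited file.
#' @return An `fpkm_matrix`: a tibble with a `gene_id` column followed by one
#'   numeric column per sample, carrying a `normalized` attribute.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  lines <- readLines(path)
  nfield <- lengths(strsplit(lines[nzchar(lines)], "\t", fixed = TRUE))
  if (length(unique(nfield)) > 1) {
    abort(sprintf("ragged matrix: line %d has %d fields, expected %d",
                  which(nfield != nfield[1])[1], nfield[nfield != nfield[1]][1],
                  nfield[1]))
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric expression values")
  if (anyNA(vals)) abort("missing expression values")
  if (any(vals < 0)) abort("negative FPKM value encountered")
  new_fpkm_matrix(as_tibble(x), normalized = FALSE)
}

#' @noRd
new_fpkm_matrix <- function(x, normalized = FALSE) {
  attr(x, "normalized") <- normalized
  class(x) <- c("fpkm_matrix", class(x))
  x
}

#' Construct an expression matrix from a tibble
#'
#' @param x Tibble with a `gene_id` column and numeric sample columns.
#' @param normalized Whether values are already on the log2(FPKM+1) scale.
#' @return An `fpkm_matrix`.
#' @export
as_fpkm_matrix <- function(x, normalized = FALSE) {
  stopifnot(is.data.frame(x), "gene_id" %in% names(x))
  vals <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  if (any(vals < 0)) abort("negative FPKM value encountered")
  new_fpkm_matrix(as_tibble(x), normalized = normalized)
}

#' Is an expression matrix normalized?
#' @param x An `fpkm_matrix`.
#' @return Logical flag.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Write a tree to Newick text
#'
#' Branch lengths are retained and internal node labels (integer bootstrap
#' supports, if present) are written.
#'
#' @param tree An [ape::phylo] object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a survey report as TSV plus JSON
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @param metadata Optional named list stored in the JSON alongside tables.
#' @return The directory path, invisibly.
#' @export
write_report <- function(tables, dir, metadata = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    readr::write_tsv(flatten_list_cols(tables[[nm]]),
                     file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  payload <- c(list(metadata = metadata),
               map(tables, flatten_list_cols))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @noRd
flatten_list_cols <- function(df) {
  is_list <- vapply(df, is.list, logical(1))
  for (nm in names(df)[is_list]) {
    df[[nm]] <- map_chr(df[[nm]], function(v) {
      if (is.data.frame(v)) {
        paste(paste0(v[[1]], "-", v[[2]]), collapse = ";")
      } else {
        paste(unlist(v), collapse = ";")
      }
    })
  }
  df
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon features with ID/Parent attributes; inverse of
#' [read_gff3()] on canonical single-transcript models.
#'
#' @param models Gene-model tibble (as from [read_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    tx <- g$transcript_id %||% paste0(g$gene_id, ".1")
    lines <- c(lines,
      paste(g$chrom, "mipsurvey", "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "mipsurvey", "mRNA", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", tx, ";Parent=", g$gene_id), sep = "\t"))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
        paste(g$chrom, "mipsurvey", "exon", ex$start[j], ex$end[j], ".",
              g$strand, ".", paste0("Parent=", tx), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression matrix to TSV
#'
#' @param matrix An `fpkm_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  readr::write_tsv(as_tibble(matrix), path, progress = FALSE)
  invisible(path)
}
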