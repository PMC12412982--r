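#' Read an expression matrix from TSV, CSV or GCT
#'
#' Loads a samples-by-genes expression matrix. For `tsv`/`csv` the orientation
#' of the file is declared with `genes_as`: `"rows"` (the GCT-like convention,
#' first column gene identifiers, remaining columns one per sample) or
#' `"cols"` (first column sample identifiers, remaining columns one per gene).
#' GCT input follows the v1.3 dialect (`#1.3` header, dimension line, `id` and
#' `Description` columns).
#'
#' Gene identifiers are upper-cased on load; matching everywhere in the
#' package is exact after this normalization. Duplicate gene or sample
#' identifiers and missing values are errors.
#'
#' @param path Path to the file.
#' @param format One of `"tsv"`, `"csv"`, `"gct"`.
#' @param genes_as For `tsv`/`csv`: `"rows"` or `"cols"`.
#' @return A numeric matrix (samples x genes) with `rownames` = sample ids and
#'   `colnames` = gene ids.
#' @export
read_expression <- function(path, format = c("tsv", "csv", "gct"),
                            genes_as = c("rows", "cols")) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) {
    stop_format(paste0("expression file not found: ", path))
  }
  if (format == "gct") {
    mat <- read_gct(path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            quote = "", comment.char = "", stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2) stop_format("expression table needs an id column plus at least one value column")
    ids <- df[[1]]
    vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
    vals <- matrix(as.numeric(vals), nrow = nrow(df),
                   dimnames = list(ids, colnames(df)[-1]))
    if (genes_as == "rows") {
      mat <- t(vals)
    } else {
      mat <- vals
    }
  }
  colnames(mat) <- toupper(colnames(mat))
  validate_expression(mat)
  inform(sprintf("read_expression: %d samples x %d genes from %s",
                 nrow(mat), ncol(mat), basename(path)))
  mat
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[[1]], "#1.")) {
    stop_format("not a GCT file: missing '#1.x' version header")
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[[2]]), "[\t ]+")[[1]]))
  if (length(dims) < 2 || anyNA(dims[1:2])) {
    stop_format("GCT dimension line is not two integers")
  }
  n_genes <- dims[[1]]
  n_samples <- dims[[2]]
  header <- strsplit(lines[[3]], "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != n_genes) {
    stop_format(sprintf("GCT declares %d data rows but file has %d", n_genes, length(body)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_meta <- length(header) - n_samples  # id + Description (+ row metadata)
  if (n_meta < 1) stop_format("GCT header has fewer columns than declared samples")
  bad <- which(lengths(fields) != length(header))
  if (length(bad) > 0) {
    stop_format(sprintf("GCT row %d has %d fields, expected %d",
                        bad[[1]], length(fields[[bad[[1]]]]), length(header)))
  }
  gene_ids <- vapply(fields, `[[`, character(1), 1L)
  vals <- t(vapply(fields, function(f) {
    suppressWarnings(as.numeric(f[(n_meta + 1):length(f)]))
  }, numeric(n_samples)))
  if (n_samples == 1) vals <- matrix(vals, ncol = 1)
  dimnames(vals) <- list(gene_ids, header[(n_meta + 1):length(header)])
  t(vals)
}

validate_expression <- function(mat) {
  if (anyDuplicated(colnames(mat))) {
    dup <- unique(colnames(mat)[duplicated(colnames(mat))])
    stop_validation(paste0("duplicate gene id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    stop_validation(paste0("duplicate sample id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyNA(mat)) {
    stop_validation("expression matrix contains missing values")
  }
  invisible(mat)
}

#' Write an expression matrix as TSV or CSV
#'
#' Inverse of [read_expression()] for the delimited formats; `write` then
#' `read` reproduces values and identifiers exactly.
#'
#' @param mat Samples-by-genes numeric matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @param genes_as `"rows"` or `"cols"` file orientation.
#' @export
write_expression <- function(mat, path, format = c("tsv", "csv"),
                             genes_as = c("rows", "cols")) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  sep <- if (format == "tsv") "\t" else ","
  if (genes_as == "rows") {
    out <- t(mat)
    id_col <- "gene_id"
  } else {
    out <- mat
    id_col <- "sample_id"
  }
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[[1]] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style protein links file
#'
#' Parses whitespace-separated `(gene_a, gene_b, score)` triples, such as the
#' STRING `protein.links` flat file restricted to gene symbols. Scores on the
#' 0-1000 STRING scale are detected automatically (any score > 1) and divided
#' by 1000, so the returned scores and `min_score` always live on \[0, 1\].
#' Pairs are deduplicated ignoring orientation, keeping the maximum score, and
#' self-pairs are dropped.
#'
#' @param path Path to the links file. A single header line is allowed.
#' @param min_score Minimum confidence score to retain, on \[0, 1\].
#'   Defaults to 0.7, the conventional "high confidence" STRING cutoff.
#' @return A tibble with columns `gene_a`, `gene_b`, `score`, one row per
#'   undirected edge, identifiers upper-cased and `gene_a < gene_b`.
#' @export
read_string_links <- function(path, min_score = 0.7) {
  if (!file.exists(path)) stop_format(paste0("links file not found: ", path))
  stopifnot(is.numeric(min_score), min_score >= 0, min_score <= 1)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(gene_a = character(), gene_b = character(), score = numeric()))
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  parse_score <- function(f) suppressWarnings(as.numeric(f[[3]]))
  # a non-numeric score on the first line is a column header
  start <- 1L
  if (length(fields[[1]]) >= 3 && is.na(parse_score(fields[[1]]))) start <- 2L
  if (start > length(fields)) {
    return(tibble(gene_a = character(), gene_b = character(), score = numeric()))
  }
  fields <- fields[start:length(fields)]
  line_no <- line_no[start:length(line_no)]
  n_fld <- lengths(fields)
  scores <- vapply(fields, function(f) if (length(f) >= 3) parse_score(f) else NA_real_,
                   numeric(1))
  bad <- which(n_fld < 3 | is.na(scores))
  if (length(bad) > 0) {
    stop_format(sprintf("cannot parse links file line %d: '%s'",
                        line_no[[bad[[1]]]], lines[[bad[[1]]]]))
  }
  a <- toupper(vapply(fields, `[[`, character(1), 1L))
  b <- toupper(vapply(fields, `[[`, character(1), 2L))
  if (any(scores < 0) || any(scores > 1000)) {
    stop_format("link scores must lie in [0,1] or [0,1000]")
  }
  if (any(scores > 1)) scores <- scores / 1000
  edges <- tibble(
    gene_a = pmin(a, b),
    gene_b = pmax(a, b),
    score = scores
  )
  edges <- edges |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::filter(.data$score >= min_score) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  inform(sprintf("read_string_links: %d edges at score >= %g from %s",
                 nrow(edges), min_score, basename(path)))
  edges
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated, the first field a
#' term identifier, the second a free-text description, then member gene
#' symbols. Member symbols are upper-cased. Lines without member genes are
#' skipped with a warning; duplicate term identifiers are an error.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `term_names` attribute mapping term id to description.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format(paste0("GMT file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short) > 0) {
    stop_format(sprintf("GMT line %d has fewer than 2 tab-separated fields", short[[1]]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_validation(paste0("duplicate GMT term id(s): ", paste(dup, collapse = ", ")))
  }
  members <- lapply(fields, function(f) {
    g <- toupper(f[-(1:2)])
    unique(g[nzchar(g)])
  })
  empty <- lengths(members) == 0
  if (any(empty)) {
    warn(sprintf("read_gmt: skipping %d term(s) with no member genes: %s",
                 sum(empty), paste(head(ids[empty], 5), collapse = ", ")))
  }
  sets <- members[!empty]
  names(sets) <- ids[!empty]
  term_names <- vapply(fields, `[[`, character(1), 2L)[!empty]
  names(term_names) <- names(sets)
  inform(sprintf("read_gmt: %d gene sets from %s", length(sets), basename(path)))
  gene_set_collection(sets, term_names)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param term_names Optional named character vector of descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, term_names = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && is.null(names(sets))) {
    stop_validation("gene sets must be named by term id")
  }
  if (any(lengths(sets) == 0)) {
    stop_validation("every gene set must be nonempty")
  }
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (is.null(term_names)) {
    term_names <- setNames(names(sets), names(sets))
  }
  structure(sets, term_names = term_names, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read a sample label table
#'
#' Expects a delimited file with header columns `sample_id`, `label`
#' (0/1) and optionally `group_id` (e.g. the drug a profile belongs to, used
#' for grouped cross-validation).
#'
#' @param path Path to a TSV/CSV file (delimiter sniffed from the extension).
#' @return A tibble with columns `sample_id`, `label` and, when present,
#'   `group_id`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_format(paste0("label file not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "label")
  if (!all(need %in% colnames(df))) {
    stop_format("label table must have columns 'sample_id' and 'label'")
  }
  if (!all(df$label %in% c(0, 1))) {
    stop_validation("labels must be 0 or 1")
  }
  out <- tibble(sample_id = as.character(df$sample_id), label = as.integer(df$label))
  if ("group_id" %in% colnames(df)) out$group_id <- as.character(df$group_id)
  out
}

# Check that every labeled sample is present in the expression matrix and
# return labels ordered to match its rows.
align_labels <- function(labels, mat) {
  missing <- setdiff(labels$sample_id, rownames(mat))
  if (length(missing) > 0) {
    stop_validation(paste0("labeled sample(s) absent from expression matrix: ",
                           paste(head(missing, 10), collapse = ", ")))
  }
  unlabeled <- setdiff(rownames(mat), labels$sample_id)
  if (length(unlabeled) > 0) {
    stop_validation(paste0("sample(s) missing from label table: ",
                           paste(head(unlabeled, 10), collapse = ", ")))
  }
  labels[match(rownames(mat), labels$sample_id), , drop = FALSE]
}
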