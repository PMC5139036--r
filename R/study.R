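#' Construct an expression study
#'
#' Bundles a probes-by-samples expression matrix with per-sample phenotype
#' information (a binary condition plus optional numeric or binary
#' covariates). The phenotype rows are joined to the matrix columns by
#' sample ID, order-insensitively.
#'
#' @param matrix Numeric matrix, probes in rows (rownames = probe IDs) and
#'   samples in columns (colnames = sample IDs). No missing values.
#' @param phenotype Data frame with a `sample_id` column, a condition
#'   column, and optional covariate columns.
#' @param condition Name of the condition column (two levels, each with at
#'   least 2 samples).
#'
#' @return An object of class `expression_study`: a list with elements
#'   `matrix`, `phenotype` (tibble, reordered to match the matrix columns),
#'   `condition` (factor), and `covariates` (character vector of covariate
#'   column names).
#' @examples
#' study <- simulate_study(n_probes = 50, n_per_group = c(5, 5), seed = 1)
#' study
#' @export
expression_study <- function(matrix, phenotype, condition = "condition") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (anyNA(matrix) || !all(is.finite(matrix))) {
    rlang::abort("expression matrix contains missing or non-finite values")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    rlang::abort("expression matrix must carry probe and sample IDs as dimnames")
  }
  if (anyDuplicated(rownames(matrix))) {
    rlang::abort(sprintf("duplicated probe ID: %s",
                         rownames(matrix)[duplicated(rownames(matrix))][1]))
  }
  phenotype <- tibble::as_tibble(phenotype)
  if (!"sample_id" %in% names(phenotype)) {
    rlang::abort("phenotype must have a `sample_id` column")
  }
  if (!condition %in% names(phenotype)) {
    rlang::abort(sprintf("phenotype has no `%s` column", condition))
  }
  missing_ids <- setdiff(colnames(matrix), phenotype$sample_id)
  if (length(missing_ids)) {
    rlang::abort(paste0("sample IDs missing from phenotype: ",
                        paste(missing_ids, collapse = ", ")))
  }
  phenotype <- phenotype[match(colnames(matrix), phenotype$sample_id), ]
  cond_raw <- phenotype[[condition]]
  lev <- sort(unique(as.character(cond_raw)))
  if (length(lev) != 2) {
    rlang::abort(sprintf("condition must have exactly 2 levels, found %d",
                         length(lev)))
  }
  cond <- factor(as.character(cond_raw), levels = lev)
  if (min(table(cond)) < 2) {
    rlang::abort("both conditions need at least 2 samples")
  }
  covars <- setdiff(names(phenotype), c("sample_id", condition))
  for (cv in covars) {
    phenotype[[cv]] <- .coerce_covariate(phenotype[[cv]], cv)
  }
  structure(
    list(matrix = matrix, phenotype = phenotype, condition = cond,
         covariates = covars),
    class = "expression_study"
  )
}

# binary text levels map 0/1 by sorted level name (deterministic)
.coerce_covariate <- function(x, name) {
  if (is.numeric(x)) return(as.numeric(x))
  lev <- sort(unique(as.character(x)))
  if (length(lev) == 2) {
    return(as.numeric(factor(as.character(x), levels = lev)) - 1)
  }
  suppressWarnings(num <- as.numeric(as.character(x)))
  if (anyNA(num)) {
    rlang::abort(sprintf(
      "covariate `%s` is neither numeric nor binary", name
    ))
  }
  num
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "expression_study: %d probes x %d samples (%s)\n",
    nrow(x$matrix), ncol(x$matrix),
    paste(sprintf("%s: %d", levels(x$condition), table(x$condition)),
          collapse = ", ")
  ))
  if (length(x$covariates)) {
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

.split_by_condition <- function(study, matrix = NULL) {
  m <- if (is.null(matrix)) study$matrix else matrix
  idx <- study$condition == levels(study$condition)[1]
  list(g1 = m[, idx, drop = FALSE], g2 = m[, !idx, drop = FALSE])
}

#' Read and write expression matrices and phenotype tables
#'
#' Tab-delimited text is the canonical interchange format: the expression
#' file has sample IDs in the header and probe IDs in the first column
#' (probes-by-samples orientation unless `orientation =
#' "samples_in_rows"`); the phenotype file has columns `sample_id`, the
#' condition, then covariates. Malformed headers, duplicate IDs, and
#' non-numeric cells are rejected with the offending coordinates named.
#'
#' @param path File path.
#' @param orientation `"probes_in_rows"` (default) or `"samples_in_rows"`
#'   (the file is transposed on read).
#' @param delim Field delimiter.
#' @return `read_expression()`: a numeric matrix with dimnames;
#'   `read_phenotype()`: a tibble.
#' @export
read_expression <- function(path, orientation = c("probes_in_rows",
                                                  "samples_in_rows"),
                            delim = "\t") {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    rlang::abort(sprintf("empty or malformed expression file: %s", path))
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicated ID in %s: %s", path,
                         ids[duplicated(ids)][1]))
  }
  cols <- names(raw)[-1]
  if (anyDuplicated(cols)) {
    rlang::abort(sprintf("duplicated ID in header of %s: %s", path,
                         cols[duplicated(cols)][1]))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    rlang::abort(sprintf(
      "non-numeric cell in %s at row %s, column %s: \"%s\"",
      path, ids[bad[1, 1]], cols[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]
    ))
  }
  if (anyNA(num)) {
    rlang::abort(sprintf("missing values are not permitted (%s)", path))
  }
  dimnames(num) <- list(ids, cols)
  if (orientation == "samples_in_rows") num <- t(num)
  num
}

#' @rdname read_expression
#' @param x A matrix (probes x samples) or an `expression_study`.
#' @export
write_expression <- function(x, path, delim = "\t") {
  m <- if (inherits(x, "expression_study")) x$matrix else x
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @param condition Name of the condition column.
#' @export
read_phenotype <- function(path, condition = "condition", delim = "\t") {
  ph <- tibble::as_tibble(utils::read.delim(path, sep = delim, header = TRUE,
                                            check.names = FALSE,
                                            stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(ph)) {
    rlang::abort(sprintf("phenotype file %s has no `sample_id` column", path))
  }
  if (!condition %in% names(ph)) {
    rlang::abort(sprintf("phenotype file %s has no `%s` column", path,
                         condition))
  }
  n_lev <- length(unique(ph[[condition]]))
  if (n_lev != 2) {
    rlang::abort(sprintf("condition column must have 2 levels, found %d",
                         n_lev))
  }
  ph$sample_id <- as.character(ph$sample_id)
  ph
}

#' @rdname read_expression
#' @param phenotype A phenotype tibble or an `expression_study`.
#' @export
write_phenotype <- function(phenotype, path, delim = "\t") {
  if (inherits(phenotype, "expression_study")) {
    phenotype <- phenotype$phenotype
  }
  utils::write.table(phenotype, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @param expr_path,pheno_path Paths to the expression matrix and phenotype
#'   table.
#' @export
read_study <- function(expr_path, pheno_path, condition = "condition",
                       orientation = "probes_in_rows", delim = "\t") {
  expression_study(
    read_expression(expr_path, orientation = orientation, delim = delim),
    read_phenotype(pheno_path, condition = condition, delim = delim),
    condition = condition
  )
}
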