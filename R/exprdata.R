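#' Construct an expression matrix
#'
#' Container for a genes-by-samples matrix of log-scale expression values
#' with gene and sample identifiers and a flag recording whether each gene
#' row has been centered at zero.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to colnames of `values`).
#' @param centered logical; `TRUE` only if every gene row has mean zero.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `centered`.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
#' dim(m$values)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              centered = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- trimws(as.character(gene_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite; missing values are not supported")
  if (isTRUE(centered) && nrow(values) > 0 &&
      max(abs(rowMeans(values))) > 1e-10)
    stop("centered = TRUE but some gene rows do not have mean zero")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, centered = isTRUE(centered)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%scentered)\n",
              nrow(x$values), ncol(x$values), if (x$centered) "" else "not "))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a sample covariate table
#'
#' Per-sample covariates for a small experiment: a binary condition
#' indicator, optional pair (family / dye-swap block) labels, and an optional
#' time covariate in radians for rhythm analyses.
#'
#' @param condition integer/numeric vector of 0/1 indicators (1 = perturbed).
#' @param pair_id optional vector of pair labels; each label must occur for
#'   at least two samples.
#' @param time_radians optional numeric vector of times in radians.
#' @param sample_ids optional character vector of sample identifiers.
#' @return An object of class `covariate_table`.
#' @export
covariate_table <- function(condition, pair_id = NULL, time_radians = NULL,
                            sample_ids = NULL) {
  condition <- as.numeric(condition)
  n <- length(condition)
  if (!all(condition %in% c(0, 1)))
    stop("condition must contain only 0 and 1")
  if (!is.null(pair_id)) {
    pair_id <- as.character(pair_id)
    if (length(pair_id) != n) stop("pair_id length != condition length")
    if (any(table(pair_id) < 2))
      stop("each pair_id must appear for at least two samples")
  }
  if (!is.null(time_radians)) {
    time_radians <- as.numeric(time_radians)
    if (length(time_radians) != n) stop("time_radians length != condition length")
    if (!all(is.finite(time_radians))) stop("time_radians must be finite")
  }
  if (!is.null(sample_ids)) {
    sample_ids <- trimws(as.character(sample_ids))
    if (length(sample_ids) != n) stop("sample_ids length != condition length")
    if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  }
  structure(list(condition = condition, pair_id = pair_id,
                 time_radians = time_radians, sample_ids = sample_ids,
                 n = n),
            class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("covariate_table: %d samples (%d perturbed)%s%s\n", x$n,
              sum(x$condition == 1),
              if (!is.null(x$pair_id)) ", paired" else "",
              if (!is.null(x$time_radians)) ", with time" else ""))
  invisible(x)
}

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix from a delimited file
#'
#' Reads a TSV (default) or CSV file whose first column holds gene
#' identifiers and whose header row holds sample identifiers. With
#' `orientation = "genes-in-columns"` the file is transposed after reading so
#' the returned matrix is always genes by samples.
#'
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @param orientation `"genes-in-rows"` (default) or `"genes-in-columns"`.
#' @return An [expression_matrix()] with `centered = FALSE` (centering state
#'   is re-derived from the values, not trusted from the file).
#' @seealso [write_expression()]
#' @export
read_expression <- function(path,
                            orientation = c("genes-in-rows", "genes-in-columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  ids <- trimws(tab[[1]])
  body <- tab[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at row '%s', column '%s' in %s",
                 ids[bad[1]], colnames(body)[bad[2]], path))
  }
  dimnames(num) <- list(ids, trimws(colnames(body)))
  if (orientation == "genes-in-columns") num <- t(num)
  expression_matrix(num, centered = FALSE)
}

#' Write an expression matrix to a delimited file
#'
#' @param m an [expression_matrix()].
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param id_column header name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_column = "gene_id") {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(id = m$gene_ids, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a covariate table from a delimited file
#'
#' Expects columns `sample_id` and `condition`, plus optional `pair_id` and
#' `time_radians`.
#'
#' @param path file path (`.csv` comma, otherwise tab).
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% colnames(tab)))
    stop("covariate file must have columns 'sample_id' and 'condition'")
  covariate_table(condition = tab$condition,
                  pair_id = if ("pair_id" %in% colnames(tab)) tab$pair_id,
                  time_radians = if ("time_radians" %in% colnames(tab)) tab$time_radians,
                  sample_ids = tab$sample_id)
}

#' Write a covariate table to a delimited file
#'
#' @param cov a [covariate_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  stopifnot(inherits(cov, "covariate_table"))
  df <- data.frame(
    sample_id = if (is.null(cov$sample_ids)) paste0("s", seq_len(cov$n)) else cov$sample_ids,
    condition = cov$condition, stringsAsFactors = FALSE)
  if (!is.null(cov$pair_id)) df$pair_id <- cov$pair_id
  if (!is.null(cov$time_radians)) df$time_radians <- cov$time_radians
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Center every gene row at zero
#'
#' Subtracts the row mean from each gene. Variances are deliberately left
#' unscaled: the magnitude of (log-scale) expression variability is
#' biologically meaningful and is assumed to be comparable across platforms,
#' so only the location is removed.
#'
#' @param m an [expression_matrix()].
#' @return The centered [expression_matrix()] with `centered = TRUE`.
#' @export
center_genes <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values - rowMeans(m$values)
  expression_matrix(v, m$gene_ids, m$sample_ids, centered = TRUE)
}

#' Average spots to genes and replicate arrays to subjects
#'
#' Collapses a spot-by-array matrix to a gene-by-subject matrix by averaging
#' all spots mapped to the same gene and all replicate arrays mapped to the
#' same subject. Channels of a dye-swap design are treated as ordinary
#' replicates.
#'
#' @param m an [expression_matrix()] whose rows are spots and columns arrays.
#' @param spot_to_gene named character vector mapping every spot id to a gene
#'   id.
#' @param array_to_subject named character vector mapping every array id to a
#'   subject id.
#' @return An [expression_matrix()] with one row per gene and one column per
#'   subject, in order of first appearance in the maps' targets.
#' @export
collapse_replicates <- function(m, spot_to_gene, array_to_subject) {
  stopifnot(inherits(m, "expression_matrix"))
  missing_spots <- setdiff(m$gene_ids, names(spot_to_gene))
  if (length(missing_spots))
    stop("unmapped spots: ", paste(utils::head(missing_spots, 5), collapse = ", "))
  missing_arrays <- setdiff(m$sample_ids, names(array_to_subject))
  if (length(missing_arrays))
    stop("unmapped arrays: ", paste(utils::head(missing_arrays, 5), collapse = ", "))
  genes <- as.character(spot_to_gene[m$gene_ids])
  subjects <- as.character(array_to_subject[m$sample_ids])
  gene_lev <- unique(genes)
  subj_lev <- unique(subjects)
  # row-average spots within gene, then column-average arrays within subject
  by_gene <- rowsum(m$values, group = genes, reorder = FALSE) /
    as.vector(table(factor(genes, levels = gene_lev)))
  by_both <- t(rowsum(t(by_gene), group = subjects, reorder = FALSE)) /
    rep(as.vector(table(factor(subjects, levels = subj_lev))),
        each = length(gene_lev))
  expression_matrix(by_both, gene_lev, subj_lev, centered = FALSE)
}

#' Restrict two expression matrices to their shared genes
#'
#' Matches gene identifiers by exact string equality (identifiers are
#' whitespace-trimmed at construction); no alias resolution is attempted.
#' Both outputs carry the shared genes in the same, lexicographic order.
#'
#' @param db,expt [expression_matrix()] objects.
#' @return A list with elements `db` and `expt`, both restricted to the
#'   intersection of the gene sets.
#' @export
intersect_genes <- function(db, expt) {
  stopifnot(inherits(db, "expression_matrix"), inherits(expt, "expression_matrix"))
  shared <- sort(intersect(db$gene_ids, expt$gene_ids))
  if (length(shared) == 0) stop("no genes in common between the two matrices")
  sub <- function(m) expression_matrix(m$values[shared, , drop = FALSE],
                                       shared, m$sample_ids,
                                       centered = FALSE)
  list(db = sub(db), expt = sub(expt))
}

#' Flag genes with (near-)zero variance
#'
#' Ridge regression on a constant outcome is degenerate, so genes whose
#' expression does not vary are excluded from network fitting.
#'
#' @param m an [expression_matrix()].
#' @param tol variance threshold below which a gene is flagged.
#' @return Logical vector, `TRUE` for zero-variance genes.
#' @export
zero_variance_genes <- function(m, tol = 1e-12) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- apply(m$values, 1, stats::var)
  stats::setNames(v < tol, m$gene_ids)
}
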