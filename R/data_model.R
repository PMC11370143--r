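#' seqMI: multiple imputation of missing covariates for RNA-seq differential
#' expression
#'
#' Implements a PCA-augmented multiple-imputation differential-expression
#' workflow for RNA-seq studies with missing covariate data, together with
#' complete-case and single-imputation baselines and a simulation framework
#' for benchmarking them. See `vignette("seqMI-methods")` for the statistical
#' model and the design choices.
#'
#' @keywords internal
"_PACKAGE"

#' Construct and validate a count matrix
#'
#' The central data container: a gene x sample matrix of non-negative
#' integer read counts with unique gene and sample identifiers. Counts are
#' the only data the imputation machinery never touches.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns. All
#'   entries must be non-negative integers (stored as `numeric` is fine as
#'   long as the values are integral).
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `colnames(counts)`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the validated matrix, dimnames set), `gene_ids` and `sample_ids`.
#' @examples
#' cm <- count_matrix(matrix(c(1, 2, 3, 4), 2, 2),
#'                    gene_ids = c("g1", "g2"), sample_ids = c("s1", "s2"))
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("counts must be numeric")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count matrix must have at least one gene and one sample")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match number of rows")
  if (length(sample_ids) != ncol(counts))
    stop("sample_ids length does not match number of columns")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(counts)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(counts)) + 1L
    stop(sprintf(
      "counts must be non-negative integers; offending cell: gene '%s', sample '%s' (value %s)",
      gene_ids[i], sample_ids[j], format(counts[i, j])))
  }
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supported formats: delimited tables (`tsv`, `csv`) with gene ids in the
#' first column and sample ids in the header, and MatrixMarket (`mtx`)
#' triplet files accompanied by one-id-per-line gene and sample id files.
#' Orientation is normalized to gene x sample; pass `transpose = TRUE` for
#' sample-major tables.
#'
#' @param path Path to the count file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Defaults to a guess from
#'   the file extension.
#' @param gene_ids_file,sample_ids_file Sidecar id files (MTX only).
#' @param transpose Logical; set `TRUE` if the table on disk is
#'   sample x gene.
#' @return A [count_matrix].
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        gene_ids_file = NULL, sample_ids_file = NULL,
                        transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(gene_ids_file) || is.null(sample_ids_file))
      stop("MTX input requires gene_ids_file and sample_ids_file")
    m <- as.matrix(Matrix::readMM(path))
    gid <- readLines(gene_ids_file)
    sid <- readLines(sample_ids_file)
    if (transpose) m <- t(m)
    return(count_matrix(m, gene_ids = gid, sample_ids = sid))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (transpose) m <- t(m)
  count_matrix(m)
}

#' Write a count matrix to disk
#'
#' @param cm A [count_matrix].
#' @param path Output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param gene_ids_file,sample_ids_file Sidecar id file paths (MTX only).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("tsv", "csv", "mtx"),
                         gene_ids_file = NULL, sample_ids_file = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(gene_ids_file) || is.null(sample_ids_file))
      stop("MTX output requires gene_ids_file and sample_ids_file")
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(cm$gene_ids, gene_ids_file)
    writeLines(cm$sample_ids, sample_ids_file)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cov_types <- c("continuous", "binary", "categorical_unordered", "categorical_ordered")
.cov_roles <- c("predictor", "adjustment", "shadow")

#' Construct a typed covariate table
#'
#' Per-sample covariates with declared variable types and modelling roles.
#' Exactly one variable must carry the `predictor` role (the predictor of
#' interest whose coefficient is reported); `adjustment` covariates enter
#' the model and may be missing; `shadow` variables never enter the
#' differential-expression model but may drive (and, under MAR, inform the
#' imputation of) missingness.
#'
#' @param data A data.frame of covariate values, one row per sample.
#'   Missing cells are `NA`.
#' @param schema A data.frame with columns `variable`, `type`
#'   (`continuous`, `binary`, `categorical_unordered`, `categorical_ordered`)
#'   and `role` (`predictor`, `adjustment`, `shadow`), one row per covariate.
#' @param sample_ids Character vector of unique sample ids, aligned to the
#'   rows of `data`; defaults to `rownames(data)`.
#' @param levels Optional named list giving the level sets (and, for ordered
#'   variables, the level order) of categorical variables. Required for
#'   `categorical_ordered` unless the column is already an ordered factor.
#' @return An object of class `covariate_table`: list with `data` (typed
#'   data.frame), `schema`, `sample_ids`, `miss` (logical missingness mask)
#'   and `masked` (character vector of variables hidden from imputers,
#'   normally empty; set by [ampute_covariates()] under MNAR).
#' @export
covariate_table <- function(data, schema, sample_ids = rownames(data),
                            levels = NULL) {
  data <- as.data.frame(data)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(data)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in covariate table")
  if (length(sample_ids) != nrow(data)) stop("sample_ids length mismatch")
  schema <- as.data.frame(schema, stringsAsFactors = FALSE)
  need <- c("variable", "type", "role")
  if (!all(need %in% names(schema)))
    stop("schema must have columns: ", paste(need, collapse = ", "))
  schema <- schema[, need]
  if (!all(schema$type %in% .cov_types))
    stop("unknown variable type(s): ",
         paste(setdiff(schema$type, .cov_types), collapse = ", "))
  if (!all(schema$role %in% .cov_roles))
    stop("unknown role(s): ", paste(setdiff(schema$role, .cov_roles), collapse = ", "))
  missing_cols <- setdiff(schema$variable, names(data))
  if (length(missing_cols))
    stop("schema variable(s) not present as columns: ",
         paste(missing_cols, collapse = ", "))
  if (sum(schema$role == "predictor") != 1L)
    stop("exactly one variable must have role 'predictor' (found ",
         sum(schema$role == "predictor"), ")")
  out <- data[, schema$variable, drop = FALSE]
  for (k in seq_len(nrow(schema))) {
    v <- schema$variable[k]
    ty <- schema$type[k]
    col <- out[[v]]
    if (ty == "continuous") {
      out[[v]] <- as.numeric(col)
    } else if (ty == "categorical_ordered") {
      lv <- if (!is.null(levels[[v]])) levels[[v]]
            else if (is.ordered(col)) base::levels(col)
            else stop("level order must be supplied for ordered variable '", v, "'")
      out[[v]] <- factor(col, levels = lv, ordered = TRUE)
    } else {
      lv <- if (!is.null(levels[[v]])) levels[[v]] else sort(unique(stats::na.omit(as.character(col))))
      out[[v]] <- factor(as.character(col), levels = lv)
      if (ty == "binary" && nlevels(out[[v]]) != 2L)
        stop("binary variable '", v, "' must have exactly 2 levels, found ",
             nlevels(out[[v]]))
    }
    if (is.factor(out[[v]])) {
      seen <- base::levels(droplevels(out[[v]][!is.na(out[[v]])]))
      unseen <- setdiff(base::levels(out[[v]]), seen)
      if (length(unseen))
        stop("variable '", v, "' has level(s) never observed: ",
             paste(unseen, collapse = ", "))
    }
    if (all(is.na(out[[v]])))
      stop("variable '", v, "' has no observed values")
  }
  rownames(out) <- sample_ids
  miss <- is.na(out)
  structure(list(data = out, schema = schema, sample_ids = sample_ids,
                 miss = miss, masked = character(0)),
            class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("covariate_table: %d samples x %d variables (%d missing cells)\n",
              nrow(x$data), ncol(x$data), sum(x$miss)))
  print(x$schema, row.names = FALSE)
  invisible(x)
}

#' Read a covariate table with a declared schema
#'
#' @param path CSV/TSV file with a header; sample ids are taken from the
#'   column named by `id_column` (default: first column).
#' @param schema Schema data.frame as for [covariate_table()], or the path
#'   to a YAML file mapping variable name to `{type, role, levels}`.
#' @param na_strings Strings recognized as missing (default `""`, `"NA"`,
#'   `"NaN"`).
#' @param id_column Name of the sample-id column; `NULL` uses the first
#'   column.
#' @param levels Optional named list of level sets (ignored when `schema`
#'   is a YAML path that declares levels).
#' @param mode `"pipeline"` (default): missing values in the predictor of
#'   interest are retained with a warning (imputation will handle them).
#'   `"simulation"`: missing predictor values are an error, since simulated
#'   missingness must never touch the predictor of interest.
#' @return A [covariate_table].
#' @export
read_covariates <- function(path, schema, na_strings = c("", "NA", "NaN"),
                            id_column = NULL, levels = NULL,
                            mode = c("pipeline", "simulation")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    sc <- yaml::read_yaml(schema)
    levels <- c(levels, Filter(Negate(is.null), lapply(sc, `[[`, "levels")))
    schema <- data.frame(variable = names(sc),
                         type = vapply(sc, `[[`, "", "type"),
                         role = vapply(sc, `[[`, "", "role"),
                         stringsAsFactors = FALSE)
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na_strings,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (is.null(id_column)) id_column <- names(tab)[1]
  if (!id_column %in% names(tab)) stop("id column '", id_column, "' not found")
  ids <- tab[[id_column]]
  tab <- tab[, setdiff(names(tab), id_column), drop = FALSE]
  rownames(tab) <- ids
  ct <- covariate_table(tab, schema, sample_ids = ids, levels = levels)
  pred <- predictor_variable(ct)
  if (any(ct$miss[, pred])) {
    if (mode == "simulation")
      stop("predictor of interest '", pred, "' has missing values; ",
           "simulated missingness must not touch the predictor")
    warning("predictor of interest '", pred, "' has ", sum(ct$miss[, pred]),
            " missing value(s); they will be imputed alongside the covariates")
  }
  ct
}

#' Name of the predictor-of-interest variable
#' @param cov A [covariate_table].
#' @return Character scalar.
#' @export
predictor_variable <- function(cov) {
  cov$schema$variable[cov$schema$role == "predictor"]
}

#' Filter genes with low counts
#'
#' The default rule mirrors common RNA-seq practice: a target count of
#' roughly 10 reads per gene is translated to the CPM scale by dividing by
#' the smallest library size in millions, and genes whose average CPM across
#' samples exceeds that cutoff (strictly) are kept. CPM here uses raw
#' library sizes, since filtering precedes scale normalization. The
#' `mean_logcpm` alternative keeps genes whose average log2-CPM (0.5 count /
#' 1.0 library-size offsets) exceeds `logcpm_cutoff`.
#'
#' @param cm A [count_matrix].
#' @param count_target Target count per gene (default 10) for the CPM rule.
#' @param method `"count_target"` (default) or `"mean_logcpm"`.
#' @param logcpm_cutoff Cutoff for the `mean_logcpm` rule (default 0).
#' @return A [count_matrix] with the surviving genes, order preserved.
#' @export
filter_low_counts <- function(cm, count_target = 10,
                              method = c("count_target", "mean_logcpm"),
                              logcpm_cutoff = 0) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  R <- colSums(cm$counts)
  if (any(R <= 0)) stop("library sizes must be positive to filter on CPM")
  if (method == "count_target") {
    if (count_target < 0) stop("count_target must be non-negative")
    cutoff <- count_target / (min(R) / 1e6)
    cpm <- t(t(cm$counts) / R) * 1e6
    keep <- rowMeans(cpm) > cutoff
  } else {
    lc <- logcpm_matrix(cm$counts, R)
    keep <- rowMeans(lc) > logcpm_cutoff
  }
  if (!any(keep))
    stop("all genes removed by the low-count filter; ",
         "consider a lower count_target")
  count_matrix(cm$counts[keep, , drop = FALSE],
               gene_ids = cm$gene_ids[keep],
               sample_ids = cm$sample_ids)
}
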