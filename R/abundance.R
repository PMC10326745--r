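#' Construct an abundance table
#'
#' The central data container of the pipeline: a proteins-by-samples
#' matrix of log2 abundances (missing entries as `NA`) together with a
#' two-group sample design.
#'
#' @param values Numeric matrix with unique protein row names and unique
#'   sample column names.
#' @param design Named character vector (or factor) mapping every sample
#'   to a group label, conventionally `"case"` and `"control"`.
#' @return An object of class `abundance_table` with elements `values`
#'   and `design`.
#' @export
abundance_table <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique protein row names")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique sample column names")
  }
  design <- structure(as.character(design), names = names(design))
  if (is.null(names(design)) || !all(colnames(values) %in% names(design))) {
    stop("design must be named and cover all samples")
  }
  design <- design[colnames(values)]
  structure(list(values = values, design = design),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  groups:",
      paste(sprintf("%s=%d", names(table(x$design)), table(x$design)),
            collapse = ", "), "\n")
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

# Samples belonging to one group, in column order.
group_samples <- function(x, group) {
  colnames(x$values)[x$design[colnames(x$values)] == group]
}

#' Read / write an abundance matrix as TSV
#'
#' The on-disk format is tab-separated with a header row of sample
#' identifiers, a first column named `protein`, and empty cells for
#' missing values.
#'
#' @param path File path.
#' @param design Named character vector of group labels (see
#'   [abundance_table()]); for `read_abundance` it may also be the path
#'   of a design TSV written by [write_design()].
#' @return `read_abundance` returns an `abundance_table`;
#'   `write_abundance` returns `path` invisibly.
#' @export
read_abundance <- function(path, design) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (colnames(df)[1] != "protein") {
    stop("first column of an abundance TSV must be 'protein'")
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$protein
  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    design <- read_design(design)
  }
  abundance_table(values, design)
}

#' @rdname read_abundance
#' @param x An `abundance_table`.
#' @export
write_abundance <- function(x, path) {
  df <- data.frame(protein = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a sample design TSV (columns `sample`, `group`)
#' @param path File path.
#' @return `read_design` returns a named character vector of group
#'   labels; `write_design` returns `path` invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path)
  structure(as.character(df$group), names = df$sample)
}

#' @rdname read_design
#' @param design Named character vector of group labels.
#' @export
write_design <- function(design, path) {
  utils::write.table(data.frame(sample = names(design), group = design),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
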