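#' Construct a spatial transcriptomics slice
#'
#' Bundles the two components of one tissue slice — a spot-by-gene expression
#' matrix and per-spot planar coordinates — together with optional categorical
#' region labels. This is the basic data container every other function in the
#' package consumes.
#'
#' @param expression Numeric matrix, `N` spots by `G` genes. Raw counts or
#'   normalized values; must be finite and non-negative.
#' @param coords Numeric matrix or data frame with `N` rows and 2 columns
#'   (x, y positions; arbitrary units). Must be finite.
#' @param labels Optional length-`N` vector of region labels (character or
#'   factor). `NULL` for unannotated slices.
#' @param spot_ids Character vector of `N` unique spot identifiers. Defaults to
#'   the rownames of `expression` or `spot_1..spot_N`.
#' @param gene_ids Character vector of `G` unique gene identifiers. Defaults to
#'   the colnames of `expression` or `gene_1..gene_G`.
#' @param slice_id Single string naming the slice.
#'
#' @return An object of class `"st_slice"`: a list with elements `expression`,
#'   `coords`, `labels`, `spot_ids`, `gene_ids`, `slice_id`.
#' @export
#' @examples
#' x <- matrix(rpois(20, 5), 5, 4)
#' s <- st_slice(x, cbind(runif(5), runif(5)), labels = c("a","a","b","b","b"))
#' s
st_slice <- function(expression, coords, labels = NULL,
                     spot_ids = NULL, gene_ids = NULL, slice_id = "slice") {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"

  n <- nrow(expression)
  g <- ncol(expression)
  if (is.null(spot_ids)) {
    spot_ids <- rownames(expression)
    if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(expression)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(g))
  }
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)

  if (nrow(coords) != n)
    stop("coords has ", nrow(coords), " rows but expression has ", n, " spots")
  if (ncol(coords) != 2)
    stop("coords must have exactly 2 columns (x, y)")
  if (length(spot_ids) != n) stop("spot_ids length != number of spots")
  if (length(gene_ids) != g) stop("gene_ids length != number of genes")
  if (anyDuplicated(spot_ids))
    stop("duplicated spot_ids: ",
         paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicated gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!all(is.finite(expression))) stop("expression must be finite")
  if (any(expression < 0)) stop("expression must be non-negative")
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("labels length (", length(labels), ") != number of spots (", n, ")")
    labels <- as.character(labels)
  }

  rownames(expression) <- spot_ids
  colnames(expression) <- gene_ids
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")

  structure(
    list(expression = expression, coords = coords, labels = labels,
         spot_ids = spot_ids, gene_ids = gene_ids,
         slice_id = as.character(slice_id)[1]),
    class = "st_slice"
  )
}

#' @export
print.st_slice <- function(x, ...) {
  cat("st_slice '", x$slice_id, "': ", nrow(x$expression), " spots x ",
      ncol(x$expression), " genes", sep = "")
  if (!is.null(x$labels)) {
    cl <- sort(unique(x$labels))
    cat("; ", length(cl), " region labels (", paste(cl, collapse = ", "), ")",
        sep = "")
  } else {
    cat("; unlabeled")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.st_slice <- function(x) dim(x$expression)

#' Read a slice from disk
#'
#' Reads one tissue slice stored as a pair of delimited text tables: an
#' expression table (first column spot id, remaining columns genes) and a
#' coordinate table (columns spot id, x, y and optionally a label column).
#' The two tables are joined on spot id; the coordinate table's label column,
#' when present, supplies the region annotation.
#'
#' @param expression_file Path to the expression table.
#' @param coords_file Path to the coordinate table.
#' @param format Input format. Only `"csv_pair"` (comma- or tab-separated
#'   pair of tables, delimiter inferred from the file extension) is supported;
#'   `"h5ad"` is recognised but not available in this build and raises an
#'   informative error.
#' @param label_col Name of the optional annotation column in the coordinate
#'   table (default `"label"`).
#' @param slice_id Slice name; defaults to the expression file name.
#'
#' @return An [st_slice] object.
#' @export
read_slice <- function(expression_file, coords_file = NULL,
                       format = c("csv_pair", "h5ad"),
                       label_col = "label", slice_id = NULL) {
  format <- match.arg(format)
  if (format == "h5ad")
    stop("h5ad input is not supported by this build (no HDF5 bindings); ",
         "export the slice as a CSV pair (expression + coordinates) and use ",
         "format = 'csv_pair'")
  if (is.null(coords_file))
    stop("csv_pair format needs both an expression file and a coordinates file")
  if (!file.exists(expression_file)) stop("file not found: ", expression_file)
  if (!file.exists(coords_file)) stop("file not found: ", coords_file)
  if (is.null(slice_id))
    slice_id <- sub("\\.[^.]*$", "", basename(expression_file))

  sep_of <- function(p) if (grepl("\\.tsv$|\\.txt$", p, ignore.case = TRUE)) "\t" else ","
  expr_df <- utils::read.table(expression_file, header = TRUE,
                               sep = sep_of(expression_file),
                               check.names = FALSE, stringsAsFactors = FALSE)
  coord_df <- utils::read.table(coords_file, header = TRUE,
                                sep = sep_of(coords_file),
                                check.names = FALSE, stringsAsFactors = FALSE)

  spot_ids <- as.character(expr_df[[1]])
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  coord_ids <- as.character(coord_df[[1]])

  missing_in_coords <- setdiff(spot_ids, coord_ids)
  missing_in_expr <- setdiff(coord_ids, spot_ids)
  if (length(missing_in_coords) || length(missing_in_expr)) {
    msg <- "spot id mismatch between expression and coordinate tables"
    if (length(missing_in_coords))
      msg <- paste0(msg, "; missing from coordinates: ",
                    paste(utils::head(missing_in_coords, 10), collapse = ", "))
    if (length(missing_in_expr))
      msg <- paste0(msg, "; missing from expression: ",
                    paste(utils::head(missing_in_expr, 10), collapse = ", "))
    stop(msg)
  }
  coord_df <- coord_df[match(spot_ids, coord_ids), , drop = FALSE]

  if (!all(c("x", "y") %in% names(coord_df)))
    stop("coordinate table must contain columns 'x' and 'y'")
  coords <- as.matrix(coord_df[, c("x", "y")])

  labels <- NULL
  if (label_col %in% names(coord_df)) labels <- as.character(coord_df[[label_col]])

  st_slice(expr, coords, labels = labels, spot_ids = spot_ids,
           gene_ids = colnames(expr), slice_id = slice_id)
}

#' Write a slice to disk as a CSV pair
#'
#' Inverse of [read_slice]: writes the expression table (spot_id + genes) and
#' coordinate table (spot_id, x, y, and a label column when the slice is
#' annotated).
#'
#' @param slice An [st_slice].
#' @param expression_file,coords_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_slice <- function(slice, expression_file, coords_file) {
  stopifnot(inherits(slice, "st_slice"))
  expr_df <- data.frame(spot_id = slice$spot_ids,
                        slice$expression, check.names = FALSE)
  utils::write.csv(expr_df, expression_file, row.names = FALSE, quote = FALSE)
  coord_df <- data.frame(spot_id = slice$spot_ids,
                         x = slice$coords[, 1], y = slice$coords[, 2])
  if (!is.null(slice$labels)) coord_df$label <- slice$labels
  utils::write.csv(coord_df, coords_file, row.names = FALSE, quote = FALSE)
  invisible(c(expression_file, coords_file))
}
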