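#' Binary contact fingerprint matrix
#'
#' The central data container: a frames x contact-nodes binary matrix where
#' entry (f, n) is 1 when contact node n is present in frame f. Column names
#' are canonical contact-node ids (see [contact_node_id()]).
#'
#' @param values numeric/integer matrix of 0/1 values (frames in rows).
#' @param provenance free-text description of where the matrix came from.
#' @return a `fingerprint_matrix` object.
#' @export
fingerprint_matrix <- function(values, provenance = "unspecified") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("fingerprint matrix needs column labels")
  if (anyDuplicated(colnames(values))) {
    stop("duplicate contact node labels: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (!all(values %in% c(0, 1))) stop("fingerprint values must be binary 0/1")
  storage.mode(values) <- "integer"
  colnames(values) <- normalize_generic_id(colnames(values))
  rownames(values) <- NULL
  structure(
    list(values = values, provenance = provenance),
    class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d frames x %d contact nodes\n",
              nrow(x$values), ncol(x$values)))
  cst <- constant_nodes(x)
  if (length(cst)) cat("constant columns:", paste(cst, collapse = ", "), "\n")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.matrix.fingerprint_matrix <- function(x, ...) x$values

#' @rdname fingerprint_matrix
#' @param x a `fingerprint_matrix`.
#' @export
n_frames <- function(x) nrow(x$values)

#' @rdname fingerprint_matrix
#' @export
node_labels <- function(x) colnames(x$values)

#' Contact nodes whose column never changes
#'
#' Constant columns carry no dependency information; they are retained as
#' isolated network nodes but flagged here so callers can report them.
#'
#' @param x a `fingerprint_matrix`.
#' @return character vector of constant column labels.
#' @export
constant_nodes <- function(x) {
  v <- x$values
  if (nrow(v) == 0L) return(character(0))
  colnames(v)[apply(v, 2L, function(col) all(col == col[1L]))]
}

#' Read a fingerprint matrix from a tab-separated file
#'
#' Expects a header row of canonical contact-node ids followed by one row of
#' 0/1 values per frame. Any non-binary cell or duplicate header is a format
#' error naming the offending row/column.
#'
#' @param path file path.
#' @return a `fingerprint_matrix`.
#' @export
read_fingerprint_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("fingerprint file is empty: ", path)
  headers <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  headers <- normalize_generic_id(headers)
  if (anyDuplicated(headers)) {
    stop("duplicate column header(s) in ", path, ": ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  }
  body <- lines[-1L]
  vals <- matrix(0L, nrow = length(body), ncol = length(headers),
                 dimnames = list(NULL, headers))
  for (i in seq_along(body)) {
    cells <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != length(headers)) {
      stop("row ", i, " has ", length(cells), " cells, expected ", length(headers))
    }
    bad <- !cells %in% c("0", "1")
    if (any(bad)) {
      stop("non-binary cell at row ", i, ", column '",
           headers[which(bad)[1L]], "': '", cells[which(bad)[1L]], "'")
    }
    vals[i, ] <- as.integer(cells)
  }
  fingerprint_matrix(vals, provenance = paste0("file:", path))
}

#' Write a fingerprint matrix as a tab-separated file
#'
#' @param x a `fingerprint_matrix`.
#' @param path output file path.
#' @export
write_fingerprint_table <- function(x, path) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(x$values), collapse = "\t"), con)
  if (nrow(x$values) > 0L) {
    writeLines(apply(x$values, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
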