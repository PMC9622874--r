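#' Read a two-column interaction edge list
#'
#' Reads a delimited text file of pairwise interactions (one of the three
#' network layers: mRNA-miRNA, miRNA-lncRNA or drug-lncRNA). The delimiter is
#' auto-detected between tab and comma unless given. Identifiers keep their
#' original case but are compared case-insensitively after trimming, so
#' duplicate pairs differing only in case collapse to a single edge.
#'
#' @param path path to a delimited file with at least two columns
#'   (source, target); extra columns are ignored.
#' @param layer layer tag, one of `"mrna_mirna"`, `"mirna_lncrna"`,
#'   `"drug_lncrna"`.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @param header does the file carry a header line?
#' @return A data frame of class `interaction_edges` with columns `source`
#'   and `target`, the layer in `attr(, "layer")`, and the raw/deduplicated
#'   row counts in `attr(, "load_log")`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "A\tB", "A\tC"), f)
#' e <- read_edge_list(f, "mrna_mirna")
#' nrow(e)  # 2: the duplicate pair collapses
read_edge_list <- function(path,
                           layer = c("mrna_mirna", "mirna_lncrna", "drug_lncrna"),
                           sep = NULL, header = FALSE) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("edge-list file is empty: ", path)
  if (is.null(sep)) {
    sep <- if (sum(grepl("\t", lines)) >= sum(grepl(",", lines))) "\t" else ","
  }
  first_data <- if (header) 2L else 1L
  if (header && length(lines) < 2) stop("edge-list file has a header but no rows: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  bad <- bad[bad >= first_data]
  if (length(bad)) {
    stop("malformed edge row (fewer than 2 fields) at line ",
         paste(bad, collapse = ", "), " of ", path)
  }
  src <- trimws(vapply(parts, `[[`, "", 1L))[seq(first_data, length(parts))]
  tgt <- trimws(vapply(parts, `[[`, "", 2L))[seq(first_data, length(parts))]
  make_edges(data.frame(source = src, target = tgt, stringsAsFactors = FALSE),
             layer, path = path)
}

#' Construct an interaction edge collection from a data frame
#'
#' In-memory counterpart of [read_edge_list()]: validates, deduplicates
#' (case-insensitively) and tags a two-column edge table.
#'
#' @param edges data frame whose first two columns are source and target ids.
#' @inheritParams read_edge_list
#' @param path optional provenance string recorded in the load log.
#' @return An `interaction_edges` data frame; see [read_edge_list()].
#' @export
make_edges <- function(edges,
                       layer = c("mrna_mirna", "mirna_lncrna", "drug_lncrna"),
                       path = NA_character_) {
  layer <- match.arg(layer)
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  src <- trimws(as.character(edges[[1L]]))
  tgt <- trimws(as.character(edges[[2L]]))
  if (any(!nzchar(src)) || any(!nzchar(tgt))) {
    stop("empty source or target identifier in edge list")
  }
  if (any(norm_id(src) == norm_id(tgt))) {
    stop("self-pair in edge list; the two layers of a bipartite network are disjoint")
  }
  n_raw <- length(src)
  keep <- !duplicated(paste(norm_id(src), norm_id(tgt), sep = "\r"))
  out <- data.frame(source = src[keep], target = tgt[keep],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("edge list is empty after validation")
  attr(out, "layer") <- layer
  attr(out, "load_log") <- list(path = path, n_raw = n_raw, n_dedup = nrow(out))
  class(out) <- c("interaction_edges", "data.frame")
  out
}

#' Read a PaDEL-style molecular descriptor CSV
#'
#' The first column (conventionally `Name`) holds molecule identifiers; all
#' remaining columns are numeric 1D-2D descriptors. Empty cells become `NA`
#' (never zero: zero is a valid descriptor value). Column order is preserved.
#'
#' @param path path to the CSV file.
#' @param natom_name name of the atom-count descriptor column, if present;
#'   recorded on the returned matrix for the screening filter.
#' @return A numeric matrix with molecule ids as row names and the atom-count
#'   column name in `attr(, "natom_column")` (`NULL` when absent).
#' @export
read_descriptor_csv <- function(path, natom_name = "nAtom") {
  if (!file.exists(path)) stop("descriptor file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("descriptor CSV needs a name column plus descriptors: ", path)
  ids <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(norm_id(ids))) {
    dup <- unique(ids[duplicated(norm_id(ids))])
    stop("duplicate molecule identifiers in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(is.na(num) & !is.na(v))) {
        stop("non-numeric value in descriptor column '", names(vals)[j],
             "' of ", path)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  descriptor_matrix(m, natom_column = natom_name)
}

#' Construct a descriptor matrix
#'
#' Validates a molecules-by-descriptors numeric matrix: unique row and column
#' names, `NA` as the only missing-value sentinel, and (when present) a
#' non-negative integer atom-count column.
#'
#' @param values numeric matrix; rows are molecules, columns descriptors.
#' @param natom_column name of the atom-count column or `NULL`; silently
#'   dropped when the column does not exist in `values`.
#' @return The matrix with `attr(, "natom_column")` set.
#' @export
descriptor_matrix <- function(values, natom_column = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("descriptor matrix needs molecule row names and descriptor column names")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate descriptor names")
  if (anyDuplicated(norm_id(rownames(values)))) stop("duplicate molecule identifiers")
  if (!is.null(natom_column) && natom_column %in% colnames(values)) {
    na_col <- values[, natom_column]
    ok <- is.na(na_col) | (na_col >= 0 & na_col == round(na_col))
    if (!all(ok)) stop("atom-count column '", natom_column,
                       "' must be a non-negative integer")
    attr(values, "natom_column") <- natom_column
  } else {
    attr(values, "natom_column") <- NULL
  }
  values
}

#' @rdname read_descriptor_csv
#' @param m a descriptor matrix.
#' @param name_column header of the identifier column written first.
#' @export
write_descriptor_csv <- function(m, path, name_column = "Name") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- name_column
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# internal: uniform TSV report writer
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.interaction_edges <- function(x, ...) {
  log <- attr(x, "load_log")
  cat(sprintf("Interaction edges [%s]: %d edges (%d raw rows)\n",
              attr(x, "layer"), nrow(x),
              if (is.null(log)) nrow(x) else log$n_raw))
  print.data.frame(head(x, 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more edges\n")
  invisible(x)
}
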