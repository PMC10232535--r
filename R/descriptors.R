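# Descriptor tables: one fixed-length named numeric vector per chemical
# entity (indole substrate, alkene coupling partner, or CCA catalyst).
# Sterimol-type lengths are in Angstrom, charges in units of e, the rest
# dimensionless; all are consumed as precomputed features.

DEFAULT_BLOCK_DIMS <- c(indole = 35L, alkene = 6L, cca = 66L)

#' Construct a descriptor table
#'
#' @param x Numeric matrix or data frame, one row per entity. Row names
#'   (or a first character column named `entity_id`) identify entities.
#' @param entity_class One of `"indole"`, `"alkene"`, `"cca"`.
#' @param expected_length Expected number of descriptor columns. Defaults
#'   to the standard schema (indole 35, alkene 6, cca 66); a differing
#'   count raises a warning (the schema is data-driven), never an error.
#' @return A `descriptor_table`: numeric matrix with entity ids as row
#'   names and an `entity_class` attribute.
#' @export
descriptor_table <- function(x, entity_class = c("indole", "alkene", "cca"),
                             expected_length = NULL) {
  entity_class <- match.arg(entity_class)
  if (is.data.frame(x)) {
    id_col <- which(names(x) == "entity_id")
    if (length(id_col) == 1) {
      ids <- as.character(x[[id_col]])
      x <- x[, -id_col, drop = FALSE]
    } else {
      ids <- rownames(x)
    }
    non_num <- !vapply(x, is.numeric, logical(1))
    if (any(non_num)) {
      stop("non-numeric descriptor column(s) in ", entity_class, " table: ",
           paste(names(x)[non_num], collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(x)
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("descriptor table must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    stop("descriptor table rows must be named by entity id", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicate entity_id in ", entity_class, " table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("non-finite descriptor value at row '", rownames(x)[bad[1]],
         "', column ", bad[2], " of the ", entity_class, " table",
         call. = FALSE)
  }
  expected <- expected_length %||% unname(DEFAULT_BLOCK_DIMS[entity_class])
  if (ncol(x) != expected) {
    warning("'", entity_class, "' table has ", ncol(x),
            " descriptor columns (default schema expects ", expected, ")",
            call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("d%03d", seq_len(ncol(x)))
  structure(x, entity_class = entity_class, class = c("descriptor_table", "matrix", "array"))
}

#' Read a descriptor table from CSV
#'
#' Expects a header row naming the descriptors and the entity id in the
#' first column; UTF-8, `.` decimal separator. Ragged rows, duplicate ids
#' and non-numeric cells are rejected with located messages.
#'
#' @param path Path to a CSV file.
#' @inheritParams descriptor_table
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, entity_class = c("indole", "alkene", "cca"),
                                  expected_length = NULL) {
  entity_class <- match.arg(entity_class)
  if (!file.exists(path)) stop("descriptor file not found: ", path, call. = FALSE)
  fields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(fields)) > 1) {
    stop("ragged CSV (rows with differing field counts) in ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("descriptor CSV needs an id column plus descriptors: ", path, call. = FALSE)
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      parsed <- suppressWarnings(as.numeric(as.character(vals[[j]])))
      bad_row <- which(is.na(parsed))[1]
      if (is.na(bad_row)) bad_row <- 1L
      stop("non-numeric cell in ", path, " at row ", bad_row + 1L,
           " (entity '", ids[bad_row], "'), column '", names(vals)[j], "'",
           call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  descriptor_table(m, entity_class, expected_length)
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> class:", attr(x, "entity_class"),
      "|", nrow(x), "entities x", ncol(x), "descriptors\n")
  invisible(x)
}
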