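# Reaction encoding: concatenation of the indole, alkene and CCA
# descriptor blocks plus the temperature, in that fixed order. Under the
# default schema this is the 108-dimensional physical-organic space
# (35 + 6 + 66 + 1).

#' Encode reactions as descriptor vectors
#'
#' Each reaction is mapped to `[indole block | alkene block | cca block |
#' temperature]`. Column names are the table column names prefixed with
#' the entity class, so two blocks can never collide; block order is
#' fixed across all encodings produced from the same tables.
#'
#' @param records A [reaction_records()] data frame (or any data frame
#'   with the id and temperature columns).
#' @param tables Named list with `indole`, `alkene`, `cca`
#'   [descriptor_table()]s.
#' @return Numeric matrix, one row per record (row names = reaction ids).
#' @export
encode_reactions <- function(records, tables) {
  for (cls in c("indole", "alkene", "cca")) {
    if (is.null(tables[[cls]])) stop("missing descriptor table: ", cls, call. = FALSE)
    ids <- records[[paste0(cls, "_id")]]
    unknown <- setdiff(unique(ids), rownames(tables[[cls]]))
    if (length(unknown)) {
      stop("unknown ", cls, " id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  blocks <- lapply(c("indole", "alkene", "cca"), function(cls) {
    tab <- tables[[cls]]
    m <- tab[records[[paste0(cls, "_id")]], , drop = FALSE]
    colnames(m) <- paste(cls, colnames(tab), sep = ".")
    m
  })
  x <- cbind(blocks[[1]], blocks[[2]], blocks[[3]],
             temperature = as.numeric(records$temperature))
  rownames(x) <- records$reaction_id
  x
}

#' Build an encoded dataset for model fitting
#'
#' Bundles the encoded design matrix with the free-energy targets; the
#' unit of work for [kfold_cv()], [rank_algorithms()] and [fit_base()].
#'
#' @inheritParams encode_reactions
#' @return An `encoded_dataset`: list with `x` (matrix), `y` (ddg_exp,
#'   kcal/mol) and `ids`.
#' @export
encoded_dataset <- function(records, tables) {
  x <- encode_reactions(records, tables)
  structure(list(x = x, y = records$ddg_exp, ids = records$reaction_id),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("<encoded_dataset>", nrow(x$x), "reactions x", ncol(x$x),
      "descriptors; ddg range",
      paste(round(range(x$y), 3), collapse = " .. "), "kcal/mol\n")
  invisible(x)
}
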