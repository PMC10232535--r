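# Reaction records: one experiment each, pairing substrate/catalyst ids
# with the measured enantiomeric excess and temperature. The derived
# free-energy difference ddg_exp is cached on the record and kept
# consistent with ee_observed by construction.

#' Assemble and validate reaction records
#'
#' @param df Data frame with columns `reaction_id`, `indole_id`,
#'   `alkene_id`, `cca_id`, `temperature` (Kelvin), `ee_observed`
#'   (unsigned fraction in `[0, 0.999]`). An optional `domain` column (or
#'   the `domain` argument) labels each record `source` or `target`.
#' @param domain Default domain label applied when `df` has no `domain`
#'   column.
#' @return A `reaction_records` data frame with a `ddg_exp` column
#'   (kcal/mol) appended.
#' @export
reaction_records <- function(df, domain = c("source", "target")) {
  domain <- match.arg(domain)
  need <- c("reaction_id", "indole_id", "alkene_id", "cca_id",
            "temperature", "ee_observed")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("reaction records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$domain)) df$domain <- domain
  if (!all(df$domain %in% c("source", "target"))) {
    stop("'domain' must be 'source' or 'target'", call. = FALSE)
  }
  if (anyDuplicated(df$reaction_id)) {
    dup <- unique(df$reaction_id[duplicated(df$reaction_id)])
    stop("duplicate reaction_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$temperature)) || any(df$temperature <= 0)) {
    stop("temperatures must be positive Kelvin", call. = FALSE)
  }
  if (any(!is.finite(df$ee_observed)) || any(df$ee_observed < 0) ||
      any(df$ee_observed > EE_MAX)) {
    bad <- df$reaction_id[!is.finite(df$ee_observed) | df$ee_observed < 0 |
                          df$ee_observed > EE_MAX][1]
    stop("ee_observed out of [0, ", EE_MAX, "] for reaction '", bad, "'",
         call. = FALSE)
  }
  df$ddg_exp <- ee_to_ddg(df$ee_observed, df$temperature)
  for (col in c("reaction_id", "indole_id", "alkene_id", "cca_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  class(df) <- c("reaction_records", "data.frame")
  df
}

#' Read reaction records from CSV
#'
#' @param path Path to a CSV file with the columns listed in
#'   [reaction_records()].
#' @inheritParams reaction_records
#' @export
read_reaction_records <- function(path, domain = c("source", "target")) {
  if (!file.exists(path)) stop("record file not found: ", path, call. = FALSE)
  reaction_records(utils::read.csv(path, stringsAsFactors = FALSE), domain)
}

#' Cross-check a reaction dataset against its descriptor tables
#'
#' Report-returning validation: unresolvable entity ids, out-of-range
#' e.e. values and duplicated reaction ids are listed rather than thrown,
#' so a whole file can be audited in one pass. The dataset is accepted
#' iff the report is empty.
#'
#' @param records Data frame of reaction records (validated or raw; raw
#'   frames are checked field-wise without being rejected outright).
#' @param tables Named list with elements `indole`, `alkene`, `cca`, each
#'   a [descriptor_table()].
#' @return A `validation_report`: data frame with columns `reaction_id`,
#'   `field`, `problem`; zero rows means the dataset is clean.
#' @export
validate_dataset <- function(records, tables) {
  issues <- list()
  flag <- function(id, field, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      reaction_id = as.character(id), field = field, problem = problem,
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(records$reaction_id)) {
    for (id in unique(records$reaction_id[duplicated(records$reaction_id)])) {
      flag(id, "reaction_id", "duplicated")
    }
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ee <- r$ee_observed
    if (!is.finite(ee) || ee < 0 || ee > EE_MAX) {
      flag(r$reaction_id, "ee_observed",
           sprintf("out of [0, %s]: %s", EE_MAX, format(ee)))
    }
    if (!is.finite(r$temperature) || r$temperature <= 0) {
      flag(r$reaction_id, "temperature", "not a positive Kelvin value")
    }
    for (cls in c("indole", "alkene", "cca")) {
      id <- r[[paste0(cls, "_id")]]
      if (!id %in% rownames(tables[[cls]])) {
        flag(r$reaction_id, paste0(cls, "_id"),
             sprintf("unknown %s '%s'", cls, id))
      }
    }
  }
  report <- if (length(issues)) do.call(rbind, issues) else
    data.frame(reaction_id = character(), field = character(),
               problem = character(), stringsAsFactors = FALSE)
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> dataset accepted: no issues\n")
  } else {
    cat("<validation_report>", nrow(x), "issue(s):\n")
    print.data.frame(x)
  }
  invisible(x)
}

#' Write a validation report to JSON
#'
#' @param report A [validate_dataset()] result.
#' @param path Output file path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(accepted = nrow(report) == 0, n_issues = nrow(report),
         issues = as.data.frame(unclass(report))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
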