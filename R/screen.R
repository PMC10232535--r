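# Virtual screening: enumerate the combinatorial candidate-CCA library
# (backbone x N-substituent), predict each candidate's selectivity in a
# fixed substrate context, rank by predicted e.e., and summarize the
# distribution in e.e. bins.

#' Enumerate the combinatorial candidate library
#'
#' Forms the full Cartesian product of backbones and N-substituents and
#' resolves each pair to a CCA descriptor vector, either from a lookup
#' table keyed by the pair (default, "descriptors as data") or by
#' concatenating backbone-block and substituent-block sub-tables
#' (compositional mode).
#'
#' @param backbones,substituents Character vectors of ids (non-empty).
#' @param descriptor_source Either a data frame with columns
#'   `backbone_id`, `substituent_id` plus one numeric column per CCA
#'   descriptor (lookup mode), or a list with elements `backbone` and
#'   `substituent`, each a matrix of per-part descriptor blocks keyed by
#'   row name (compositional mode).
#' @return A `candidate_set`: data frame with `candidate_id`,
#'   `backbone_id`, `substituent_id`, carrying the candidate descriptor
#'   matrix as attribute `"descriptors"`.
#' @export
enumerate_candidates <- function(backbones, substituents, descriptor_source) {
  if (!length(backbones) || !length(substituents)) {
    stop("backbones and substituents must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(substituent_id = as.character(substituents),
                      backbone_id = as.character(backbones),
                      stringsAsFactors = FALSE)[, c("backbone_id", "substituent_id")]
  if (is.data.frame(descriptor_source)) {
    key <- paste(descriptor_source$backbone_id, descriptor_source$substituent_id, sep = "\r")
    want <- paste(grid$backbone_id, grid$substituent_id, sep = "\r")
    idx <- match(want, key)
    if (anyNA(idx)) {
      miss <- grid[is.na(idx), ][1, ]
      stop("no descriptor row for candidate pair (", miss$backbone_id, ", ",
           miss$substituent_id, ")", call. = FALSE)
    }
    desc_cols <- setdiff(names(descriptor_source), c("backbone_id", "substituent_id", "candidate_id"))
    desc <- as.matrix(descriptor_source[idx, desc_cols, drop = FALSE])
  } else if (is.list(descriptor_source) &&
             all(c("backbone", "substituent") %in% names(descriptor_source))) {
    bb <- descriptor_source$backbone
    sb <- descriptor_source$substituent
    if (!all(grid$backbone_id %in% rownames(bb)) ||
        !all(grid$substituent_id %in% rownames(sb))) {
      stop("unresolvable backbone or substituent id in compositional source",
           call. = FALSE)
    }
    desc <- cbind(bb[grid$backbone_id, , drop = FALSE],
                  sb[grid$substituent_id, , drop = FALSE])
  } else {
    stop("descriptor_source must be a pair-keyed data frame or a ",
         "list(backbone=, substituent=) of block tables", call. = FALSE)
  }
  out <- data.frame(candidate_id = paste(grid$backbone_id, grid$substituent_id, sep = "_"),
                    backbone_id = grid$backbone_id,
                    substituent_id = grid$substituent_id,
                    stringsAsFactors = FALSE)
  rownames(desc) <- out$candidate_id
  attr(out, "descriptors") <- desc
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Screen a candidate library in a fixed substrate context
#'
#' Each candidate CCA is encoded with the context's indole, alkene and
#' temperature, its free-energy difference is predicted with the given
#' model (transfer or base), converted to e.e., and the library is
#' ranked by descending predicted e.e. (equivalently descending
#' predicted free energy — the conversion is monotone). Ties are broken
#' by `candidate_id` so the ranking is reproducible.
#'
#' @param model A `transfer_model` or `base_model`.
#' @param candidates An [enumerate_candidates()] result.
#' @param context List with `indole_id`, `alkene_id`, `temperature`
#'   (Kelvin).
#' @param tables Descriptor tables for the substrate blocks (the CCA
#'   block comes from the candidates).
#' @return A `screening_result`: data frame with `candidate_id`,
#'   `backbone_id`, `substituent_id`, `ddg_pred` (kcal/mol), `ee_pred`
#'   (signed fraction; negative = opposite enantiomer favoured), `rank`,
#'   ordered by rank.
#' @export
screen <- function(model, candidates, context, tables) {
  if (nrow(candidates) == 0) stop("empty candidate list", call. = FALSE)
  desc <- attr(candidates, "descriptors")
  cca_tab <- descriptor_table(desc, "cca", expected_length = ncol(desc))
  recs <- data.frame(reaction_id = candidates$candidate_id,
                     indole_id = context$indole_id,
                     alkene_id = context$alkene_id,
                     cca_id = candidates$candidate_id,
                     temperature = context$temperature,
                     stringsAsFactors = FALSE)
  x <- encode_reactions(recs, list(indole = tables$indole,
                                   alkene = tables$alkene,
                                   cca = cca_tab))
  ddg <- as.numeric(predict(model, x))
  # signed e.e.: negative values mean the opposite enantiomer is favoured
  # and rank last; the conversion is monotone so the e.e. ranking equals
  # the free-energy ranking
  ee <- ddg_to_ee(ddg, context$temperature)
  out <- data.frame(candidate_id = candidates$candidate_id,
                    backbone_id = candidates$backbone_id,
                    substituent_id = candidates$substituent_id,
                    ddg_pred = ddg, ee_pred = ee,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ee_pred, out$candidate_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "context") <- context
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Top-k candidates of a screen
#'
#' @param result A [screen()] result.
#' @param k Number of candidates, `1 <= k <= N`.
#' @return The first `k` rows by rank.
#' @export
top_k <- function(result, k) {
  if (k < 1 || k > nrow(result)) {
    stop("k must be in [1, ", nrow(result), "]", call. = FALSE)
  }
  out <- result[seq_len(k), ]
  attr(out, "context") <- attr(result, "context")
  out
}

#' Bin the predicted-e.e. distribution
#'
#' With the default thresholds (0.40, 0.80) the bins are: predicted e.e.
#' below 40%, between 40 and 80% (both boundaries inclusive), and above
#' 80%. Generally, values equal to a threshold are counted in the
#' interior (non-extreme) bin; counts always sum to the library size.
#'
#' @param result A [screen()] result.
#' @param thresholds Strictly increasing e.e. cut points in (0, 1).
#' @return Named integer vector of counts, one per interval.
#' @export
bin_distribution <- function(result, thresholds = c(0.40, 0.80)) {
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must be strictly increasing within (0, 1)", call. = FALSE)
  }
  ee <- result$ee_pred
  m <- length(thresholds)
  edges <- c(-Inf, thresholds, Inf)
  counts <- integer(m + 1)
  assigned <- rep(FALSE, length(ee))
  counts[1] <- sum(ee < thresholds[1])
  assigned <- ee < thresholds[1]
  for (j in seq_len(m - 1)) {
    inbin <- !assigned & ee >= thresholds[j] & ee <= thresholds[j + 1]
    counts[j + 1] <- sum(inbin)
    assigned <- assigned | inbin
  }
  counts[m + 1] <- sum(!assigned)
  labels <- c(sprintf("<%g%%", 100 * thresholds[1]))
  if (m > 1) {
    labels <- c(labels, sprintf("%g-%g%%", 100 * thresholds[-m], 100 * thresholds[-1]))
  }
  labels <- c(labels, sprintf(">%g%%", 100 * thresholds[m]))
  stats::setNames(counts, labels)
}

#' @export
print.screening_result <- function(x, n = 5, ...) {
  ctx <- attr(x, "context")
  cat("<screening_result>", nrow(x), "candidates | context:",
      ctx$indole_id, "/", ctx$alkene_id, "@", ctx$temperature, "K\n")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' @export
plot.screening_result <- function(x, thresholds = c(0.40, 0.80), ...) {
  graphics::hist(100 * x$ee_pred, breaks = 20,
                 xlab = "predicted e.e. (%)", main = "Virtual screen", ...)
  graphics::abline(v = 100 * thresholds, lty = 2)
  invisible(x)
}

#' Write a screening result to CSV
#'
#' @param result A [screen()] result.
#' @param path Output path; columns `candidate_id`, `backbone_id`,
#'   `substituent_id`, `ddg_pred_kcal_mol`, `ee_pred`, `rank`.
#' @export
write_screening_csv <- function(result, path) {
  out <- data.frame(candidate_id = result$candidate_id,
                    backbone_id = result$backbone_id,
                    substituent_id = result$substituent_id,
                    ddg_pred_kcal_mol = result$ddg_pred,
                    ee_pred = result$ee_pred,
                    rank = result$rank)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
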