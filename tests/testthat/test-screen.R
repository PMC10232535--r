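# Candidate enumeration, screening, ranking and binning.

lookup_source <- function(nb, ns, p = 5, seed = 3) {
  set.seed(seed)
  grid <- expand.grid(substituent_id = sprintf("s%02d", seq_len(ns)),
                      backbone_id = sprintf("b%02d", seq_len(nb)),
                      stringsAsFactors = FALSE)
  cbind(grid[, c("backbone_id", "substituent_id")],
        as.data.frame(matrix(rnorm(nrow(grid) * p), ncol = p,
                             dimnames = list(NULL, sprintf("d%02d", 1:p)))))
}

screen_setup <- function(seed = 1) {
  cfg <- synthetic_config(seed = seed)
  lib <- generate_descriptor_library(cfg)
  src <- generate_source_domain(cfg, lib)
  tgt <- generate_target_domain(cfg, lib, src$latent)
  base <- fit_base(encoded_dataset(src$records, lib$tables))
  tm <- fit_transfer(base, tgt$records, lib$tables, loo = FALSE)
  cand <- enumerate_candidates(lib$backbones, lib$substituents, lib$candidates)
  list(lib = lib, tgt = tgt, tm = tm, cand = cand)
}

test_that("the Cartesian product has the expected size and unique ids", {
  src <- lookup_source(4, 90)
  cand <- enumerate_candidates(unique(src$backbone_id), unique(src$substituent_id), src)
  expect_equal(nrow(cand), 360)
  expect_false(anyDuplicated(cand$candidate_id) > 0)

  small <- lookup_source(2, 3)
  c2 <- enumerate_candidates(unique(small$backbone_id), unique(small$substituent_id), small)
  expect_equal(nrow(c2), 6)
  one <- lookup_source(1, 1)
  expect_equal(nrow(enumerate_candidates("b01", "s01", one)), 1)
})

test_that("unresolvable pairs and empty part lists are rejected", {
  src <- lookup_source(2, 3)
  expect_error(enumerate_candidates(c("b01", "b99"), unique(src$substituent_id), src),
               "b99")
  expect_error(enumerate_candidates(character(0), "s01", src), "non-empty")
})

test_that("compositional descriptor sources concatenate part blocks", {
  bb <- matrix(1:4, 2, dimnames = list(c("b1", "b2"), c("k1", "k2")))
  sb <- matrix(5:10, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("m1", "m2")))
  cand <- enumerate_candidates(c("b1", "b2"), c("s1", "s2", "s3"),
                               list(backbone = bb, substituent = sb))
  expect_equal(nrow(cand), 6)
  desc <- attr(cand, "descriptors")
  expect_equal(ncol(desc), 4)
  expect_equal(unname(desc["b1_s1", ]), c(1, 3, 5, 8))
  expect_error(enumerate_candidates("b3", "s1", list(backbone = bb, substituent = sb)),
               "unresolvable")
})

test_that("screening ranks the whole library by predicted e.e.", {
  s <- screen_setup()
  res <- screen(s$tm, s$cand, s$tgt$context, s$lib$tables)
  expect_equal(nrow(res), nrow(s$cand))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(!is.unsorted(rev(res$ee_pred)))
  # monotone conversion: e.e. order equals free-energy order
  expect_equal(order(-res$ee_pred), order(-res$ddg_pred))
  expect_equal(res$ee_pred, ddg_to_ee(res$ddg_pred, s$tgt$context$temperature))
})

test_that("screening is deterministic and ties break by candidate id", {
  s <- screen_setup()
  res1 <- screen(s$tm, s$cand, s$tgt$context, s$lib$tables)
  res2 <- screen(s$tm, s$cand, s$tgt$context, s$lib$tables)
  expect_identical(res1, res2)

  # all-identical candidates: stable lexicographic ranking
  dup <- s$lib$candidates[rep(1, 4), ]
  dup$substituent_id <- sprintf("s%d", 4:1)
  cand_dup <- enumerate_candidates(dup$backbone_id[1], dup$substituent_id, dup)
  res <- screen(s$tm, cand_dup, s$tgt$context, s$lib$tables)
  expect_equal(res$candidate_id, sort(res$candidate_id))
  expect_equal(length(unique(res$ddg_pred)), 1)
})

test_that("top_k returns the ranked head and respects bounds", {
  s <- screen_setup()
  res <- screen(s$tm, s$cand, s$tgt$context, s$lib$tables)
  expect_equal(top_k(res, nrow(res)), res)
  expect_equal(nrow(top_k(res, 3)), 3)
  expect_equal(top_k(res, 1)$candidate_id,
               res$candidate_id[which.max(res$ee_pred)])
  expect_error(top_k(res, 0), "k must be")
  expect_error(top_k(res, nrow(res) + 1), "k must be")
})

test_that("bin counts follow the documented boundary convention", {
  fake <- data.frame(ee_pred = c(0.10, 0.50, 0.90))
  expect_equal(unname(bin_distribution(fake)), c(1, 1, 1))
  expect_equal(names(bin_distribution(fake)), c("<40%", "40-80%", ">80%"))
  # boundaries land in the interior bin
  edge <- data.frame(ee_pred = c(0.40, 0.80, 0.399999, 0.800001))
  expect_equal(unname(bin_distribution(edge)), c(1, 2, 1))
  low <- data.frame(ee_pred = rep(0.1, 7))
  expect_equal(unname(bin_distribution(low)), c(7, 0, 0))
  expect_error(bin_distribution(fake, c(0.8, 0.4)), "strictly increasing")
})

test_that("bin counts always sum to the library size", {
  s <- screen_setup()
  res <- screen(s$tm, s$cand, s$tgt$context, s$lib$tables)
  for (th in list(c(0.4, 0.8), c(0.25, 0.5, 0.75), 0.6)) {
    expect_equal(sum(bin_distribution(res, th)), nrow(res))
  }
})

test_that("ranking is invariant under strictly increasing score transforms", {
  s <- screen_setup()
  res <- screen(s$tm, s$cand, s$tgt$context, s$lib$tables)
  monotone <- exp(2 * res$ddg_pred) - 1
  expect_equal(order(-monotone), order(-res$ddg_pred))
  expect_equal(rank(-monotone, ties.method = "first"),
               rank(-res$ee_pred, ties.method = "first"))
})

test_that("screening rejects an empty candidate list", {
  s <- screen_setup()
  empty <- s$cand[0, ]
  attr(empty, "descriptors") <- attr(s$cand, "descriptors")[0, , drop = FALSE]
  class(empty) <- class(s$cand)
  expect_error(screen(s$tm, empty, s$tgt$context, s$lib$tables), "empty")
})
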