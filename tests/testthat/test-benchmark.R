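# Brute-force enumeration oracle: plain nested loops over a roster.
oracle_enumerate <- function(registry, ics) {
  out <- list()
  for (gwid in sort(registry$id[registry$level == "groupwise-direct"])) {
    if (registry$needs_ic[registry$id == gwid])
      for (ic in sort(ics)) out[[length(out) + 1]] <- c(gwid, NA, ic)
    else out[[length(out) + 1]] <- c(gwid, NA, NA)
  }
  for (gwid in sort(registry$id[registry$level == "groupwise-indirect"]))
    for (pwid in sort(registry$id[registry$level == "pairwise"])) {
      if (registry$needs_ic[registry$id == pwid])
        for (ic in sort(ics)) out[[length(out) + 1]] <- c(gwid, pwid, ic)
      else out[[length(out) + 1]] <- c(gwid, pwid, NA)
    }
  do.call(rbind, out)
}

mini_registry <- function(n_ind, n_pw_plain, n_pw_ic, n_dir_plain, n_dir_ic) {
  data.frame(
    id = c(paste0("ind", seq_len(n_ind), recycle0 = TRUE), paste0("pw", seq_len(n_pw_plain), recycle0 = TRUE),
           paste0("pwic", seq_len(n_pw_ic), recycle0 = TRUE), paste0("dir", seq_len(n_dir_plain), recycle0 = TRUE),
           paste0("diric", seq_len(n_dir_ic), recycle0 = TRUE)),
    level = c(rep("groupwise-indirect", n_ind), rep("pairwise", n_pw_plain + n_pw_ic),
              rep("groupwise-direct", n_dir_plain + n_dir_ic)),
    needs_ic = c(rep(FALSE, n_ind + n_pw_plain), rep(TRUE, n_pw_ic),
                 rep(FALSE, n_dir_plain), rep(TRUE, n_dir_ic)),
    needs_pairwise = c(rep(TRUE, n_ind), rep(FALSE, n_pw_plain + n_pw_ic + n_dir_plain + n_dir_ic)),
    stringsAsFactors = FALSE)
}

test_that("enumerate_configs matches the cross-product oracle on reduced rosters", {
  expect_equal(nrow(enumerate_configs(mini_registry(1, 1, 0, 0, 0), character())), 1)
  expect_equal(nrow(enumerate_configs(mini_registry(1, 0, 1, 0, 0), c("icA", "icB"))), 2)
  # worked example: 2 indirect, 2 non-IC pairwise, 1 IC pairwise, 3 ICs,
  # 2 direct non-IC, 1 direct IC -> 2*2 + 2*1*3 + 2 + 1*3 = 15
  reg15 <- mini_registry(2, 2, 1, 2, 1)
  ics <- c("icA", "icB", "icC")
  got <- enumerate_configs(reg15, ics)
  expect_equal(nrow(got), 15)
  oracle <- oracle_enumerate(reg15, ics)
  got_mat <- as.matrix(got[, c("groupwise", "pairwise", "ic")])
  dimnames(got_mat) <- NULL
  key <- function(m) sort(apply(m, 1, paste, collapse = "|"))
  expect_equal(key(got_mat), key(oracle))
  # config ids are unique and stable across calls
  expect_false(anyDuplicated(got$config_id) > 0)
  expect_identical(got, enumerate_configs(reg15, ics))
})

test_that("enumerate_configs rejects malformed rosters", {
  bad <- mini_registry(1, 1, 0, 0, 0)
  bad$needs_pairwise[2] <- TRUE    # a pairwise measure claiming to need one
  expect_error(enumerate_configs(bad, character()), "needs_pairwise")
  dup <- rbind(default_registry(), default_registry()[1, ])
  expect_error(enumerate_configs(dup), "unique")
  noneed <- mini_registry(1, 1, 0, 0, 0)
  noneed$needs_pairwise[1] <- FALSE
  expect_error(enumerate_configs(noneed, character()), "needs_pairwise")
})

test_that("similarity matrices equal entry-by-entry direct measure calls", {
  g <- toy_ontology()
  corpus <- toy_corpus()
  adm <- labeled_admissions(c("V1", "V2", "V3"),
                            list(c("c", "e"), c("d", "f"), c("e")),
                            c("X", "X", "Y"))
  ic <- corpus_ic(g, corpus)
  configs <- list(list(groupwise = "jaccard"),
                  list(groupwise = "ui"),
                  list(groupwise = "gic", ic = "resnik"),
                  list(groupwise = "avg", pairwise = "resnik", ic = "resnik"),
                  list(groupwise = "bma", pairwise = "rada"),
                  list(groupwise = "max", pairwise = "node_sim"),
                  list(groupwise = "min", pairwise = "jaccard_pw"))
  for (cfg in configs) {
    S <- compute_similarity_matrix(g, corpus, adm, cfg)
    expect_true(isSymmetric(S, tol = 1e-9))
    for (i in 1:3) for (j in 1:3) {
      a <- adm$profiles[[i]]; b <- adm$profiles[[j]]
      expected <- if (is.null(cfg$pairwise)) switch(cfg$groupwise,
        jaccard = gw_jaccard(a, b),
        ui = gw_ui(g, a, b),
        gic = gw_gic(g, a, b, ic))
      else gw_indirect(g, a, b, cfg$pairwise, cfg$groupwise, ic = ic)
      expect_equal(S[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("known profile geometry produces the expected jaccard matrix", {
  g <- ontology(list(r = character(), a = "r", b = "r", c = "r", d = "r"))
  adm <- labeled_admissions(c("V1", "V2", "V3"),
                            list(c("a", "b"), c("b", "c"), c("d")),
                            c("X", "X", "Y"))
  S <- compute_similarity_matrix(g, NULL, adm, list(groupwise = "jaccard"))
  expect_equal(S["V1", "V2"], 1 / 3)
  expect_equal(S["V1", "V3"], 0)
  expect_equal(S["V2", "V3"], 0)
  expect_equal(diag(S), c(V1 = 1, V2 = 1, V3 = 1))
  # identical profiles give off-diagonal 1
  adm2 <- labeled_admissions(c("V1", "V2"), list(c("a", "b"), c("a", "b")), c("X", "Y"))
  S2 <- compute_similarity_matrix(g, NULL, adm2, list(groupwise = "jaccard"))
  expect_equal(S2["V1", "V2"], 1)
})

test_that("build_pair_records flattens the upper triangle with shared flags", {
  fx_g <- ontology(list(r = character(), a = "r"))
  adm <- labeled_admissions(c("V1", "V2", "V3"), list("a", "a", "a"), c("X", "X", "Y"))
  S <- matrix(c(1, .5, .2, .5, 1, .3, .2, .3, 1), 3, 3,
              dimnames = list(adm$ids, adm$ids))
  rec <- build_pair_records(S, adm)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$shared, c(TRUE, FALSE, FALSE))
  expect_equal(rec$score, c(.5, .2, .3))
  # n(n-1)/2 scaling
  n <- 40
  admn <- labeled_admissions(sprintf("V%02d", 1:n), replicate(n, list("a")),
                             rep(c("X", "Y"), n / 2))
  Sn <- diag(n); dimnames(Sn) <- list(admn$ids, admn$ids)
  expect_equal(nrow(build_pair_records(Sn, admn)), n * (n - 1) / 2)
  expect_error(build_pair_records(Sn[1:3, 1:3], admn), "dimensions")
})

test_that("run_benchmark composes the stages and isolates config failures", {
  g <- toy_ontology()
  corpus <- toy_corpus()
  adm <- labeled_admissions(c("V1", "V2", "V3"),
                            list(c("c", "e"), c("c", "f"), c("d")),
                            c("X", "X", "Y"))
  cfgs <- data.frame(config_id = c("jaccard", "avg+rada", "gic"),
                     groupwise = c("jaccard", "avg", "gic"),
                     pairwise = c(NA, "rada", NA),
                     ic = c(NA, NA, NA),        # gic lacks its IC -> must fail
                     stringsAsFactors = FALSE)
  res <- run_benchmark(g, corpus, adm, cfgs)
  expect_equal(nrow(res), 3)
  expect_equal(res$status[1:2], c("ok", "ok"))
  expect_match(res$status[3], "failed")
  expect_true(all(is.na(res[3, c("auc", "mrr0")])))

  # row 1 must match manual composition of the stage operations
  S <- compute_similarity_matrix(g, corpus, adm, cfgs[1, ])
  manual_auc <- evaluate_auc(build_pair_records(S, adm))
  manual_rank <- evaluate_rankings(S, adm)
  expect_equal(res$auc[1], manual_auc$auc)
  expect_equal(res$mrr0[1], manual_rank$mrr0)
  expect_equal(res$a10[1], manual_rank$a_at_k)
  expect_equal(res$n_matchable[1], manual_rank$n_matchable)

  # empty config set: empty report, no error
  empty <- run_benchmark(g, corpus, adm, cfgs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("run_benchmark writes incremental results and summary tables", {
  g <- toy_ontology()
  adm <- labeled_admissions(c("V1", "V2", "V3", "V4"),
                            list(c("c", "e"), c("c", "f"), c("d"), c("d", "e")),
                            c("X", "X", "Y", "Y"))
  out <- withr::local_tempdir()
  cfgs <- enumerate_configs(default_registry()[default_registry()$id %in%
                              c("jaccard", "ui", "avg", "rada", "gic"), ],
                            ics = "seco")
  res <- run_benchmark(g, toy_corpus(), adm, cfgs, out_dir = out)
  tsv <- utils::read.delim(file.path(out, "results.tsv"))
  expect_equal(nrow(tsv), nrow(cfgs))
  expect_equal(tsv$config_id, res$config_id)
  expect_true(all(c("auc", "auc_lo", "auc_hi", "mrr0", "mrrna", "a10",
                    "a10_lo", "a10_hi", "n", "n_matchable", "status") %in% names(tsv)))
  sg <- utils::read.delim(file.path(out, "summary_groupwise.tsv"))
  expect_setequal(sg$component, unique(res$groupwise))
  expect_equal(sg$auc[sg$component == "jaccard"],
               mean(res$auc[res$groupwise == "jaccard"]))
  si <- utils::read.delim(file.path(out, "summary_ic.tsv"))
  expect_true("none" %in% si$component)
})
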