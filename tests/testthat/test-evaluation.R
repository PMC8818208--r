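make_records <- function(scores, shared)
  data.frame(admission_i = paste0("A", seq_along(scores)),
             admission_j = paste0("B", seq_along(scores)),
             score = scores, shared = shared, stringsAsFactors = FALSE)

test_that("evaluate_auc matches the brute-force pair-comparison oracle", {
  r <- make_records(c(0.9, 0.2, 0.5), c(TRUE, FALSE, FALSE))
  expect_equal(evaluate_auc(r)$auc, 1.0)
  # perfect separation
  r2 <- make_records(c(0.8, 0.9, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(evaluate_auc(r2)$auc, 1.0)
  # identical interleaved distributions give exactly one half
  r3 <- make_records(rep(c(0.1, 0.5, 0.9), 2), rep(c(TRUE, FALSE), each = 3))
  expect_equal(evaluate_auc(r3)$auc, 0.5)

  set.seed(14)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    scores <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    shared <- runif(n) < 0.4
    if (!any(shared) || all(shared)) next
    got <- evaluate_auc(make_records(scores, shared))
    expect_equal(got$auc, oracle_auc(scores, shared), tolerance = 1e-12)
    expect_gte(got$ci_lo, 0); expect_lte(got$ci_hi, 1)
    expect_lte(got$ci_lo, got$auc); expect_gte(got$ci_hi, got$auc)
  }
  expect_error(evaluate_auc(make_records(1:3, c(TRUE, TRUE, TRUE))), "AUC undefined")
  expect_error(evaluate_auc(make_records(1:3, c(FALSE, FALSE, FALSE))), "AUC undefined")
})

rank_fixture <- function() {
  adm <- labeled_admissions(c("A1", "A2", "A3"),
                            list(c("x"), c("x"), c("y")),
                            c("X", "X", "Y"))
  S <- matrix(0, 3, 3, dimnames = list(adm$ids, adm$ids))
  S["A1", "A2"] <- S["A2", "A1"] <- 0.9
  S["A1", "A3"] <- S["A3", "A1"] <- 0.2
  S["A2", "A3"] <- S["A3", "A2"] <- 0.5
  diag(S) <- 1
  list(adm = adm, S = S)
}

test_that("evaluate_rankings reproduces the hand-enumerated example", {
  fx <- rank_fixture()
  rk <- evaluate_rankings(fx$S, fx$adm, k = 10)
  expect_equal(rk$mrr0, 2 / 3)     # RR = (1, 1, 0)
  expect_equal(rk$mrrna, 1.0)
  expect_equal(rk$a_at_k, 2 / 3)
  expect_equal(rk$n_matchable, 2)
  expect_error(evaluate_rankings(fx$S, fx$adm, k = 0), "k must be")
})

test_that("degenerate label patterns are handled as specified", {
  # no two admissions share a diagnosis: mrr0 = 0, a@k = 0, mrrna errors
  adm <- labeled_admissions(c("A1", "A2", "A3"), list("x", "x", "y"),
                            c("X", "Y", "Z"))
  S <- diag(3); dimnames(S) <- list(adm$ids, adm$ids)
  expect_error(evaluate_rankings(S, adm), "no admission has a same-diagnosis")
  # nearest neighbour always shares the diagnosis: everything is 1
  fx <- rank_fixture()
  adm2 <- labeled_admissions(fx$adm$ids, fx$adm$profiles, c("X", "X", "X"))
  rk <- evaluate_rankings(fx$S, adm2)
  expect_equal(rk$mrr0, 1); expect_equal(rk$mrrna, 1); expect_equal(rk$a_at_k, 1)
})

test_that("tie policies order tied scores as documented", {
  adm <- labeled_admissions(paste0("A", 1:4), as.list(letters[1:4]),
                            c("X", "Y", "Y", "X"))
  S <- matrix(0.5, 4, 4, dimnames = list(adm$ids, adm$ids))  # all tied
  diag(S) <- 1
  # For A1 the match is A4, tied with A2 and A3 at 0.5.
  rk_id <- evaluate_rankings(S, adm, tie_policy = "id")
  # id order puts A2, A3 before A4 for A1: rank 3; A4 sees A1 first: rank 1
  expect_equal(rk_id$mrr0, mean(c(1/3, 1/2, 1/2, 1)))
  rk_opt <- evaluate_rankings(S, adm, tie_policy = "optimistic")
  expect_equal(rk_opt$mrr0, 1)                       # every match can rank first
  rk_pes <- evaluate_rankings(S, adm, tie_policy = "pessimistic")
  expect_equal(rk_pes$mrr0, mean(c(1/3, 1/3, 1/3, 1/3)))
  rk_mid <- evaluate_rankings(S, adm, tie_policy = "mid")
  expect_equal(rk_mid$mrr0, mean(rep(1/2, 4)))
})

test_that("mrr0 equals mrrna scaled by the matchable fraction on random benchmarks", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:20, 1)
    adm <- labeled_admissions(sprintf("A%02d", 1:n),
                              replicate(n, list("t")),
                              sample(LETTERS[1:4], n, replace = TRUE))
    S <- matrix(runif(n * n), n, n)
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    diag(S) <- 1
    rk <- tryCatch(evaluate_rankings(S, adm), error = function(e) NULL)
    if (is.null(rk)) next
    expect_equal(rk$mrr0, rk$mrrna * rk$n_matchable / rk$n, tolerance = 1e-12)
  }
})

test_that("rank metrics are invariant under strictly increasing score transforms", {
  set.seed(8)
  n <- 25
  adm <- labeled_admissions(sprintf("A%02d", 1:n), replicate(n, list("t")),
                            sample(LETTERS[1:5], n, replace = TRUE))
  S <- matrix(round(runif(n * n), 2), n, n)   # ties included
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- 1
  S2 <- S + S^3 + 2          # strictly increasing transform
  rec <- build_pair_records(S, adm); rec2 <- build_pair_records(S2, adm)
  expect_equal(evaluate_auc(rec2)$auc, evaluate_auc(rec)$auc, tolerance = 1e-12)
  for (pol in c("id", "mid", "optimistic", "pessimistic")) {
    a <- evaluate_rankings(S, adm, tie_policy = pol)
    b <- evaluate_rankings(S2, adm, tie_policy = pol)
    expect_equal(b$mrr0, a$mrr0, tolerance = 1e-12)
    expect_equal(b$a_at_k, a$a_at_k)
  }
})

test_that("correlate_metrics matches the covariance formula", {
  res <- data.frame(auc = c(0.5, 0.6, 0.7, 0.8), a10 = c(0.2, 0.3, 0.25, 0.5),
                    status = "ok", stringsAsFactors = FALSE)
  res$mirror <- res$auc
  res$anti <- 1 - res$auc
  expect_equal(correlate_metrics(res, "auc", "mirror")$r, 1)
  expect_equal(correlate_metrics(res, "auc", "anti")$r, -1)

  set.seed(99)
  res2 <- data.frame(auc = runif(10), a10 = runif(10), status = "ok")
  got <- correlate_metrics(res2, "auc", "a10")
  x <- res2$auc; y <- res2$a10
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  t_stat <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(got$p, 2 * stats::pt(-abs(t_stat), 8), tolerance = 1e-12)

  res3 <- data.frame(auc = rep(0.5, 5), a10 = runif(5), status = "ok")
  expect_error(correlate_metrics(res3, "auc", "a10"), "zero variance")
  expect_error(correlate_metrics(res2[1:2, ], "auc", "a10"), "at least three")
})
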