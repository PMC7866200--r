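hits_for <- function(ids, matrix_id = "M1") {
  n <- length(ids)
  data.frame(promoter_id = ids, start = rep_len(0L, n),
             end = rep_len(10L, n), matrix_id = rep_len(matrix_id, n),
             score = rep_len(1, n), strand = rep_len("+", n),
             stringsAsFactors = FALSE)
}

test_that("the worked 2x2 case reproduces OR and the 99% CI lower bound", {
  r <- enrich_matrix(hits_for(sprintf("d%03d", 1:30)),
                     hits_for(sprintf("r%04d", 1:250)),
                     sprintf("d%03d", 1:300), sprintf("r%04d", 1:5000))
  expect_equal(r$a, 30); expect_equal(r$b, 270)
  expect_equal(r$c, 250); expect_equal(r$d, 4750)
  expect_equal(r$odds_ratio, 2.1111, tolerance = 1e-4)
  # exp(ln OR - 2.5758 * sqrt(1/30 + 1/270 + 1/250 + 1/4750)) ~ 1.25
  expect_equal(r$fe_adj,
               exp(log(2.111111) - stats::qnorm(0.995) * 0.203093),
               tolerance = 1e-4)
  expect_equal(round(r$fe_adj, 2), 1.25)
})

test_that("null tables and empty cells are handled as specified", {
  # equal proportions: OR = 1, one-sided p >= 0.5
  r <- enrich_matrix(hits_for(sprintf("d%d", 1:10)),
                     hits_for(sprintf("r%d", 1:100)),
                     sprintf("d%d", 1:100), sprintf("r%d", 1:1000))
  expect_equal(r$odds_ratio, 1)
  expect_gte(r$fisher_p, 0.5)
  # a = 0: correction applied, fe_adj < 1
  r0 <- enrich_matrix(hits_for(character(0)),
                      hits_for(sprintf("r%d", 1:50)),
                      sprintf("d%d", 1:100), sprintf("r%d", 1:1000))
  expect_lt(r0$fe_adj, 1)
  expect_true(is.finite(r0$fe_adj))
  # hits outside the declared sets are an error
  expect_error(enrich_matrix(hits_for("zz"), hits_for(character(0)),
                             c("d1"), c("r1")), "outside")
})

test_that("Fisher p matches hypergeometric enumeration on small margins", {
  set.seed(61)
  for (i in 1:30) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    cc <- sample(0:20, 1); d <- sample(0:20, 1)
    if (a + b == 0 || cc + d == 0 || a + cc == 0) next
    r <- enrich_matrix(hits_for(sprintf("d%d", seq_len(a))),
                       hits_for(sprintf("r%d", seq_len(cc))),
                       sprintf("d%d", seq_len(a + b)),
                       sprintf("r%d", seq_len(cc + d)))
    expect_equal(r$fisher_p, enum_fisher_greater(a, b, cc, d),
                 tolerance = 1e-10)
  }
})

test_that("fe_adj stays below OR for enrichment and tightens with sample size", {
  set.seed(77)
  for (i in 1:200) {
    cells <- sample(1:400, 4, replace = TRUE)
    r <- enrich_matrix(hits_for(sprintf("d%d", seq_len(cells[1]))),
                       hits_for(sprintf("r%d", seq_len(cells[3]))),
                       sprintf("d%d", seq_len(cells[1] + cells[2])),
                       sprintf("r%d", seq_len(cells[3] + cells[4])))
    if (r$odds_ratio > 1) expect_lt(r$fe_adj, r$odds_ratio)
  }
  # doubling all cells at fixed proportions narrows the CI: fe_adj rises
  fe <- vapply(c(1, 2, 4, 8), function(k) {
    enrich_matrix(hits_for(sprintf("d%d", seq_len(30 * k))),
                  hits_for(sprintf("r%d", seq_len(100 * k))),
                  sprintf("d%d", seq_len(300 * k)),
                  sprintf("r%d", seq_len(2000 * k)))$fe_adj
  }, numeric(1))
  expect_true(all(diff(fe) > 0))
})

test_that("BH adjustment reproduces step-up arithmetic and validates input", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.5, 1.01)), "0, 1")
})

test_that("TF collapse takes the maximal fe_adj and applies printed cutoffs", {
  recs <- data.frame(matrix_id = c("M1", "M2", "M3", "M4"),
                     fe_adj = c(1.3, 1.6, 1.4, 2.0),
                     fdr = c(0.01, 0.02, 0.2, 0.001))
  map <- c(M1 = "TFA", M2 = "TFA", M3 = "TFB", M4 = "TFC")
  s <- collapse_to_tf(recs, map)
  tfa <- s[s$tf_name == "TFA", ]
  expect_equal(tfa$fe_adj_max, 1.6)
  expect_equal(tfa$best_matrix_id, "M2")
  expect_equal(tfa$fdr_min, 0.01)
  expect_true(tfa$highly_enriched)
  # fe_adj 1.4 with fdr 0.2 is not significant
  expect_false(s$significant[s$tf_name == "TFB"])
  expect_true(s$significant[s$tf_name == "TFC"])
  # single matrix: identity
  one <- collapse_to_tf(recs[3, ], map)
  expect_equal(one$fe_adj_max, 1.4)
  expect_error(collapse_to_tf(recs, map[-1]), "unmapped")
})

test_that("a planted matrix dominates enrichment over a synthetic corpus", {
  pwms <- lapply(simulate_pwm_library(4, seed = 41), log_odds_matrix)
  cfg <- promoter_sim_config(n_deg = 200, n_ref = 1000,
                             planted_pwm_ids = pwms[[1]]$matrix_id,
                             planted_prevalence = 0.4, seed = 43)
  corp <- simulate_promoter_corpus(cfg, pwms)
  cals <- lapply(pwms, calibrate_threshold, background_seqs = corp$ref,
                 target_rate = 1 / 2000)
  deg_hits <- scan_library(corp$deg, pwms, cals)
  ref_hits <- scan_library(corp$ref, pwms, cals)
  enr <- suppressMessages(
    enrich_library(deg_hits, ref_hits, names(corp$deg), names(corp$ref),
                   matrix_tf_map(pwms)))
  expect_equal(enr$matrix_id[1], pwms[[1]]$matrix_id)
  expect_lte(enr$fdr[1], 0.05)
  expect_equal(sum(enr$significant & enr$matrix_id != pwms[[1]]$matrix_id),
               0)
})
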