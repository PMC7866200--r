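toy_pwm <- function(consensus = "ACGTAC", weight = 97) {
  bases <- c("A", "C", "G", "T")
  counts <- t(vapply(strsplit(consensus, "")[[1]], function(b) {
    row <- rep(1, 4)
    row[match(b, bases)] <- weight
    row
  }, numeric(4)))
  log_odds_matrix(new_pwm("TOY", "TOYTF", counts))
}

test_that("flat-file parsing preserves counts and rejects malformed input", {
  pwms <- simulate_pwm_library(3, seed = 2)
  tf_path <- withr::local_tempfile()
  write_pwms(pwms, tf_path, "transfac")
  back <- parse_pwms(tf_path, "transfac")
  expect_equal(lapply(back, `[[`, "counts"),
               lapply(pwms, `[[`, "counts"), ignore_attr = FALSE)
  # same counts through the jaspar dialect give identical probabilities
  jp_path <- withr::local_tempfile()
  write_pwms(pwms, jp_path, "jaspar")
  back_j <- parse_pwms(jp_path, "jaspar")
  expect_equal(lapply(back_j, `[[`, "probabilities"),
               lapply(back, `[[`, "probabilities"))

  writeLines(c("AC M1", "P0 A C G T", "01 5 -2 1 1", "//"),
             bad <- withr::local_tempfile())
  expect_error(parse_pwms(bad, "transfac"), "negative")
  writeLines(c("AC M2", "P0 A C G T", "//"),
             empty <- withr::local_tempfile())
  expect_error(parse_pwms(empty, "transfac"), "zero-length")
  expect_error(new_pwm("X", "X", matrix(-1, 4, 4)), "negative")
})

test_that("log-odds cells follow the background-weighted pseudocount formula", {
  p <- log_odds_matrix(new_pwm("M", "TF", matrix(c(8, 0, 0, 0), 1, 4)))
  expect_equal(unname(p$log_odds[1, "A"]), log2((8.25 / 9) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(p$log_odds[1, "A"]), 1.874, tolerance = 1e-3)
  # uninformative column scores 0 everywhere
  u <- log_odds_matrix(new_pwm("M", "TF", matrix(2, 1, 4)))
  expect_true(all(abs(u$log_odds) < 1e-12))
  # background equal to the column frequencies gives a row of zeros
  bkg <- c(0.4, 0.3, 0.2, 0.1)
  m <- log_odds_matrix(new_pwm("M", "TF", matrix(bkg * 40, 1, 4)),
                       background = bkg)
  expect_true(all(abs(m$log_odds) < 1e-12))
  expect_error(log_odds_matrix(new_pwm("M", "TF", matrix(1, 1, 4)),
                               background = c(0.5, 0.5, 0, 0)), "positive")
})

test_that("scanning finds planted consensus sites at exact coordinates", {
  pwm <- toy_pwm("ACGTAC")
  set.seed(9)
  seq1 <- random_dna(200)
  substr(seq1, 38, 43) <- "ACGTAC"   # 0-based offset 37
  hits <- scan_sequences(c(s1 = seq1), pwm, threshold = 10)
  fwd <- hits[hits$strand == "+", ]
  expect_true(37 %in% fwd$start)
  expect_true(all(hits$end - hits$start == 6))
})

test_that("N bases score as background and do not crash the scan", {
  pwm <- toy_pwm("ACGTAC")
  hits <- scan_sequences(c(s = "NNNNNNNNNNNN"), pwm, threshold = 0.0)
  # all-N windows score exactly 0 bits, at threshold 0 they are reported
  expect_true(all(hits$score == 0))
  expect_equal(nrow(hits), 14)  # 7 windows x 2 strands
})

test_that("scan equals the naive per-window oracle on random promoters", {
  pwms <- lapply(simulate_pwm_library(3, length_range = c(6, 9), seed = 3),
                 log_odds_matrix)
  set.seed(71)
  for (p in pwms) {
    thr <- 0.6 * sum(apply(p$log_odds, 1, max))
    for (i in 1:4) {
      s <- random_dna(600)
      got <- scan_sequences(c(x = s), p, thr)
      want <- naive_scan(s, p$log_odds, thr)
      got <- got[order(got$start, got$strand), ]
      want <- want[order(want$start, want$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("reverse-complementing the sequences mirrors hit coordinates", {
  pwm <- lapply(simulate_pwm_library(2, seed = 13), log_odds_matrix)[[1]]
  set.seed(23)
  s <- random_dna(500)
  # plant the consensus so hits exist on both strands
  cons <- paste(c("A", "C", "G", "T")[apply(pwm$log_odds, 1, which.max)],
                collapse = "")
  substr(s, 101, 100 + pwm$length) <- cons
  substr(s, 301, 300 + pwm$length) <- revcomp_str(cons)
  thr <- 0.5 * sum(apply(pwm$log_odds, 1, max))
  fwd_hits <- scan_sequences(c(x = s), pwm, thr)
  rc_hits <- scan_sequences(c(x = revcomp_str(s)), pwm, thr)
  # a + hit at [a, b) maps to a - hit at [n-b, n-a) and vice versa
  n <- nchar(s)
  mirrored <- data.frame(start = n - rc_hits$end, end = n - rc_hits$start,
                         strand = as.character(
                           ifelse(rc_hits$strand == "+", "-", "+")),
                         score = rc_hits$score)
  expect_gt(nrow(fwd_hits), 0)
  key <- function(d) d[order(d$start, d$strand), c("start", "strand")]
  expect_equal(key(fwd_hits[c("start", "strand")]), key(mirrored),
               ignore_attr = TRUE)
})

test_that("palindromic matrices hit both strands at the same coordinate", {
  pal <- toy_pwm("ACGCGT")  # reverse complement of ACGCGT is itself
  set.seed(31)
  s <- random_dna(3000)
  substr(s, 101, 106) <- "ACGCGT"
  hits <- scan_sequences(c(x = s), pal, threshold = 10)
  plus <- hits$start[hits$strand == "+"]
  minus <- hits$start[hits$strand == "-"]
  expect_setequal(plus, minus)
})

test_that("threshold calibration achieves the target rate and is monotone", {
  pwm <- lapply(simulate_pwm_library(2, seed = 17), log_odds_matrix)[[1]]
  bg <- random_dna(1e6, seed = 55)
  cal <- calibrate_threshold(pwm, c(b = bg), target_rate = 1 / 2000)
  expect_lte(cal$achieved_rate, 1 / 2000)
  # rescan and count: hits per position match the reported rate
  hits <- scan_sequences(c(b = bg), pwm, cal$threshold)
  expect_equal(nrow(hits) / cal$n_positions, cal$achieved_rate)
  # stricter target => higher threshold
  cal10k <- calibrate_threshold(pwm, c(b = bg), target_rate = 1 / 10000)
  expect_gte(cal10k$threshold, cal$threshold)
  # degenerate target: every position hit at the minimal score
  cal_all <- calibrate_threshold(pwm, c(b = bg), target_rate = 2)
  expect_gte(cal_all$achieved_rate, 1)
  # too-short background is an error stating the requirement
  expect_error(calibrate_threshold(pwm, c(b = random_dna(1000)),
                                   target_rate = 1 / 2000), "required")
})

test_that("planted sites are recalled at the 1/2000 calibration", {
  pwms <- lapply(simulate_pwm_library(2, seed = 29), log_odds_matrix)
  low_entropy <- pwms[[1]]
  cfg <- promoter_sim_config(n_deg = 150, n_ref = 200,
                             planted_pwm_ids = low_entropy$matrix_id,
                             planted_prevalence = 0.5, seed = 37)
  corp <- simulate_promoter_corpus(cfg, pwms)
  cal <- calibrate_threshold(low_entropy, corp$ref, target_rate = 1 / 2000)
  hits <- scan_sequences(corp$deg, low_entropy, cal$threshold)
  tr <- corp$truth$planted_site_coordinates
  found <- mapply(function(pid, s) any(hits$promoter_id == pid &
                                         hits$start == s),
                  tr$promoter_id, tr$start)
  expect_gte(mean(found), 0.9)
})
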