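test_that("meta table simulation is deterministic and writes identical files", {
  cfg <- meta_sim_config(n_genes = 400, n_studies = 4, n_true_up = 20,
                         n_true_down = 10, seed = 7)
  sim1 <- simulate_meta_tables(cfg)
  sim2 <- simulate_meta_tables(cfg)
  expect_identical(sim1, sim2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study_tables(sim1$tables, d1)
  write_study_tables(sim2$tables, d2)
  f <- list.files(d1)
  expect_identical(lapply(file.path(d1, f), readLines),
                   lapply(file.path(d2, f), readLines))
})

test_that("planted true DEGs pass the per-study filter at the penetrance rate", {
  cfg <- meta_sim_config(n_genes = 5000, n_studies = 10, n_true_up = 100,
                         n_true_down = 0, penetrance = 0.7, seed = 1)
  sim <- simulate_meta_tables(cfg)
  # count filter passes of true-up genes against the truth set
  passes <- 0L; cells <- 0L
  for (st in sim$tables) {
    cutoff <- platform_padj_cutoffs[[st$platform]]
    tab <- st$table[st$table$gene_id %in% sim$truth$true_up_genes, ]
    cells <- cells + nrow(tab)
    passes <- passes + sum(tab$padj < cutoff & tab$fold_change > 1.25)
  }
  p_hat <- passes / cells
  tol <- 3 * sqrt(0.7 * 0.3 / cells)
  expect_lt(abs(p_hat - 0.7), tol + 0.02)  # small excess from chance null passes
})

test_that("all-null tables pass the filter at the product of marginal rates", {
  cfg <- meta_sim_config(n_genes = 20000, n_studies = 4, n_true_up = 0,
                         n_true_down = 0, missing_rate = 0,
                         platform_mix = 0, null_lfc_sd = 0.25, seed = 3)
  sim <- simulate_meta_tables(cfg)
  # P(U < 0.05) * P(|N(0, 0.25)| > log2(1.25)), independent draws
  p_expected <- 0.05 * 2 * stats::pnorm(log2(1.25) / 0.25,
                                        lower.tail = FALSE)
  rates <- vapply(sim$tables, function(st)
    mean(st$table$padj < 0.05 & abs(log2(st$table$fold_change)) >
           log2(1.25)), numeric(1))
  n <- nrow(sim$tables[[1]]$table)
  expect_lt(abs(mean(rates) - p_expected),
            3 * sqrt(p_expected * (1 - p_expected) / (n * length(rates))))
})

test_that("truth set is consistent with the generated universe", {
  cfg <- meta_sim_config(n_genes = 300, n_studies = 5, n_true_up = 30,
                         n_true_down = 30, missing_rate = 0.3, seed = 11)
  sim <- simulate_meta_tables(cfg)
  measured_anywhere <- unique(unlist(lapply(sim$tables, `[[`,
                                            "measured_universe")))
  expect_true(all(sim$truth$true_up_genes %in% measured_anywhere))
  expect_true(all(sim$truth$true_down_genes %in% measured_anywhere))
  expect_length(intersect(sim$truth$true_up_genes,
                          sim$truth$true_down_genes), 0)
})

test_that("invalid simulation fractions are rejected", {
  expect_error(meta_sim_config(penetrance = 1.3), "penetrance")
  expect_error(meta_sim_config(missing_rate = -0.1), "missing_rate")
  expect_error(meta_sim_config(n_genes = 50, n_true_up = 40,
                               n_true_down = 30), "exceed")
})

test_that("promoter corpus plants sites at the target prevalence and GC", {
  pwms <- simulate_pwm_library(2, seed = 5)
  cfg <- promoter_sim_config(n_deg = 300, n_ref = 100,
                             promoter_length = 500, gc_content = 0.5,
                             planted_pwm_ids = pwms[[1]]$matrix_id,
                             planted_prevalence = 0.4,
                             background_prevalence = 0, seed = 9)
  corp <- simulate_promoter_corpus(cfg, pwms)
  tr <- corp$truth$planted_site_coordinates
  # ~120 of 300 DEG promoters carry a planted site; none in reference
  n_carriers <- length(unique(tr$promoter_id[grepl("^deg", tr$promoter_id)]))
  expect_lt(abs(n_carriers - 120), 3 * sqrt(300 * 0.4 * 0.6) + 1)
  expect_false(any(grepl("^ref", tr$promoter_id)))
  # every planted interval lies inside its promoter
  expect_true(all(tr$start >= 0 & tr$end <= 500))
  # the planted subsequence matches a column-wise draw from the matrix:
  # spot-check that consensus-dominant positions mostly agree
  # base composition of the reference group ~ uniform at gc 0.5
  freq <- colSums(Biostrings::alphabetFrequency(corp$ref)[, 1:4])
  n_bases <- sum(freq)
  for (b in 1:4)
    expect_lt(abs(freq[b] / n_bases - 0.25),
              3 * sqrt(0.25 * 0.75 / n_bases) + 0.001)
})

test_that("prevalence zero plants nothing and same seed reproduces the corpus", {
  pwms <- simulate_pwm_library(1, seed = 5)
  cfg <- promoter_sim_config(n_deg = 20, n_ref = 10,
                             promoter_length = 200,
                             planted_pwm_ids = pwms[[1]]$matrix_id,
                             planted_prevalence = 0, seed = 2)
  corp <- simulate_promoter_corpus(cfg, pwms)
  expect_equal(nrow(corp$truth$planted_site_coordinates), 0)
  corp2 <- simulate_promoter_corpus(cfg, pwms)
  expect_identical(as.character(corp$deg), as.character(corp2$deg))
  expect_identical(as.character(corp$ref), as.character(corp2$ref))
})

test_that("motifs longer than the promoter are a configuration error", {
  pwms <- simulate_pwm_library(1, length_range = c(10, 10), seed = 1)
  cfg <- promoter_sim_config(n_deg = 5, n_ref = 0, promoter_length = 8,
                             planted_pwm_ids = pwms[[1]]$matrix_id,
                             planted_prevalence = 1, seed = 1)
  expect_error(simulate_promoter_corpus(cfg, pwms), "longer than")
})

test_that("simulated PWM libraries round-trip through both dialects", {
  pwms <- simulate_pwm_library(5, length_range = c(8, 8), seed = 4)
  expect_length(pwms, 5)
  expect_true(all(vapply(pwms, function(p) p$length, integer(1)) == 8))
  # library spans low and high entropy
  ic <- vapply(pwms, function(p) {
    pr <- p$probabilities
    sum(pr * log2(pmax(pr, 1e-12) / 0.25))
  }, numeric(1))
  expect_gt(max(ic), 1.5 * 8)   # near-consensus
  expect_lt(min(ic), 0.1 * 8)   # degenerate

  for (dialect in c("transfac", "jaspar")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_pwms(pwms, path, dialect)
    back <- parse_pwms(path, dialect)
    expect_equal(lapply(back, function(p) unname(p$counts)),
                 lapply(pwms, function(p) unname(p$counts)))
    expect_identical(vapply(back, function(p) p$matrix_id, character(1)),
                     vapply(pwms, function(p) p$matrix_id, character(1)))
  }
  # fixed seed => byte-identical files
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_pwms(simulate_pwm_library(3, seed = 8), p1, "transfac")
  write_pwms(simulate_pwm_library(3, seed = 8), p2, "transfac")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted partition graphs have the promised structure", {
  # two disjoint triangles
  ppi <- simulate_ppi_edges(c(3, 3), p_within = 1, p_between = 0, seed = 1)
  expect_equal(nrow(ppi$edges), 6)
  m <- ppi$truth$planted_clusters
  same <- m[ppi$edges$node_a] == m[ppi$edges$node_b]
  expect_true(all(same))
  # complete graph K5
  k5 <- simulate_ppi_edges(5, p_within = 1, p_between = 0, seed = 1)
  expect_equal(nrow(k5$edges), 10)
  # determinism
  again <- simulate_ppi_edges(c(3, 3), p_within = 1, p_between = 0, seed = 1)
  expect_identical(ppi, again)
  expect_error(simulate_ppi_edges(c(3, 3), p_within = 0.2,
                                  p_between = 0.5), "exceed")
})
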