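test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(n_samples = 40, n_genes = 10, seed = 77)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  for (tbl in c("mutations", "cnv", "clinical", "expression", "genes",
                "eccdna")) {
    expect_identical(a[[tbl]], b[[tbl]])
  }
  expect_identical(a$truth, b$truth)
  c2 <- suppressWarnings(simulate_cohort(sim_config(n_samples = 40,
                                                    n_genes = 10,
                                                    seed = 78)))
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("expected VAF follows the purity/copy model", {
  expect_equal(expected_vaf(1.0, 1, 1), 0.5)
  expect_equal(expected_vaf(0.5, 1, 1), 0.25)
  expect_equal(expected_vaf(1.0, 3, 1), 0.75)
  expect_equal(expected_vaf(0.6, 1, 0), 0.6 / (0.6 + 0.8))
  expect_error(expected_vaf(0.5, 0, 0), "at least one")
  expect_error(expected_vaf(1.2, 1, 1), "purity")
  # monotone in purity for amplified-mutant states
  p <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(expected_vaf(p, 2, 1)) > 0))
})

test_that("simulated read counts concentrate at the expected VAF", {
  cfg <- sim_config(depth_dna_mean = 10000, rna_coverage_prob = 1, seed = 1)
  clinical <- tibble::tibble(sample_id = c("S1", "S2"), purity = 1)
  muts <- tibble::tibble(
    sample_id = c("S1", "S2"), gene = "G01",
    c_mut = c(1L, 1L), c_ref = c(1L, 0L), rna_multiplier = 1
  )
  set.seed(2)
  got <- simulate_read_counts(muts, clinical, cfg)
  v <- got$dna_alt / (got$dna_alt + got$dna_ref)
  expect_lt(abs(v[1] - 0.5), 0.02)  # pure heterozygous diploid
  expect_gt(v[2], 0.98)             # reference allele deleted
  # determinism
  set.seed(9); a <- simulate_read_counts(muts, clinical, cfg)
  set.seed(9); b <- simulate_read_counts(muts, clinical, cfg)
  expect_identical(a, b)
})

test_that("expression follows the generative arithmetic", {
  cfg <- sim_config(n_samples = 50, n_genes = 6, expr_noise_sd = 0,
                    seed = 31,
                    planted_expression = tibble::tibble(
                      gene = "G01", cancer_type = "LUAD",
                      beta_mut = 1, beta_cnv = 0.5, beta_int = 0.5
                    ))
  co <- suppressWarnings(simulate_cohort(cfg))
  truth <- co$truth$expression
  df <- merge(co$expression, co$clinical[, c("sample_id", "age_at_diagnosis",
                                             "gender")])
  mut_key <- paste(co$mutations$sample_id, co$mutations$gene)
  df$mut <- as.integer(paste(df$sample_id, df$gene) %in% mut_key)
  cnv_key <- paste(co$cnv$sample_id, co$cnv$gene)
  df$gistic <- ifelse(paste(df$sample_id, df$gene) %in% cnv_key,
                      co$cnv$gistic[match(paste(df$sample_id, df$gene),
                                          cnv_key)], 0L)
  for (g in c("G01", "G02")) {
    tr <- truth[truth$gene == g, ]
    d <- df[df$gene == g, ]
    pred <- tr$baseline + tr$beta_mut * d$mut + tr$beta_cnv * d$gistic +
      tr$beta_int * d$mut * d$gistic +
      cfg$age_beta * (d$age_at_diagnosis - 60) +
      cfg$gender_beta * (d$gender == "male")
    expect_equal(d$expression, pred) # zero noise: exact reconstruction
  }
  # beta_int = 0.5: the (mut=1, gistic=2) group exceeds the additive
  # prediction by exactly 1.0 under the generative model
  tr <- truth[truth$gene == "G01", ]
  expect_equal(tr$beta_int * 1 * 2, 1.0)
})

test_that("a null cohort shows no mutation-CNV association", {
  cfg <- sim_config(
    n_samples = 2000, n_genes = 20,
    planted_pairs = tibble::tibble(gene = character(),
                                   cancer_type = character(),
                                   direction = character(),
                                   enrichment = numeric()),
    seed = 55
  )
  co <- simulate_cohort(cfg)
  mut <- build_alteration_matrix(co$mutations, co$clinical$sample_id,
                                 sprintf("G%02d", 1:20))
  cna_ev <- co$cnv[co$cnv$gistic == 2L, ]
  cna <- build_alteration_matrix(cna_ev, co$clinical$sample_id,
                                 sprintf("G%02d", 1:20))
  # within-gene 2x2 association, aggregated over genes
  tab <- table(mut = as.vector(mut), cna = as.vector(cna))
  or_ci <- stats::fisher.test(tab)$conf.int
  expect_true(or_ci[1] <= 1 && or_ci[2] >= 1)
})

test_that("planted enrichment raises co-occurrence toward its expectation", {
  cfg <- sim_config(
    n_samples = 2000, n_genes = 20, cna_rate = 0.05,
    cnv_burden_dispersion = 1e6, # effectively homogeneous CNV burden
    planted_pairs = tibble::tibble(gene = "G01", cancer_type = "LUAD",
                                   direction = "CNA", enrichment = 10),
    seed = 66
  )
  co <- suppressWarnings(simulate_cohort(cfg))
  mut_s <- co$mutations$sample_id[co$mutations$gene == "G01"]
  cna_s <- co$cnv$sample_id[co$cnv$gene == "G01" & co$cnv$gistic == 2L]
  prop <- mean(mut_s %in% cna_s)
  expect_lt(abs(prop - 0.5), 0.07) # analytic expectation 0.05 x 10
})

test_that("the truth table covers every planted effect exactly once", {
  co <- small_cohort(seed = 3)
  expect_equal(nrow(co$truth$pairs),
               nrow(unique(co$truth$pairs[, c("gene", "cancer_type",
                                              "direction")])))
  expect_setequal(co$truth$pairs$gene, co$config$planted_pairs$gene)
  # every simulated mutation appears in the truth table once
  expect_equal(nrow(co$truth$mutations), nrow(co$mutations))
  # planted eccDNA genes exist on the toy genome
  expect_true(all(co$truth$pairs$gene %in% co$genes$label))
})
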