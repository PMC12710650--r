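test_that("background pooling is read-weighted at every aggregation level", {
  muts <- tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S2"),
    gene = c("G01", "G01", "G01", "G02"),
    protein_change = NA_character_, mutation_class = "missense",
    is_functional_driver = TRUE,
    dna_alt = c(3L, 7L, 9L, 2L), dna_ref = c(7L, 3L, 1L, 8L),
    rna_alt = NA_integer_, rna_ref = NA_integer_,
    gistic = c(0L, 0L, 1L, 0L) # the gistic=1 row is not background
  )
  muts$gene <- c("G01", "G01", "G01", "G02")
  clinical <- tibble::tibble(sample_id = c("S1", "S2"),
                             cancer_type = "LUAD", center = "TCGA")
  bg <- build_background_table(muts, clinical, "DNA")
  # two background mutations 3/10 and 7/10 pooled in (gene, cancer): 10/20
  gc <- bg$gene_cancer
  expect_equal(gc$p0[gc$gene == "G01"], 0.5)
  expect_equal(gc$total_sum[gc$gene == "G01"], 20L)
  # per-sample pooling (read-weighted, not mean of VAFs)
  expect_equal(bg$sample$p0[bg$sample$sample_id == "S1"], 10 / 20)
  expect_equal(bg$sample$p0[bg$sample$sample_id == "S2"], 2 / 10)
  # cancer-wide pooling over all background reads
  expect_equal(bg$cancer$p0, 12 / 30)

  # brute-force group-by recount on a simulated cohort
  co <- small_cohort(seed = 13)
  bg <- build_background_table(co$mutations, co$clinical, "DNA")
  df <- merge(co$mutations, co$clinical[, c("sample_id", "cancer_type")])
  df <- df[df$gistic == 0 & (df$dna_alt + df$dna_ref) > 0, ]
  for (s in unique(df$sample_id)) {
    d <- df[df$sample_id == s, ]
    expect_equal(bg$sample$p0[bg$sample$sample_id == s],
                 sum(d$dna_alt) / sum(d$dna_alt + d$dna_ref))
  }
  for (cc in unique(df$cancer_type)) {
    d <- df[df$cancer_type == cc, ]
    expect_equal(bg$cancer$p0[bg$cancer$cancer_type == cc],
                 sum(d$dna_alt) / sum(d$dna_alt + d$dna_ref))
  }
})

test_that("background matching precedence holds for all 16 presence patterns", {
  # distinct rate per level: gcs 0.1, sample 0.2, gene-cancer 0.3, cancer 0.4
  expected_order <- c(gcs = 0.1, sample = 0.2, gc = 0.3, cancer = 0.4)
  for (mask in 0:15) {
    present <- c(
      gcs = bitwAnd(mask, 1L) > 0, sample = bitwAnd(mask, 2L) > 0,
      gc = bitwAnd(mask, 4L) > 0, cancer = bitwAnd(mask, 8L) > 0
    )
    bg <- fake_background(present)
    got <- match_background(bg, "G01", "LUAD", "S1")
    if (!any(present)) {
      expect_true(is.na(got$p0))
      expect_true(is.na(got$match_level))
    } else {
      first <- names(expected_order)[which(present)[1]]
      expect_equal(got$p0, unname(expected_order[first]))
    }
  }
  # full table: the most specific level wins for a matching mutation,
  # and falls through for a different sample/gene
  bg <- fake_background()
  expect_equal(match_background(bg, "G01", "LUAD", "S1")$match_level,
               "gene_cancer_sample")
  expect_equal(match_background(bg, "G99", "LUAD", "S9")$match_level,
               "cancer")
})

test_that("the exact binomial test equals the enumeration oracle", {
  # printed-input case: 7 alt of 10 reads against 0.5
  expect_equal(binomial_imbalance_test(7, 10, 0.5),
               2 * (120 + 45 + 10 + 1) / 1024)
  # observing the distribution's mode includes every outcome
  expect_equal(binomial_imbalance_test(5, 10, 0.5), 1)
  for (p0 in seq(0.1, 0.9, by = 0.2)) {
    for (total in c(1, 5, 12)) {
      for (alt in 0:total) {
        expect_equal(binomial_imbalance_test(alt, total, p0),
                     binom_two_sided_oracle(alt, total, p0),
                     tolerance = 1e-12)
      }
    }
  }
  expect_true(is.na(binomial_imbalance_test(0, 0, 0.5)))
  expect_error(binomial_imbalance_test(3, 10, 0), "strictly inside")
  expect_error(binomial_imbalance_test(11, 10, 0.5), "alt counts")
})

test_that("amplified-mutant mutations are called increased; balanced ones are not", {
  co <- make_imbalance_cohort(true_vaf = 0.7, seed = 21)
  res <- run_binoculars(co, "DNA", "CNA")
  expect_gte(mean(res$call == "increased"), 0.9)
  expect_true(all(res$match_level %in%
                    c("gene_cancer_sample", "sample", "gene_cancer",
                      "cancer")))

  # calibration: tested VAF equals the background rate
  false_frac <- vapply(1:10, function(s) {
    co <- make_imbalance_cohort(true_vaf = 0.45, seed = 100 + s)
    res <- run_binoculars(co, "DNA", "CNA")
    mean(res$call != "no_change")
  }, numeric(1))
  expect_lte(mean(false_frac), 0.05)
})

test_that("an empty co-occurring set yields an empty result", {
  co <- make_imbalance_cohort(0.7, n_tested = 5, seed = 3)
  co$mutations$gistic <- 0L # nothing co-occurs
  res <- run_binoculars(co, "DNA", "CNA")
  expect_equal(nrow(res), 0)
})

test_that("direction summaries tally recurrent mutations", {
  results <- tibble::tibble(
    gene = c(rep("G01", 10), rep("G02", 9)),
    protein_change = c(rep("p.A1B", 10), rep("p.C2D", 9)),
    mutation_class = "missense",
    call = c(rep("increased", 4), rep("no_change", 6), rep("increased", 9))
  )
  got <- summarize_mutation_direction(results, min_count = 10)
  expect_equal(nrow(got), 1) # the 9-occurrence mutation is excluded
  expect_equal(got$prop_increased, 0.4)
  expect_equal(got$prop_decreased, 0.0)
  expect_equal(got$prop_no_change, 0.6)
  expect_equal(got$prop_increased + got$prop_decreased + got$prop_no_change, 1)
})

test_that("paired VAF correlations respect thresholds and recover rho", {
  d <- tibble::tibble(
    gene = "G01", protein_change = "p.A1B",
    dna_vaf = seq(0.1, 0.9, length.out = 12)
  )
  d$rna_vaf <- d$dna_vaf
  got <- correlate_vaf(d)
  expect_equal(got$r, 1)
  expect_equal(got$n, 12L)

  # unit below the pairing threshold is skipped entirely
  expect_equal(nrow(correlate_vaf(d[1:9, ])), 0)

  d$rna_vaf <- 0.5 # zero variance
  got <- correlate_vaf(d)
  expect_true(got$unestimable)

  set.seed(31)
  ests <- vapply(1:5, function(i) {
    x <- rnorm(50)
    y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(50)
    dd <- tibble::tibble(gene = "G", protein_change = "p",
                         dna_vaf = x, rna_vaf = y)
    correlate_vaf(dd)$r
  }, numeric(1))
  expect_true(all(abs(ests - 0.8) < 0.15))
})
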