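test_that("observed proportion matches the worked example and a brute-force recount", {
  # five mutated samples, two of them CNV-positive in the same gene
  mut <- matrix(1L, 5, 1, dimnames = list(paste0("S", 1:5), "GENEA"))
  cnv <- matrix(c(1L, 1L, 0L, 0L, 0L), 5, 1,
                dimnames = list(paste0("S", 1:5), "GENEA"))
  got <- observed_proportion(mut, cnv, "GENEA")
  expect_equal(got$proportion, 0.4)
  expect_equal(got$n_mut, 5L)
  expect_equal(got$n_co, 2L)

  cnv0 <- cnv; cnv0[] <- 0L
  expect_equal(observed_proportion(mut, cnv0)$proportion, 0)
  expect_error(observed_proportion(mut, cnv, "MISSING"), "not present")

  set.seed(11)
  m1 <- random_binary_matrix(20, 10, 0.3)
  m2 <- random_binary_matrix(20, 10, 0.3)
  got <- observed_proportion(m1, m2)
  oracle <- cooc_oracle(m1, m2)
  expect_equal(got$n_mut, oracle$n_mut)
  expect_equal(got$n_co, oracle$n_co)
  expect_equal(got$proportion, oracle$proportion)
})

test_that("checkerboard randomization preserves all margins and swaps the 2x2 case", {
  # the only checkerboard trade on the identity pattern
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  set.seed(1)
  swapped <- randomize_matrix(m, n_trades = 1, count = "swaps")
  expect_equal(swapped, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_equal(rowSums(swapped), rowSums(m))
  expect_equal(colSums(swapped), colSums(m))

  ones <- matrix(1L, 4, 4)
  expect_equal(randomize_matrix(ones, n_trades = 100), ones)

  set.seed(2)
  m <- random_binary_matrix(50, 20, 0.2)
  cur <- m
  for (i in 1:200) {
    cur <- randomize_matrix(cur, n_trades = 50)
    expect_identical(rowSums(cur), rowSums(m))
    expect_identical(colSums(cur), colSums(m))
  }
  expect_false(identical(cur, m)) # the chain actually moves

  set.seed(3)
  a <- randomize_matrix(m)
  set.seed(3)
  b <- randomize_matrix(m)
  expect_identical(a, b) # deterministic under seed
})

test_that("permutation p-values count exceedances with the add-one rule", {
  expect_equal(permutation_pvalue(0.4, c(0.1, 0.5, 0.4, 0.2)), 0.6)
  expect_equal(permutation_pvalue(0.4, c(0.1, 0.5, 0.4, 0.2),
                                  pseudocount = FALSE), 0.5)
  # everything exceeds an observed proportion of zero
  expect_equal(permutation_pvalue(0, runif(10), pseudocount = FALSE), 1)
  # bounds with pseudocount
  expect_equal(permutation_pvalue(2, runif(99)), 1 / 100)
  expect_true(permutation_pvalue(-1, runif(99)) == 1)
  expect_error(permutation_pvalue(0.4, numeric(0)), "at least one")
})

test_that("BH adjustment matches the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  p <- runif(1000)
  q <- bh_adjust(p)
  expect_equal(q, bh_oracle(p))
  expect_true(all(q >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("Edgington combination matches closed forms and Monte Carlo", {
  expect_equal(edgington_combine(0.05), 0.05)      # k = 1 identity
  expect_equal(edgington_combine(c(0.1, 0.1)), 0.2^2 / 2) # S <= 1 closed form
  expect_equal(edgington_combine(c(1, 1, 1)), 1)
  expect_equal(edgington_combine(c(0, 0)), 0)       # zero p-values allowed
  expect_error(edgington_combine(numeric(0)), "empty")
  expect_error(edgington_combine(c(0.5, 1.5)), "\\[0,1\\]")

  # monotone in each component
  expect_true(edgington_combine(c(0.1, 0.2)) < edgington_combine(c(0.1, 0.3)))

  set.seed(8)
  for (k in c(2, 3, 5)) {
    ps <- runif(k, 0.05, 0.6)
    s <- sum(ps)
    n_mc <- 2e5
    draws <- matrix(runif(n_mc * k), ncol = k)
    mc <- mean(rowSums(draws) <= s)
    se <- sqrt(mc * (1 - mc) / n_mc)
    expect_lt(abs(edgington_combine(ps) - mc), 3 * se + 1e-12)
  }
})

test_that("planted co-occurring pairs are recovered and ranked on top", {
  cfg <- sim_config(n_samples = 400, mutation_burden_mean = 6,
                    gene_weight_shape = 8, seed = 11)
  co <- suppressWarnings(simulate_cohort(cfg))
  res <- suppressWarnings(run_cooccurrence(co, "CNA", n_perm = 5000))
  planted <- co$truth$pairs$gene
  expect_gte(mean(planted %in% res$gene[res$significant]), 0.8)
  expect_true(all(head(res$gene, 10) %in% planted))
  # single center: combined p equals that center's permutation p
  centers <- cooccurrence_centers(res)
  joined <- merge(res, centers, by = c("gene", "cancer_type"))
  expect_equal(joined$edgington_p, joined$perm_p)
})

test_that("two identical centers tighten small combined p-values", {
  # Irwin-Hall at k=2: P(U1+U2 <= 2p) = 2p^2 < p for p < 1/2
  for (p in c(0.01, 0.05, 0.2)) {
    expect_lt(edgington_combine(c(p, p)), p)
  }
})

test_that("the permutation null is calibrated on independent matrices", {
  # no planted pairs: the fraction of q < 0.01 calls should not exceed 0.01
  frac <- vapply(1:5, function(s) {
    cfg <- sim_config(planted_pairs = tibble::tibble(
      gene = character(), cancer_type = character(),
      direction = character(), enrichment = numeric()
    ), seed = 100 + s)
    co <- simulate_cohort(cfg)
    res <- run_cooccurrence(co, "CNA", n_perm = 2000)
    if (nrow(res) == 0) 0 else mean(res$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.01)
})

test_that("two-hit frequencies match direct counting", {
  co <- small_cohort(seed = 9, planted_pairs = tibble::tibble(
    gene = "G01", cancer_type = "LUAD", direction = "CND", enrichment = 5
  ))
  res <- tibble::tibble(gene = c("G01", "G02"), cancer_type = "LUAD")
  got <- summarize_two_hit(res, co)
  for (i in seq_len(nrow(got))) {
    g <- got$gene[i]
    samples <- co$clinical$sample_id
    mut_s <- unique(co$mutations$sample_id[co$mutations$gene == g])
    cnd_s <- unique(co$cnv$sample_id[co$cnv$gene == g & co$cnv$gistic == -2L])
    expect_equal(got$freq_mut_cnd[i],
                 length(intersect(mut_s, cnd_s)) / length(samples))
    expect_equal(got$freq_homdel[i], length(cnd_s) / length(samples))
  }
  expect_true(all(got$predominant %in% c("mut_cnd", "homdel", "tie")))
})
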