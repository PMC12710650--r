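# Parameterised generative fixtures used by the regression, expression and
# imbalance tests (and by the end-to-end property checks).

make_vaf_rows <- function(n, slope = 0.1, base = 0.3, noise_sd = 0.05,
                          gistic_levels = 0:2, seed = 1) {
  set.seed(seed)
  g <- sample(gistic_levels, n, replace = TRUE)
  tibble::tibble(
    gene = "G01", cancer_type = "LUAD", sample_id = sprintf("S%04d", 1:n),
    vaf = pmin(1, pmax(0, base + slope * g + rnorm(n, 0, noise_sd))),
    gistic = as.integer(g),
    purity = runif(n, 0.4, 0.9), ploidy = rnorm(n, 2, 0.1),
    gender = sample(c("female", "male"), n, TRUE),
    subtype = sample(c("ST1", "ST2"), n, TRUE),
    age_at_diagnosis = runif(n, 40, 80),
    level = "DNA", direction = "CNA"
  )
}

make_expr_rows <- function(n = 200, beta_mut = 0, beta_cnv = 0.5,
                           beta_int = 0, noise_sd = 0.5, seed = 1,
                           mut_rate = 0.3) {
  set.seed(seed)
  mut <- rbinom(n, 1, mut_rate)
  gistic <- sample(-2:2, n, replace = TRUE)
  age <- runif(n, 40, 80)
  gender <- sample(c("female", "male"), n, TRUE)
  tibble::tibble(
    gene = "G01", cancer_type = "LUAD", stratum = "missense",
    sample_id = sprintf("S%04d", 1:n),
    expression = 8 + beta_mut * mut + beta_cnv * gistic +
      beta_int * mut * gistic + 0.005 * (age - 60) +
      0.2 * (gender == "male") + rnorm(n, 0, noise_sd),
    mut = mut, gistic = as.integer(gistic),
    age_at_diagnosis = age, gender = gender,
    ethnicity = sample(c("groupA", "groupB"), n, TRUE),
    subtype = sample(c("ST1", "ST2"), n, TRUE)
  )
}

# one cancer type; background mutations at GISTIC 0 with rate bg_vaf, tested
# mutations co-occurring with a gain at true_vaf
make_imbalance_cohort <- function(true_vaf, n_tested = 50, depth = 200,
                                  bg_vaf = 0.45, n_bg = 200, seed = 1) {
  set.seed(seed)
  bg_samples <- sprintf("B%03d", seq_len(n_bg))
  bg_depth <- rpois(n_bg, depth)
  bg <- tibble::tibble(
    sample_id = bg_samples, gene = "G01", protein_change = "p.R100H",
    mutation_class = "missense", is_functional_driver = TRUE,
    dna_alt = rbinom(n_bg, bg_depth, bg_vaf),
    dna_ref = 0L, rna_alt = NA_integer_, rna_ref = NA_integer_,
    gistic = 0L
  )
  bg$dna_ref <- bg_depth - bg$dna_alt
  t_samples <- sprintf("T%03d", seq_len(n_tested))
  t_depth <- rpois(n_tested, depth)
  tested <- tibble::tibble(
    sample_id = t_samples, gene = "G01", protein_change = "p.R100H",
    mutation_class = "missense", is_functional_driver = TRUE,
    dna_alt = rbinom(n_tested, t_depth, true_vaf),
    dna_ref = 0L, rna_alt = NA_integer_, rna_ref = NA_integer_,
    gistic = 1L
  )
  tested$dna_ref <- t_depth - tested$dna_alt
  clinical <- tibble::tibble(
    sample_id = c(bg_samples, t_samples), cancer_type = "LUAD",
    center = "TCGA", purity = 0.7, ploidy = 2, gender = "female",
    age_at_diagnosis = 60, subtype = "ST1", ethnicity = "groupA",
    stage = "stage2"
  )
  list(mutations = rbind(bg, tested), clinical = clinical)
}
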