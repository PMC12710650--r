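#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the simulated multi-center tumor cohort:
#' cohort sizes, per-sample burden heterogeneity, per-gene mutability,
#' planted mutation-CNV co-occurrence enrichments, the purity and sequencing
#' depth distributions, the allele-copy model behind read counts, the
#' expression effect structure, and the eccDNA fragment model. The defaults
#' describe the reference study condition used throughout the package's
#' calibration and recovery analyses: 200 samples x 50 genes per
#' (cancer, center), ten CNA-enriched genes planted at enrichment 5, deep
#' event base rate 0.10, Beta(6,3) purity, Poisson read depths (80x DNA,
#' 50x RNA), and a 0.9 mutant-allele preference at planted loci.
#'
#' @param cancer_types,centers Character vectors; one cohort part is
#'   simulated per (cancer, center) combination.
#' @param n_samples Samples per cohort part.
#' @param n_genes Number of genes (symbols `G01`, `G02`, ...).
#' @param mutation_burden_mean,mutation_burden_dispersion Negative-binomial
#'   (gamma-Poisson) per-sample expected number of mutated genes and its
#'   gamma shape.
#' @param gene_weight_shape Gamma shape of per-gene mutability weights
#'   (mean 1; smaller = more skewed).
#' @param cna_rate,cnd_rate Baseline per-sample-gene probability of a deep
#'   (GISTIC +/-2) event.
#' @param cnv_burden_dispersion Gamma shape of the per-sample CNV burden
#'   multiplier.
#' @param shallow_rate Probability that an otherwise neutral gene carries a
#'   single-copy (GISTIC +/-1) event, split evenly between gain and loss.
#' @param planted_pairs Tibble (`gene`, `cancer_type`, `direction`,
#'   `enrichment`): in mutated samples of these gene-cancer pairs the deep
#'   CNV probability is multiplied by `enrichment` (capped at 1).
#' @param purity_shape1,purity_shape2 Beta parameters of tumor purity.
#' @param depth_dna_mean,depth_rna_mean Poisson means of read depth.
#' @param rna_coverage_prob Fraction of mutations with RNA counts at all.
#' @param mutant_preference_planted,mutant_preference_other Probability that
#'   a CNV at a mutated locus targets the mutant allele (amplifies it, or
#'   deletes the reference allele), at planted vs background loci.
#' @param rna_ase_planted Allele-specific expression multiplier on the mutant
#'   allele at planted loci (1 = none).
#' @param expr_baseline_mean,expr_baseline_sd Per-gene baseline expression
#'   (log2 scale).
#' @param beta_cnv Default per-GISTIC-unit expression dosage effect.
#' @param planted_expression Tibble (`gene`, `cancer_type`, `beta_mut`,
#'   `beta_cnv`, `beta_int`) overriding expression effects per pair.
#' @param expr_noise_sd Residual standard deviation of expression.
#' @param age_beta,gender_beta Covariate effects on expression.
#' @param eccdna_rate Poisson mean of eccDNA fragments per sample.
#' @param eccdna_len_meanlog,eccdna_len_sdlog Log-normal fragment length.
#' @param eccdna_containment Fraction of fragments forced to fully contain a
#'   planted gene.
#' @param seed Root seed; all stage streams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cancer_types = "LUAD", centers = "TCGA",
                       n_samples = 200, n_genes = 50,
                       mutation_burden_mean = 5,
                       mutation_burden_dispersion = 5,
                       gene_weight_shape = 2,
                       cna_rate = 0.10, cnd_rate = 0.10,
                       cnv_burden_dispersion = 5,
                       shallow_rate = 0.10,
                       planted_pairs = NULL,
                       purity_shape1 = 6, purity_shape2 = 3,
                       depth_dna_mean = 80, depth_rna_mean = 50,
                       rna_coverage_prob = 0.8,
                       mutant_preference_planted = 0.9,
                       mutant_preference_other = 0.5,
                       rna_ase_planted = 1.5,
                       expr_baseline_mean = 8, expr_baseline_sd = 1,
                       beta_cnv = 0.5,
                       planted_expression = NULL,
                       expr_noise_sd = 0.5,
                       age_beta = 0.005, gender_beta = 0.2,
                       eccdna_rate = 0.2,
                       eccdna_len_meanlog = log(5e4), eccdna_len_sdlog = 1,
                       eccdna_containment = 0.3,
                       seed = 1) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(
      gene = genes[seq_len(min(10, n_genes))],
      cancer_type = cancer_types[1],
      direction = "CNA",
      enrichment = 5
    )
  }
  if (is.null(planted_expression)) {
    planted_expression <- tibble::tibble(
      gene = genes[seq_len(min(5, n_genes))],
      cancer_type = cancer_types[1],
      beta_mut = 1, beta_cnv = beta_cnv, beta_int = 0.5
    )
  }
  stopifnot(all(planted_pairs$enrichment >= 1),
            cna_rate >= 0, cna_rate <= 1, cnd_rate >= 0, cnd_rate <= 1,
            shallow_rate >= 0, shallow_rate <= 1,
            rna_coverage_prob >= 0, rna_coverage_prob <= 1,
            eccdna_containment >= 0, eccdna_containment <= 1)
  cfg <- as.list(environment())
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Toy genome scaffold: 25 genes per synthetic chromosome, each gene 10 kb
# long and 100 kb apart — purely positional scaffolding for containment
# tests.
toy_gene_intervals <- function(genes) {
  i <- seq_along(genes)
  chrom <- paste0("chrS", (i - 1) %/% 25 + 1)
  start <- as.integer(((i - 1) %% 25) * 100000 + 50000)
  tibble::tibble(chrom = chrom, start = start, end = start + 10000L,
                 label = genes)
}

#' Expected variant allele fraction under the purity/copy model
#'
#' A tumor with purity `rho` carrying `c_mut` mutant and `c_ref` reference
#' copies at a locus, mixed with diploid normal cells contributing two
#' reference copies, yields expected VAF
#' `rho * c_mut / (rho * (c_mut + c_ref) + 2 * (1 - rho))`.
#'
#' @param purity Tumor purity in `[0,1]`.
#' @param c_mut,c_ref Tumor allele copy counts; `c_mut + c_ref >= 1`.
#' @return Expected VAF in `[0,1]`. Vectorized.
#' @export
expected_vaf <- function(purity, c_mut, c_ref) {
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0,1]")
  if (any(c_mut + c_ref < 1)) {
    stop("at least one tumor copy required (c_mut + c_ref >= 1)")
  }
  purity * c_mut / (purity * (c_mut + c_ref) + 2 * (1 - purity))
}

# assign tumor allele copy counts from the GISTIC call and whether the CNV
# targets the mutant allele
copy_states <- function(gistic, mutant_preferred) {
  c_mut <- integer(length(gistic))
  c_ref <- integer(length(gistic))
  pref <- as.integer(mutant_preferred)
  for (i in seq_along(gistic)) {
    cs <- switch(as.character(gistic[i]),
      "0" = c(1L, 1L),
      "1" = if (pref[i] == 1L) c(2L, 1L) else c(1L, 2L),
      "2" = if (pref[i] == 1L) c(3L, 1L) else c(1L, 3L),
      "-1" = if (pref[i] == 1L) c(1L, 0L) else c(0L, 1L),
      "-2" = if (pref[i] == 1L) c(1L, 0L) else c(0L, 1L),
      stop("GISTIC value outside {-2..2}")
    )
    c_mut[i] <- cs[1]; c_ref[i] <- cs[2]
  }
  tibble::tibble(c_mut = c_mut, c_ref = c_ref)
}

#' Simulate DNA and RNA read counts for a mutation table
#'
#' Read depth is Poisson at the configured mean; alt counts are binomial at
#' the expected VAF implied by purity and the mutation's allele copy state
#' (`c_mut`, `c_ref` columns). For RNA, an allele-specific expression
#' multiplier (`rna_multiplier` column) inflates the mutant allele's rate
#' before renormalization, and a configurable fraction of mutations has no
#' RNA coverage at all.
#'
#' @param muts Mutation tibble carrying `c_mut`, `c_ref`, `rna_multiplier`.
#' @param clinical Clinical tibble supplying `purity`.
#' @param config A [sim_config()].
#' @return `muts` with `dna_alt`, `dna_ref`, `rna_alt`, `rna_ref`,
#'   `true_dna_vaf`, `true_rna_vaf` filled in.
#' @export
simulate_read_counts <- function(muts, clinical, config) {
  df <- dplyr::inner_join(
    muts, dplyr::select(clinical, "sample_id", "purity"), by = "sample_id"
  )
  n <- nrow(df)
  ev_dna <- expected_vaf(df$purity, df$c_mut, df$c_ref)
  m <- df$rna_multiplier
  ev_rna <- (m * df$purity * df$c_mut) /
    (m * df$purity * df$c_mut + df$purity * df$c_ref +
       2 * (1 - df$purity))
  depth_dna <- rpois(n, config$depth_dna_mean)
  df$dna_alt <- rbinom(n, depth_dna, ev_dna)
  df$dna_ref <- depth_dna - df$dna_alt
  has_rna <- runif(n) < config$rna_coverage_prob
  depth_rna <- rpois(n, config$depth_rna_mean)
  rna_alt <- rbinom(n, depth_rna, ev_rna)
  df$rna_alt <- ifelse(has_rna, rna_alt, NA_integer_)
  df$rna_ref <- ifelse(has_rna, depth_rna - rna_alt, NA_integer_)
  df$true_dna_vaf <- ev_dna
  df$true_rna_vaf <- ev_rna
  dplyr::select(df, -"purity")
}

#' Simulate a gene x sample expression matrix with planted interactions
#'
#' Expression (log2 scale) is a per-gene baseline plus linear mutation,
#' CNV-dosage and mutation-by-CNV interaction effects, covariate effects and
#' Gaussian noise:
#' `baseline + beta_mut*mut + beta_cnv*gistic + beta_int*mut*gistic +
#'  age_beta*(age - 60) + gender_beta*(gender == "male") + N(0, sd)`.
#'
#' @param mut_events Tibble (`sample_id`, `gene`) of mutated sample-gene
#'   pairs.
#' @param cnv Long CNV tibble (`sample_id`, `gene`, `gistic`).
#' @param clinical Clinical tibble.
#' @param genes Character vector of gene symbols.
#' @param config A [sim_config()].
#' @return List with `expression` (long tibble) and `betas` (per gene-cancer
#'   truth tibble including baselines).
#' @export
simulate_expression <- function(mut_events, cnv, clinical, genes, config) {
  grid <- tidyr::expand_grid(
    gene = genes,
    sample_id = clinical$sample_id
  )
  grid <- dplyr::inner_join(
    grid,
    dplyr::select(clinical, "sample_id", "cancer_type", "age_at_diagnosis",
                  "gender"),
    by = "sample_id"
  )
  grid <- dplyr::mutate(
    dplyr::left_join(grid, dplyr::mutate(mut_events, mut = 1L),
                     by = c("sample_id", "gene")),
    mut = tidyr::replace_na(.data$mut, 0L)
  )
  grid <- dplyr::mutate(
    dplyr::left_join(grid, cnv, by = c("sample_id", "gene")),
    gistic = tidyr::replace_na(.data$gistic, 0L)
  )
  betas <- tidyr::expand_grid(
    gene = genes, cancer_type = unique(clinical$cancer_type)
  )
  betas$baseline <- rnorm(nrow(betas), config$expr_baseline_mean,
                          config$expr_baseline_sd)
  betas$beta_mut <- 0
  betas$beta_cnv <- config$beta_cnv
  betas$beta_int <- 0
  pe <- config$planted_expression
  if (!is.null(pe) && nrow(pe) > 0) {
    idx <- match(paste(betas$gene, betas$cancer_type),
                 paste(pe$gene, pe$cancer_type))
    hit <- !is.na(idx)
    betas$beta_mut[hit] <- pe$beta_mut[idx[hit]]
    betas$beta_cnv[hit] <- pe$beta_cnv[idx[hit]]
    betas$beta_int[hit] <- pe$beta_int[idx[hit]]
  }
  grid <- dplyr::inner_join(grid, betas, by = c("gene", "cancer_type"))
  grid$expression <- grid$baseline +
    grid$beta_mut * grid$mut +
    grid$beta_cnv * grid$gistic +
    grid$beta_int * grid$mut * grid$gistic +
    config$age_beta * (grid$age_at_diagnosis - 60) +
    config$gender_beta * (grid$gender == "male") +
    rnorm(nrow(grid), 0, config$expr_noise_sd)
  list(
    expression = dplyr::select(grid, "sample_id", "gene", "expression"),
    betas = betas
  )
}

#' Simulate per-sample eccDNA fragments on the toy genome
#'
#' Each sample draws a Poisson number of fragments. A configurable fraction
#' is forced to fully contain a planted gene (start before its start, end
#' after its end); the rest fall uniformly on a random chromosome with
#' log-normal lengths.
#'
#' @param config A [sim_config()].
#' @param genes Gene interval tibble from the cohort.
#' @param samples Character vector of sample ids.
#' @return Fragment tibble (`chrom`, `start`, `end`, `label`, `sample_id`).
#' @export
simulate_eccdna <- function(config, genes, samples) {
  planted_genes <- intersect(config$planted_pairs$gene, genes$label)
  if (length(planted_genes) == 0) planted_genes <- genes$label
  chrom_len <- 25 * 100000 + 100000
  n_frag <- rpois(length(samples), config$eccdna_rate)
  total <- sum(n_frag)
  if (total == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), label = character(),
                          sample_id = character()))
  }
  sample_id <- rep(samples, n_frag)
  contains <- runif(total) < config$eccdna_containment
  len <- pmax(1000, round(stats::rlnorm(total, config$eccdna_len_meanlog,
                                        config$eccdna_len_sdlog)))
  chrom <- sample(unique(genes$chrom), total, replace = TRUE)
  start <- floor(runif(total, 0, pmax(1, chrom_len - len)))
  end <- start + len
  # forced-containment fragments wrap a planted gene with random margins
  if (any(contains)) {
    g <- genes[match(sample(planted_genes, sum(contains), replace = TRUE),
                     genes$label), ]
    lead <- floor(runif(sum(contains), 0, 20000))
    trail <- floor(runif(sum(contains), 0, 20000))
    chrom[contains] <- g$chrom
    start[contains] <- pmax(0, g$start - lead)
    end[contains] <- g$end + trail
  }
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    label = sprintf("frag%05d", seq_len(total)), sample_id = sample_id
  )
}

#' Simulate a full multi-center cohort
#'
#' Draws every table the pipeline consumes — mutations with DNA/RNA read
#' counts, gene-level GISTIC calls, clinical profiles, expression, gene
#' intervals and eccDNA fragments — together with a truth table recording
#' every planted effect. Mutation and CNV incidence follow per-sample burden
#' heterogeneity (gamma-Poisson) and per-gene mutability weights; for planted
#' gene-cancer pairs the probability of a deep CNV given a mutation is
#' multiplied by the enrichment factor (capped at 1, with a warning when the
#' cap binds). The output is deterministic given the config (including its
#' seed).
#'
#' @param config A [sim_config()].
#' @return A `comut_cohort` list: `mutations`, `cnv`, `clinical`,
#'   `expression`, `genes`, `eccdna`, `truth` (list of `pairs`, `mutations`,
#'   `expression` tibbles) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  # derived stage seeds: stages can be regenerated independently
  stage_seed <- sample.int(.Machine$integer.max - 1L, 6)

  genes <- sprintf("G%02d", seq_len(config$n_genes))
  gene_iv <- toy_gene_intervals(genes)
  parts <- tidyr::expand_grid(cancer_type = config$cancer_types,
                              center = config$centers)

  set.seed(stage_seed[1]) # clinical profiles
  clinical <- purrr::pmap_dfr(parts, function(cancer_type, center) {
    n <- config$n_samples
    tibble::tibble(
      sample_id = sprintf("%s-%s-S%03d", cancer_type, center, seq_len(n)),
      cancer_type = cancer_type,
      center = center,
      purity = round(rbeta(n, config$purity_shape1, config$purity_shape2), 4),
      ploidy = round(exp(rnorm(n, log(2), 0.15)), 3),
      gender = sample(c("female", "male"), n, replace = TRUE),
      age_at_diagnosis = round(runif(n, 35, 85)),
      subtype = sample(paste0("ST", 1:3), n, replace = TRUE),
      ethnicity = sample(c("groupA", "groupB", "groupC"), n, replace = TRUE,
                         prob = c(0.6, 0.25, 0.15)),
      stage = sample(paste0("stage", 1:4), n, replace = TRUE)
    )
  })

  set.seed(stage_seed[2]) # incidence: mutations then CNVs
  gene_w <- rgamma(config$n_genes, shape = config$gene_weight_shape,
                   rate = config$gene_weight_shape)
  gene_w <- gene_w / mean(gene_w)
  n_all <- nrow(clinical)
  lambda_mut <- rgamma(n_all, shape = config$mutation_burden_dispersion,
                       rate = config$mutation_burden_dispersion /
                         config$mutation_burden_mean)
  p_mut <- outer(lambda_mut / config$n_genes, gene_w)
  p_mut <- pmin(p_mut, 0.95)
  mut_mat <- matrix(rbinom(length(p_mut), 1L, p_mut), nrow = n_all,
                    dimnames = list(clinical$sample_id, genes))

  cnv_factor <- rgamma(n_all, shape = config$cnv_burden_dispersion,
                       rate = config$cnv_burden_dispersion)
  planted_cna <- dplyr::filter(config$planted_pairs, .data$direction == "CNA")
  planted_cnd <- dplyr::filter(config$planted_pairs, .data$direction == "CND")
  enrich <- function(planted) {
    e <- matrix(1, nrow = n_all, ncol = config$n_genes,
                dimnames = list(clinical$sample_id, genes))
    for (k in seq_len(nrow(planted))) {
      rows <- clinical$cancer_type == planted$cancer_type[k]
      g <- planted$gene[k]
      e[rows, g] <- ifelse(mut_mat[rows, g] == 1L, planted$enrichment[k], 1)
    }
    e
  }
  p_cna <- config$cna_rate * cnv_factor * enrich(planted_cna)
  p_cnd <- config$cnd_rate * cnv_factor * enrich(planted_cnd)
  if (any(p_cna > 1) || any(p_cnd > 1)) {
    warning("planted enrichment pushed CNV probability above 1; capped")
  }
  p_cna <- pmin(p_cna, 1)
  p_cnd <- pmin(p_cnd, 1)
  cna_mat <- matrix(rbinom(length(p_cna), 1L, p_cna), nrow = n_all)
  cnd_mat <- matrix(rbinom(length(p_cnd), 1L, p_cnd), nrow = n_all)
  cnd_mat[cna_mat == 1L] <- 0L # a gene is not both deep-amplified and deleted
  gistic_mat <- 2L * cna_mat - 2L * cnd_mat
  neutral <- gistic_mat == 0L
  shallow <- matrix(
    sample(c(0L, 1L, -1L), length(gistic_mat), replace = TRUE,
           prob = c(1 - config$shallow_rate, config$shallow_rate / 2,
                    config$shallow_rate / 2)),
    nrow = n_all
  )
  gistic_mat[neutral] <- shallow[neutral]
  dimnames(gistic_mat) <- list(clinical$sample_id, genes)
  cnv <- tibble::as_tibble(as.data.frame.table(gistic_mat,
                                               stringsAsFactors = FALSE))
  names(cnv) <- c("sample_id", "gene", "gistic")
  cnv$gistic <- as.integer(cnv$gistic)
  cnv <- dplyr::filter(cnv, .data$gistic != 0L)

  set.seed(stage_seed[3]) # mutation annotations and copy states
  mut_events <- tibble::as_tibble(as.data.frame.table(mut_mat,
                                                      stringsAsFactors = FALSE))
  names(mut_events) <- c("sample_id", "gene", "present")
  mut_events <- dplyr::select(
    dplyr::filter(mut_events, .data$present == 1L), -"present"
  )
  n_mut <- nrow(mut_events)
  # three recurrent hotspots per gene so per-mutation summaries have support
  aa <- c("A", "R", "G", "V", "E", "K", "Q", "H", "L", "P")
  hotspots <- tibble::tibble(
    gene = rep(genes, each = 3),
    hot_id = rep(1:3, times = length(genes)),
    protein_change = sprintf("p.%s%d%s",
                             sample(aa, 3 * length(genes), replace = TRUE),
                             sample(50:900, 3 * length(genes), replace = TRUE),
                             sample(aa, 3 * length(genes), replace = TRUE))
  )
  hot_pick <- sample(1:3, n_mut, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  muts <- dplyr::mutate(mut_events,
    protein_change = hotspots$protein_change[
      match(paste(.data$gene, hot_pick), paste(hotspots$gene, hotspots$hot_id))
    ],
    mutation_class = sample(c("missense", "truncating", "other"), n_mut,
                            replace = TRUE, prob = c(0.65, 0.25, 0.10)),
    is_functional_driver = dplyr::case_when(
      mutation_class == "truncating" ~ TRUE,
      mutation_class == "missense" ~ runif(n_mut) < 0.8,
      TRUE ~ FALSE
    )
  )
  muts <- dplyr::mutate(
    dplyr::left_join(muts, cnv, by = c("sample_id", "gene")),
    gistic = tidyr::replace_na(.data$gistic, 0L)
  )
  muts <- dplyr::inner_join(
    muts, dplyr::select(clinical, "sample_id", "cancer_type"),
    by = "sample_id"
  )
  planted_key <- paste(config$planted_pairs$gene,
                       config$planted_pairs$cancer_type)
  muts$planted <- paste(muts$gene, muts$cancer_type) %in% planted_key
  pref_prob <- ifelse(muts$planted, config$mutant_preference_planted,
                      config$mutant_preference_other)
  muts$mutant_preferred <- runif(n_mut) < pref_prob
  cs <- copy_states(muts$gistic, muts$mutant_preferred)
  muts$c_mut <- cs$c_mut
  muts$c_ref <- cs$c_ref
  muts$rna_multiplier <- ifelse(muts$planted & muts$gistic != 0L,
                                config$rna_ase_planted, 1)

  set.seed(stage_seed[4]) # read counts
  muts <- simulate_read_counts(muts, clinical, config)

  set.seed(stage_seed[5]) # expression
  expr <- simulate_expression(dplyr::select(mut_events, "sample_id", "gene"),
                              cnv, clinical, genes, config)

  set.seed(stage_seed[6]) # eccDNA
  eccdna <- simulate_eccdna(config, gene_iv, clinical$sample_id)

  truth_mut <- dplyr::select(
    muts, "sample_id", "gene", "planted", "mutant_preferred",
    "c_mut", "c_ref", "true_dna_vaf", "true_rna_vaf"
  )
  mutation_table <- dplyr::select(
    muts, "sample_id", "gene", "protein_change", "mutation_class",
    "is_functional_driver", "dna_alt", "dna_ref", "rna_alt", "rna_ref",
    "gistic"
  )
  cohort <- list(
    mutations = mutation_table,
    cnv = cnv,
    clinical = clinical,
    expression = expr$expression,
    genes = gene_iv,
    eccdna = eccdna,
    truth = list(
      pairs = config$planted_pairs,
      mutations = truth_mut,
      expression = expr$betas
    ),
    config = config
  )
  class(cohort) <- c("comut_cohort", "list")
  cohort
}

#' @export
print.comut_cohort <- function(x, ...) {
  cat("Synthetic tumor cohort:",
      nrow(x$clinical), "samples,",
      length(unique(c(x$cnv$gene, x$mutations$gene))), "genes,",
      nrow(x$mutations), "mutations,",
      nrow(x$cnv), "non-neutral CNV calls\n")
  cat("  cancer types:", paste(unique(x$clinical$cancer_type),
                               collapse = ", "),
      "| centers:", paste(unique(x$clinical$center), collapse = ", "), "\n")
  invisible(x)
}
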