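expr_covars <- c("age_at_diagnosis", "gender", "ethnicity", "subtype")

#' Build per-gene expression datasets for one mutation-class stratum
#'
#' For each gene-cancer pair, assembles the rows of the expression models:
#' the gene's own (log2-scale) expression per sample, a binary mutation
#' status for the requested stratum, the gene-level GISTIC code and the
#' clinical covariates. A sample is `mut = 1` when it carries a qualifying
#' mutation of the stratum's class (functional missense, or truncating) in
#' the gene; samples carrying only mutations of other classes in the gene are
#' excluded from the stratum rather than pooled into the wild-type group.
#'
#' @param cohort Cohort list with an expression table.
#' @param stratum `"missense"` or `"truncating"`.
#' @return Tibble with `gene`, `cancer_type`, `stratum`, `sample_id`,
#'   `expression`, `mut`, `gistic` and covariate columns. Only pairs with at
#'   least one mutated and one wild-type sample are retained.
#' @export
build_expression_dataset <- function(cohort, stratum = c("missense",
                                                         "truncating")) {
  stratum <- match.arg(stratum)
  if (is.null(cohort$expression) || nrow(cohort$expression) == 0) {
    stop("cohort has no expression matrix")
  }
  muts <- cohort$mutations
  qualifying <- if (stratum == "missense") {
    muts$mutation_class == "missense" &
      (is.na(muts$is_functional_driver) | muts$is_functional_driver)
  } else {
    muts$mutation_class == "truncating"
  }
  stratum_muts <- dplyr::distinct(muts[qualifying, ], .data$sample_id,
                                  .data$gene)
  other_muts <- dplyr::distinct(muts[!qualifying, ], .data$sample_id,
                                .data$gene)
  # samples with only other-class mutations in the gene contaminate neither
  # group; drop them from this stratum
  excluded <- dplyr::anti_join(other_muts, stratum_muts,
                               by = c("sample_id", "gene"))

  df <- dplyr::inner_join(
    cohort$expression,
    dplyr::select(cohort$clinical, "sample_id", "cancer_type",
                  dplyr::any_of(expr_covars)),
    by = "sample_id"
  )
  df <- dplyr::anti_join(df, excluded, by = c("sample_id", "gene"))
  df <- dplyr::mutate(
    dplyr::left_join(df,
                     dplyr::mutate(stratum_muts, mut = 1L),
                     by = c("sample_id", "gene")),
    mut = tidyr::replace_na(.data$mut, 0L)
  )
  df <- dplyr::mutate(
    dplyr::left_join(df, cohort$cnv, by = c("sample_id", "gene")),
    gistic = tidyr::replace_na(.data$gistic, 0L)
  )
  # keep only pairs where the gene is mutated at all and a contrast exists
  eligible <- dplyr::filter(
    dplyr::summarise(
      dplyr::group_by(df, .data$gene, .data$cancer_type),
      n_mut = sum(.data$mut), n_wt = sum(1L - .data$mut), .groups = "drop"
    ),
    .data$n_mut >= 1, .data$n_wt >= 1
  )
  df <- dplyr::semi_join(df, eligible, by = c("gene", "cancer_type"))
  df$stratum <- stratum
  df
}

fit_lm_term <- function(df, response, terms, term_of_interest) {
  covars <- usable_covariates(df, intersect(expr_covars, names(df)))
  rhs <- paste(c(terms, covars), collapse = " + ")
  fit <- tryCatch(
    lm(stats::as.formula(paste(response, "~", rhs)), data = df),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  sm <- summary(fit)$coefficients
  if (!term_of_interest %in% rownames(sm)) return(NULL)
  list(fit = fit, coefs = sm)
}

#' Step-1 screen: mutation effect on the gene's own expression
#'
#' Per gene-cancer regression of expression on binary mutation status with
#' clinical covariates (age, gender, ethnicity, subtype where available),
#' followed by Benjamini-Hochberg correction within each cancer type. Pairs
#' without both mutated and wild-type samples are skipped.
#'
#' @param ds Dataset from [build_expression_dataset()].
#' @return Tibble with `gene`, `cancer_type`, `stratum`, `n`, `beta_mut_screen`,
#'   `step1_p`, `step1_q`.
#' @export
screen_mutation_expression <- function(ds) {
  parts <- dplyr::group_split(
    dplyr::group_by(ds, .data$gene, .data$cancer_type)
  )
  rows <- purrr::map_dfr(parts, function(d) {
    if (length(unique(d$mut)) < 2) return(NULL)
    r <- fit_lm_term(d, "expression", "mut", "mut")
    if (is.null(r)) return(NULL)
    tibble::tibble(
      gene = d$gene[1], cancer_type = d$cancer_type[1],
      stratum = d$stratum[1], n = nrow(d),
      beta_mut_screen = r$coefs["mut", "Estimate"],
      step1_p = r$coefs["mut", "Pr(>|t|)"]
    )
  })
  if (nrow(rows) == 0) return(rows)
  rows <- dplyr::mutate(
    dplyr::group_by(rows, .data$cancer_type),
    step1_q = bh_adjust(.data$step1_p)
  )
  dplyr::ungroup(rows)
}

#' Step-2: mutation x CNV interaction model on expression
#'
#' Least-squares fit of `expression ~ mut + gistic + mut:gistic + covariates`
#' for one gene-cancer pair, with the GISTIC code entered as a continuous
#' dosage. A positive interaction coefficient means samples carrying both the
#' mutation and the copy-number event express the gene above the additive
#' expectation.
#'
#' @param ds Rows of one gene-cancer pair from [build_expression_dataset()].
#' @return One-row tibble with `beta_mut`, `beta_cnv`, `beta_interaction`,
#'   `p_interaction` and an `unestimable` flag (set when the pair lacks both
#'   mutation levels, CNV variation, or the interaction contrast).
#' @export
fit_interaction_model <- function(ds) {
  base <- tibble::tibble(
    gene = ds$gene[1], cancer_type = ds$cancer_type[1],
    stratum = ds$stratum[1], n = nrow(ds),
    beta_mut = NA_real_, beta_cnv = NA_real_, beta_interaction = NA_real_,
    p_interaction = NA_real_, unestimable = TRUE
  )
  if (length(unique(ds$mut)) < 2 || length(unique(ds$gistic)) < 2) {
    return(base)
  }
  r <- fit_lm_term(ds, "expression", c("mut", "gistic", "mut:gistic"),
                   "mut:gistic")
  if (is.null(r) || is.na(r$coefs["mut:gistic", "Estimate"])) return(base)
  base$beta_mut <- r$coefs["mut", "Estimate"]
  base$beta_cnv <- r$coefs["gistic", "Estimate"]
  base$beta_interaction <- r$coefs["mut:gistic", "Estimate"]
  base$p_interaction <- r$coefs["mut:gistic", "Pr(>|t|)"]
  base$unestimable <- FALSE
  base
}

#' Two-step screen for synergistic mutation-CNV effects on expression
#'
#' Step 1 screens every gene-cancer pair of the stratum for a mutation effect
#' on the gene's own expression (covariate-adjusted, FDR within cancer type).
#' Step 2 fits the interaction model for pairs passing the step-1 gate
#' (FDR < `step1_fdr`) and applies Benjamini-Hochberg correction across all
#' step-2 fits. No pair failing the gate carries step-2 results.
#'
#' @param cohort Cohort list with an expression table.
#' @param stratum `"missense"` or `"truncating"`.
#' @param step1_fdr Step-1 gate (default 0.05).
#' @param fdr Step-2 significance threshold on q (default 0.05).
#' @return Tibble with one row per step-2 pair: screen columns plus
#'   `beta_mut`, `beta_cnv`, `beta_interaction`, `p_interaction`, `q`,
#'   `significant`. The full step-1 table is attached as attribute
#'   `"screen"`.
#' @export
run_interaction <- function(cohort, stratum = c("missense", "truncating"),
                            step1_fdr = 0.05, fdr = 0.05) {
  stratum <- match.arg(stratum)
  ds <- build_expression_dataset(cohort, stratum)
  screen <- screen_mutation_expression(ds)
  empty <- tibble::tibble(
    gene = character(), cancer_type = character(), stratum = character(),
    n = integer(), beta_mut = numeric(), beta_cnv = numeric(),
    beta_interaction = numeric(), p_interaction = numeric(),
    unestimable = logical(), step1_q = numeric(), q = numeric(),
    significant = logical()
  )
  if (nrow(screen) == 0) {
    attr(empty, "screen") <- screen
    return(empty)
  }
  gated <- dplyr::filter(screen, .data$step1_q < step1_fdr)
  if (nrow(gated) == 0) {
    attr(empty, "screen") <- screen
    return(empty)
  }
  ds_gated <- dplyr::semi_join(ds, gated, by = c("gene", "cancer_type"))
  parts <- dplyr::group_split(
    dplyr::group_by(ds_gated, .data$gene, .data$cancer_type)
  )
  res <- purrr::map_dfr(parts, fit_interaction_model)
  res <- dplyr::left_join(
    res, dplyr::select(gated, "gene", "cancer_type", "step1_q"),
    by = c("gene", "cancer_type")
  )
  res$q <- NA_real_
  est <- !res$unestimable
  res$q[est] <- bh_adjust(res$p_interaction[est])
  res$significant <- !is.na(res$q) & res$q < fdr
  res <- dplyr::arrange(res, .data$q)
  attr(res, "screen") <- screen
  res
}
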