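# Shared helper: keep only covariates that vary (>= 2 distinct non-missing
# values) in this data subset; constant or all-missing covariates cannot be
# estimated and are dropped with a note.
usable_covariates <- function(df, covars) {
  keep <- vapply(covars, function(v) {
    x <- df[[v]]
    length(unique(x[!is.na(x)])) >= 2
  }, logical(1))
  covars[keep]
}

level_counts <- function(muts, level = c("DNA", "RNA")) {
  level <- match.arg(level)
  if (level == "DNA") {
    list(alt = muts$dna_alt, ref = muts$dna_ref)
  } else {
    list(alt = muts$rna_alt, ref = muts$rna_ref)
  }
}

#' Assemble per-pair VAF regression datasets
#'
#' Builds, for every eligible gene-cancer pair, the rows entering the VAF
#' dosage regression: variant allele fractions at the requested level (DNA or
#' RNA) with read depth >= `min_depth`, the gene-level GISTIC code restricted
#' to the requested direction (amplifications use codes {0,1,2}, deletions
#' {-2,-1,0}), and the clinical covariates. A pair is eligible when it has at
#' least `min_mut_with` mutations co-occurring with a CNV of that direction
#' and at least `min_mut_without` mutations at GISTIC 0. Rows missing purity,
#' ploidy, age or gender are excluded (the model requires them; values are
#' never imputed).
#'
#' @param muts Mutation tibble.
#' @param clinical Clinical tibble (see [read_clinical_table()]).
#' @param level `"DNA"` or `"RNA"`.
#' @param direction `"CNA"` or `"CND"`.
#' @param min_mut_with,min_mut_without Eligibility thresholds (default 3 and
#'   3, the minimum giving the slope a contrast).
#' @param min_depth Minimum read depth (default 5).
#' @return Tibble of regression rows keyed by `gene`, `cancer_type`, with
#'   `vaf`, `gistic`, and covariate columns; `level` and `direction` recorded.
#' @export
build_vaf_dataset <- function(muts, clinical, level = c("DNA", "RNA"),
                              direction = c("CNA", "CND"),
                              min_mut_with = 3, min_mut_without = 3,
                              min_depth = 5) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  cnt <- level_counts(muts, level)
  if (all(is.na(cnt$alt))) {
    stop("no ", level, " read counts available in the mutation table")
  }
  df <- dplyr::mutate(muts,
    alt = cnt$alt, ref = cnt$ref,
    depth = .data$alt + .data$ref,
    vaf = vaf(.data$alt, .data$ref)
  )
  df <- dplyr::filter(df, !is.na(.data$depth), .data$depth >= min_depth)
  keep_gistic <- if (direction == "CNA") 0:2 else -2:0
  df <- dplyr::filter(df, .data$gistic %in% keep_gistic)
  df <- dplyr::inner_join(
    df,
    dplyr::select(clinical, "sample_id", "cancer_type", "purity", "ploidy",
                  "gender", "subtype", "age_at_diagnosis"),
    by = "sample_id"
  )
  df <- dplyr::filter(df, !is.na(.data$purity), !is.na(.data$ploidy),
                      !is.na(.data$gender), !is.na(.data$age_at_diagnosis))
  df <- dplyr::mutate(df,
    subtype = dplyr::coalesce(.data$subtype, "unknown"),
    cnv_state = classify_cnv(.data$gistic, "any")
  )
  eligible <- dplyr::filter(
    dplyr::summarise(
      dplyr::group_by(df, .data$gene, .data$cancer_type),
      n_with = sum(.data$cnv_state == direction),
      n_without = sum(.data$gistic == 0L),
      .groups = "drop"
    ),
    .data$n_with >= min_mut_with, .data$n_without >= min_mut_without
  )
  out <- dplyr::semi_join(df, eligible, by = c("gene", "cancer_type"))
  out <- dplyr::select(out, "gene", "cancer_type", "sample_id", "vaf",
                       "gistic", "purity", "ploidy", "gender", "subtype",
                       "age_at_diagnosis")
  out$level <- level
  out$direction <- direction
  out
}

fit_vaf_row <- function(ds) {
  covars <- usable_covariates(
    ds, c("purity", "ploidy", "gender", "subtype", "age_at_diagnosis")
  )
  n <- nrow(ds)
  base <- tibble::tibble(
    gene = ds$gene[1], cancer_type = ds$cancer_type[1],
    level = ds$level[1], direction = ds$direction[1], n = n,
    cnv_coefficient = NA_real_, cnv_se = NA_real_, cnv_p = NA_real_,
    unestimable = TRUE
  )
  if (length(unique(ds$gistic)) < 2) return(base)
  rhs <- paste(c("gistic", covars), collapse = " + ")
  fit <- tryCatch(
    lm(stats::as.formula(paste("vaf ~", rhs)), data = ds),
    error = function(e) NULL
  )
  if (is.null(fit)) return(base)
  sm <- summary(fit)$coefficients
  if (!"gistic" %in% rownames(sm) || is.na(coef(fit)["gistic"])) return(base)
  base$cnv_coefficient <- sm["gistic", "Estimate"]
  base$cnv_se <- sm["gistic", "Std. Error"]
  base$cnv_p <- sm["gistic", "Pr(>|t|)"]
  base$unestimable <- FALSE
  base
}

#' Fit the VAF ~ CNV dosage model for one gene-cancer pair
#'
#' Ordinary least squares of VAF on the GISTIC code (entered as a single
#' continuous regressor) plus purity, ploidy, gender, cancer subtype and age
#' at diagnosis. Covariates that are constant in the subset are dropped. The
#' CNV term's slope is the per-GISTIC-unit change in VAF; a positive slope
#' under amplification indicates preferential amplification of the mutant
#' allele.
#'
#' @param ds Rows of one gene-cancer pair from [build_vaf_dataset()].
#' @return An object of class `vaf_fit` holding the underlying `lm` and the
#'   CNV-term summary; see [tidy.vaf_fit()] and [glance.vaf_fit()]. Pairs
#'   with fewer than two distinct GISTIC values are flagged unestimable.
#' @export
fit_vaf_model <- function(ds) {
  if (nrow(ds) == 0) stop("empty dataset")
  if (length(unique(paste(ds$gene, ds$cancer_type))) != 1) {
    stop("fit_vaf_model expects rows of a single gene-cancer pair")
  }
  row <- fit_vaf_row(ds)
  covars <- usable_covariates(
    ds, c("purity", "ploidy", "gender", "subtype", "age_at_diagnosis")
  )
  model <- NULL
  if (!row$unestimable) {
    rhs <- paste(c("gistic", covars), collapse = " + ")
    model <- lm(stats::as.formula(paste("vaf ~", rhs)), data = ds)
  }
  structure(list(result = row, model = model, data = ds),
            class = "vaf_fit")
}

#' @export
print.vaf_fit <- function(x, ...) {
  r <- x$result
  cat("VAF ~ CNV dosage fit:", r$gene, "/", r$cancer_type,
      sprintf("(%s, %s, n = %d)\n", r$level, r$direction, r$n))
  if (r$unestimable) {
    cat("  unestimable (no CNV contrast)\n")
  } else {
    cat(sprintf("  slope per GISTIC unit: %.4f (p = %.3g)\n",
                r$cnv_coefficient, r$cnv_p))
  }
  invisible(x)
}

#' Tidy a VAF dosage fit
#'
#' @param x A `vaf_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the CNV term's estimate, standard error and
#'   p-value.
#' @export
tidy.vaf_fit <- function(x, ...) {
  dplyr::select(x$result, "gene", "cancer_type", "level", "direction",
                estimate = "cnv_coefficient", std.error = "cnv_se",
                p.value = "cnv_p")
}

#' Model-level summary of a VAF dosage fit
#'
#' @param x A `vaf_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `n`, `r.squared`, `sigma` and estimability.
#' @export
glance.vaf_fit <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(n = x$result$n, r.squared = NA_real_,
                          sigma = NA_real_, unestimable = TRUE))
  }
  sm <- summary(x$model)
  tibble::tibble(n = x$result$n, r.squared = sm$r.squared,
                 sigma = sm$sigma, unestimable = FALSE)
}

#' Cross-tumor screen of CNV dosage effects on mutation VAF
#'
#' Fits the dosage model for every eligible gene-cancer pair at the requested
#' level and direction, then applies Benjamini-Hochberg correction across all
#' estimable fits within the (level, direction) screen. Significance is
#' flagged at FDR < 0.05.
#'
#' @param cohort Cohort list (mutations + clinical), or a prebuilt dataset
#'   from [build_vaf_dataset()].
#' @inheritParams build_vaf_dataset
#' @param fdr Significance threshold on q (default 0.05).
#' @return Tibble with one row per fitted pair: `gene`, `cancer_type`,
#'   `level`, `direction`, `n`, `cnv_coefficient`, `cnv_p`, `q`,
#'   `significant`; unestimable pairs carry `NA` and are excluded from FDR.
#' @export
run_vaf_screen <- function(cohort, level = c("DNA", "RNA"),
                           direction = c("CNA", "CND"),
                           min_mut_with = 3, min_mut_without = 3,
                           min_depth = 5, fdr = 0.05) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  ds <- if (is.data.frame(cohort)) {
    cohort
  } else {
    build_vaf_dataset(cohort$mutations, cohort$clinical, level, direction,
                      min_mut_with, min_mut_without, min_depth)
  }
  if (nrow(ds) == 0) {
    return(tibble::tibble(
      gene = character(), cancer_type = character(), level = character(),
      direction = character(), n = integer(), cnv_coefficient = numeric(),
      cnv_se = numeric(), cnv_p = numeric(), unestimable = logical(),
      q = numeric(), significant = logical()
    ))
  }
  parts <- dplyr::group_split(
    dplyr::group_by(ds, .data$gene, .data$cancer_type)
  )
  res <- purrr::map_dfr(parts, fit_vaf_row)
  res$q <- NA_real_
  est <- !res$unestimable
  res$q[est] <- bh_adjust(res$cnv_p[est])
  res$significant <- !is.na(res$q) & res$q < fdr
  dplyr::arrange(res, .data$q)
}
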