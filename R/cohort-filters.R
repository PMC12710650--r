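#' Variant allele fraction from read counts
#'
#' @param alt,ref Non-negative alt/ref read counts.
#' @return `alt / (alt + ref)`, `NA` where total depth is zero.
#' @export
vaf <- function(alt, ref) {
  total <- alt + ref
  ifelse(!is.na(total) & total > 0, alt / total, NA_real_)
}

#' Restrict a mutation table to qualifying driver mutations
#'
#' Keeps mutations in the driver gene set whose class is truncating, or
#' missense with a positive functional-impact annotation. All other records
#' (including class "other") are dropped; the number dropped is reported as
#' a message.
#'
#' @param muts Mutation tibble (see [read_mutation_table()]).
#' @param driver_genes Character vector of driver gene symbols.
#' @return The filtered mutation tibble.
#' @export
filter_driver_mutations <- function(muts, driver_genes) {
  if (length(driver_genes) == 0) {
    stop("empty driver gene set; this is almost certainly a misconfiguration")
  }
  driver_genes <- toupper(driver_genes)
  keep <- muts$gene %in% driver_genes &
    (muts$mutation_class == "truncating" |
       (muts$mutation_class == "missense" &
          !is.na(muts$is_functional_driver) & muts$is_functional_driver))
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " mutation record(s) dropped by driver filtering")
  }
  muts[keep, , drop = FALSE]
}

#' Classify a gene-level GISTIC call as amplification, deletion or neutral
#'
#' Two modes reflect the two uses of copy-number calls in the pipeline.
#' `deep_only` counts only deep events (GISTIC +2 amplification, -2 deep
#' deletion) and backs the co-occurrence incidence matrices; `any` also
#' counts single-copy events (+1 gain, -1 hemizygous deletion) and backs the
#' regression and allelic-imbalance stratifications.
#'
#' @param gistic Integer vector of GISTIC calls in `{-2,...,2}`.
#' @param mode `"deep_only"` or `"any"`.
#' @return Character vector with values `"CNA"`, `"CND"`, `"neutral"`.
#' @export
classify_cnv <- function(gistic, mode = c("deep_only", "any")) {
  mode <- match.arg(mode)
  if (any(!is.na(gistic) & !(gistic %in% -2:2))) {
    stop("GISTIC value outside {-2..2}")
  }
  if (mode == "deep_only") {
    dplyr::case_when(
      gistic == 2L ~ "CNA",
      gistic == -2L ~ "CND",
      is.na(gistic) ~ NA_character_,
      TRUE ~ "neutral"
    )
  } else {
    dplyr::case_when(
      gistic >= 1L ~ "CNA",
      gistic <= -1L ~ "CND",
      is.na(gistic) ~ NA_character_,
      TRUE ~ "neutral"
    )
  }
}

#' Label a sample's carrier group for a gene
#'
#' The four-level factor used for survival-style stratification and
#' expression summaries: no alteration, mutation only, CNV only, or
#' co-occurring mutation and CNV.
#'
#' @param has_mut,has_cnv Logical (or 0/1) vectors.
#' @return Factor with levels `none`, `mutation_only`, `cnv_only`, `both`.
#' @export
label_carrier_group <- function(has_mut, has_cnv) {
  has_mut <- as.logical(has_mut)
  has_cnv <- as.logical(has_cnv)
  lab <- dplyr::case_when(
    has_mut & has_cnv ~ "both",
    has_mut & !has_cnv ~ "mutation_only",
    !has_mut & has_cnv ~ "cnv_only",
    !has_mut & !has_cnv ~ "none"
  )
  factor(lab, levels = c("none", "mutation_only", "cnv_only", "both"))
}

#' Purity-adjusted variant allele fraction
#'
#' Rescales an observed VAF by tumor purity under a diploid-dilution
#' approximation: normal-cell reads contribute only reference alleles, so a
#' clonal heterozygous mutation in a pure-diploid tumor recovers VAF 0.5.
#' The adjusted value `min(1, vaf / purity)` is capped at 1, where copy-number
#' effects push the observed fraction above what dilution alone explains.
#'
#' @param vaf Observed VAF in `[0,1]`.
#' @param purity Tumor purity in `(0,1]`.
#' @return Adjusted VAF in `[0,1]`; `NA` where either input is `NA`.
#' @export
adjust_vaf_for_purity <- function(vaf, purity) {
  if (any(!is.na(purity) & purity <= 0)) {
    stop("purity must be > 0 to adjust VAF")
  }
  pmin(1, vaf / purity)
}

#' Build a binary sample x gene alteration incidence matrix
#'
#' Collapses event records (one row per sample-gene event) to presence or
#' absence. Multiple events for one sample-gene pair count once.
#'
#' @param events Tibble with columns `sample_id` and `gene`; one row per
#'   qualifying event.
#' @param samples,genes Row and column universes (character). Defaults to the
#'   values observed in `events`.
#' @return Integer matrix with `samples` as rownames and `genes` as colnames,
#'   cells in `{0,1}`.
#' @export
build_alteration_matrix <- function(events, samples = NULL, genes = NULL) {
  if (is.null(samples)) samples <- sort(unique(events$sample_id))
  if (is.null(genes)) genes <- sort(unique(events$gene))
  m <- matrix(0L, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  ev <- dplyr::distinct(
    dplyr::filter(events, .data$sample_id %in% samples, .data$gene %in% genes),
    .data$sample_id, .data$gene
  )
  if (nrow(ev) > 0) {
    m[cbind(match(ev$sample_id, samples), match(ev$gene, genes))] <- 1L
  }
  m
}

#' Per-center mutation and CNV matrices for the co-occurrence test
#'
#' Splits a cohort by (cancer type, center) and builds, for each part, the
#' binary mutation incidence matrix and the binary deep-CNV incidence matrix
#' for the requested direction, restricted to their common samples and genes.
#'
#' @param cohort A cohort list.
#' @param direction `"CNA"` (deep amplification) or `"CND"` (deep deletion).
#' @param driver_genes Optional driver gene set; when given, mutations are
#'   first passed through [filter_driver_mutations()].
#' @return A list with one element per (cancer_type, center): a list with
#'   `mut`, `cnv` (matrices over identical samples and genes), `cancer_type`
#'   and `center`.
#' @export
cooccurrence_inputs <- function(cohort, direction = c("CNA", "CND"),
                                driver_genes = NULL) {
  direction <- match.arg(direction)
  muts <- cohort$mutations
  if (!is.null(driver_genes)) {
    muts <- suppressMessages(filter_driver_mutations(muts, driver_genes))
  }
  cnv_events <- dplyr::filter(
    cohort$cnv,
    classify_cnv(.data$gistic, "deep_only") == direction
  )
  parts <- dplyr::group_split(
    dplyr::group_by(cohort$clinical, .data$cancer_type, .data$center)
  )
  out <- lapply(parts, function(cl) {
    samples <- cl$sample_id
    genes <- sort(unique(c(muts$gene, cnv_events$gene)))
    mm <- build_alteration_matrix(
      dplyr::filter(muts, .data$sample_id %in% samples), samples, genes
    )
    cm <- build_alteration_matrix(
      dplyr::filter(cnv_events, .data$sample_id %in% samples), samples, genes
    )
    list(mut = mm, cnv = cm,
         cancer_type = cl$cancer_type[1], center = cl$center[1])
  })
  names(out) <- vapply(out, function(p) paste(p$cancer_type, p$center,
                                              sep = "."), "")
  out
}
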