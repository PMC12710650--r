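#' Build the matched background table for Binoculars
#'
#' Pools read counts of "mutation-only" mutations — those whose own locus has
#' GISTIC 0 in that sample — at four aggregation levels: (gene, cancer,
#' sample), (sample), (gene, cancer) and (cancer). Pooling is read-weighted
#' (sum of alt reads over sum of total reads), respecting the binomial model,
#' not a mean of per-mutation VAFs. Strata with no reads are absent; strata
#' whose pooled rate is exactly 0 or 1 are kept in the table but are never
#' returned as a match (the exact test is undefined there).
#'
#' @param muts Mutation tibble.
#' @param clinical Clinical tibble (supplies each sample's cancer type).
#' @param level `"DNA"` or `"RNA"`.
#' @return An object of class `background_table`: the four pooled tibbles
#'   plus the level.
#' @export
build_background_table <- function(muts, clinical, level = c("DNA", "RNA")) {
  level <- match.arg(level)
  cnt <- level_counts(muts, level)
  df <- tibble::tibble(
    sample_id = muts$sample_id, gene = muts$gene, gistic = muts$gistic,
    alt = cnt$alt, total = cnt$alt + cnt$ref
  )
  df <- dplyr::filter(df, .data$gistic == 0L, !is.na(.data$total),
                      .data$total > 0)
  df <- dplyr::inner_join(
    df, dplyr::select(clinical, "sample_id", "cancer_type"), by = "sample_id"
  )
  pool <- function(...) {
    dplyr::summarise(
      dplyr::group_by(df, ...),
      alt_sum = sum(.data$alt), total_sum = sum(.data$total),
      p0 = sum(.data$alt) / sum(.data$total), .groups = "drop"
    )
  }
  structure(
    list(
      level = level,
      gene_cancer_sample = pool(.data$gene, .data$cancer_type,
                                .data$sample_id),
      sample = pool(.data$sample_id),
      gene_cancer = pool(.data$gene, .data$cancer_type),
      cancer = pool(.data$cancer_type)
    ),
    class = "background_table"
  )
}

#' @export
print.background_table <- function(x, ...) {
  cat("Binoculars background table (", x$level, " level)\n", sep = "")
  cat("  strata: gene-cancer-sample", nrow(x$gene_cancer_sample),
      "| sample", nrow(x$sample),
      "| gene-cancer", nrow(x$gene_cancer),
      "| cancer", nrow(x$cancer), "\n")
  invisible(x)
}

#' Match mutations against the most related background stratum
#'
#' Searches the four aggregation levels in order — (gene, cancer, sample),
#' then (sample), then (gene, cancer), then (cancer) — and returns the first
#' usable hit (pooled rate strictly between 0 and 1). Vectorized over
#' mutations.
#'
#' @param bg A `background_table`.
#' @param gene,cancer,sample Character vectors of equal length identifying
#'   each mutation's gene, cancer type and sample.
#' @return Tibble with `p0` (matched background rate, `NA` when all four
#'   levels miss) and `match_level` in
#'   `{"gene_cancer_sample", "sample", "gene_cancer", "cancer"}`.
#' @export
match_background <- function(bg, gene, cancer, sample) {
  stopifnot(inherits(bg, "background_table"))
  q <- tibble::tibble(gene = gene, cancer_type = cancer, sample_id = sample)
  usable <- function(tb) dplyr::filter(tb, .data$p0 > 0, .data$p0 < 1)
  j1 <- dplyr::left_join(q, usable(bg$gene_cancer_sample),
                         by = c("gene", "cancer_type", "sample_id"))$p0
  j2 <- dplyr::left_join(q, usable(bg$sample), by = "sample_id")$p0
  j3 <- dplyr::left_join(q, usable(bg$gene_cancer),
                         by = c("gene", "cancer_type"))$p0
  j4 <- dplyr::left_join(q, usable(bg$cancer), by = "cancer_type")$p0
  p0 <- dplyr::coalesce(j1, j2, j3, j4)
  match_level <- dplyr::case_when(
    !is.na(j1) ~ "gene_cancer_sample",
    !is.na(j2) ~ "sample",
    !is.na(j3) ~ "gene_cancer",
    !is.na(j4) ~ "cancer",
    TRUE ~ NA_character_
  )
  tibble::tibble(p0 = p0, match_level = match_level)
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' Two-sided exact binomial p-value by the minimum-likelihood method: the sum
#' of probabilities of all outcomes no more probable than the observed one
#' under Binomial(total, p0), with a small relative tolerance (1e-7) for
#' floating-point ties. Vectorized over observations.
#'
#' @param alt Observed alt read counts, `0 <= alt <= total`.
#' @param total Total read depths.
#' @param p0 Null success rates, strictly inside (0, 1).
#' @return Exact p-values in `(0, 1]`; `NA` where `total` is 0 (untestable).
#' @export
binomial_imbalance_test <- function(alt, total, p0) {
  n <- max(length(alt), length(total), length(p0))
  alt <- rep_len(alt, n); total <- rep_len(total, n); p0 <- rep_len(p0, n)
  if (any(!is.na(p0) & (p0 <= 0 | p0 >= 1))) {
    stop("background rate p0 must lie strictly inside (0, 1)")
  }
  if (any(!is.na(alt) & !is.na(total) & (alt < 0 | alt > total))) {
    stop("alt counts must satisfy 0 <= alt <= total")
  }
  vapply(seq_len(n), function(i) {
    if (is.na(alt[i]) || is.na(total[i]) || is.na(p0[i])) return(NA_real_)
    if (total[i] == 0) return(NA_real_)
    probs <- dbinom(0:total[i], total[i], p0[i])
    min(1, sum(probs[probs <= probs[alt[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Binoculars: matched-background allelic-imbalance screen
#'
#' For every mutation co-occurring with a copy-number event of the requested
#' direction (single-copy events included), tests the alt/ref read counts at
#' the requested level against the best-matched background rate from
#' mutations without co-occurring CNVs, using the exact two-sided binomial
#' test. Benjamini-Hochberg correction runs across all tested mutations
#' within the (level, direction) screen; each significant mutation is called
#' `increased` or `decreased` by the side of its VAF relative to the matched
#' background.
#'
#' @param cohort Cohort list (mutations + clinical).
#' @param level `"DNA"` or `"RNA"`.
#' @param direction `"CNA"` or `"CND"`.
#' @param q_threshold Call threshold on q (default 0.05).
#' @return Tibble with one row per tested mutation: identity columns, `alt`,
#'   `total`, `vaf`, `purity_adjusted_vaf`, `p0`, `match_level`, `p`, `q`,
#'   `call`. Mutations with no usable background or zero depth are returned
#'   in the `"unmatched"` attribute.
#' @export
run_binoculars <- function(cohort, level = c("DNA", "RNA"),
                           direction = c("CNA", "CND"), q_threshold = 0.05) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  muts <- cohort$mutations
  cnt <- level_counts(muts, level)
  df <- dplyr::mutate(muts, alt = cnt$alt, total = cnt$alt + cnt$ref)
  df <- dplyr::inner_join(
    df, dplyr::select(cohort$clinical, "sample_id", "cancer_type", "purity"),
    by = "sample_id"
  )
  df <- dplyr::filter(
    df, classify_cnv(.data$gistic, "any") == direction,
    !is.na(.data$total), .data$total > 0
  )
  empty <- tibble::tibble(
    sample_id = character(), gene = character(), protein_change = character(),
    mutation_class = character(), cancer_type = character(),
    level = character(), direction = character(), gistic = integer(),
    alt = integer(), total = integer(), vaf = numeric(),
    purity_adjusted_vaf = numeric(), p0 = numeric(), match_level = character(),
    p = numeric(), q = numeric(), call = character()
  )
  if (nrow(df) == 0) {
    attr(empty, "unmatched") <- empty
    return(empty)
  }
  bg <- build_background_table(muts, cohort$clinical, level)
  m <- match_background(bg, df$gene, df$cancer_type, df$sample_id)
  df$p0 <- m$p0
  df$match_level <- m$match_level
  df$vaf <- df$alt / df$total
  df$purity_adjusted_vaf <- ifelse(
    !is.na(df$purity) & df$purity > 0,
    adjust_vaf_for_purity(df$vaf, pmax(df$purity, 1e-9)), NA_real_
  )
  df$level <- level
  df$direction <- direction
  tested <- !is.na(df$p0)
  out <- df[tested, , drop = FALSE]
  unmatched <- df[!tested, , drop = FALSE]
  out$p <- binomial_imbalance_test(out$alt, out$total, out$p0)
  out$q <- bh_adjust(out$p)
  out$call <- dplyr::case_when(
    out$q < q_threshold & out$vaf > out$p0 ~ "increased",
    out$q < q_threshold & out$vaf < out$p0 ~ "decreased",
    TRUE ~ "no_change"
  )
  cols <- c("sample_id", "gene", "protein_change", "mutation_class",
            "cancer_type", "level", "direction", "gistic", "alt", "total",
            "vaf", "purity_adjusted_vaf", "p0", "match_level", "p", "q",
            "call")
  out <- dplyr::arrange(dplyr::select(out, dplyr::all_of(cols)), .data$q)
  attr(out, "unmatched") <- dplyr::select(
    unmatched, dplyr::any_of(setdiff(cols, c("p", "q", "call")))
  )
  out
}

#' Per-mutation direction proportions among recurrent mutations
#'
#' Tallies, for each recurrent protein change (at least `min_count`
#' occurrences across samples), the proportions of its tested occurrences
#' called increased, decreased or unchanged.
#'
#' @param results Tibble from [run_binoculars()].
#' @param min_count Minimum occurrences for a mutation to be summarized
#'   (default 10).
#' @param by_class Also stratify by `mutation_class` (missense vs truncating).
#' @return Tibble with `gene`, `protein_change` (and optionally
#'   `mutation_class`), `n`, and `prop_increased`, `prop_decreased`,
#'   `prop_no_change` summing to 1 per row.
#' @export
summarize_mutation_direction <- function(results, min_count = 10,
                                         by_class = FALSE) {
  keys <- c("gene", "protein_change", if (by_class) "mutation_class")
  out <- dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(keys))),
    n = dplyr::n(),
    prop_increased = mean(.data$call == "increased"),
    prop_decreased = mean(.data$call == "decreased"),
    prop_no_change = mean(.data$call == "no_change"),
    .groups = "drop"
  )
  dplyr::arrange(
    dplyr::filter(out, .data$n >= min_count),
    dplyr::desc(.data$prop_increased)
  )
}

#' Per-unit Pearson correlation of paired VAF (or expression) values
#'
#' Reused for DNA-vs-RNA VAF agreement and for RNA-VAF-vs-total-expression
#' analyses: for each unit (e.g. gene and protein change) with at least
#' `min_n` complete pairs, computes the Pearson correlation with a two-sided
#' p-value, then Benjamini-Hochberg correction across all tested units.
#'
#' @param data Tibble of paired values.
#' @param x,y Names (strings) of the two value columns.
#' @param unit_cols Character vector of columns identifying the unit
#'   (default `c("gene", "protein_change")`).
#' @param min_n Minimum complete pairs per unit (default 10).
#' @return Tibble with the unit columns, `n`, `r`, `p`, `q` and an
#'   `unestimable` flag for zero-variance units; units below `min_n` are
#'   skipped entirely.
#' @export
correlate_vaf <- function(data, x = "dna_vaf", y = "rna_vaf",
                          unit_cols = c("gene", "protein_change"),
                          min_n = 10) {
  parts <- dplyr::group_split(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(unit_cols)))
  )
  rows <- purrr::map_dfr(parts, function(d) {
    ok <- complete.cases(d[[x]], d[[y]])
    n <- sum(ok)
    if (n < min_n) return(NULL)
    key <- dplyr::distinct(d[, unit_cols, drop = FALSE])
    xv <- d[[x]][ok]; yv <- d[[y]][ok]
    if (sd(xv) == 0 || sd(yv) == 0) {
      return(dplyr::bind_cols(key, tibble::tibble(
        n = n, r = NA_real_, p = NA_real_, unestimable = TRUE
      )))
    }
    ct <- cor.test(xv, yv, method = "pearson")
    dplyr::bind_cols(key, tibble::tibble(
      n = n, r = unname(ct$estimate), p = ct$p.value, unestimable = FALSE
    ))
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(n = integer(), r = numeric(), p = numeric(),
                          q = numeric(), unestimable = logical()))
  }
  rows$q <- NA_real_
  rows$q[!rows$unestimable] <- bh_adjust(rows$p[!rows$unestimable])
  dplyr::arrange(rows, .data$q)
}
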