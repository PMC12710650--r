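#' Does an eccDNA fragment fully contain a gene?
#'
#' Containment in 0-based half-open coordinates: the fragment's interval must
#' start at or before the gene's start and end at or after the gene's end on
#' the same chromosome. Strand is ignored (circular DNA). Vectorized with
#' recycling.
#'
#' @param frag,gene Tibbles (or lists) with `chrom`, `start`, `end`.
#' @return Logical vector.
#' @export
fragment_contains_gene <- function(frag, gene) {
  check_iv <- function(iv, what) {
    if (any(iv$start >= iv$end)) {
      stop("malformed ", what, " interval(s): start >= end")
    }
  }
  check_iv(frag, "fragment"); check_iv(gene, "gene")
  frag$chrom == gene$chrom & frag$start <= gene$start & frag$end >= gene$end
}

#' Per gene-cancer counts of co-occurrence, eccDNA containment, and both
#'
#' For each significant gene-cancer pair, counts the samples of that cancer
#' cohort carrying a mutation-CNA co-occurrence in the gene, the samples
#' carrying an eccDNA fragment long enough to contain the entire gene, and
#' the intersection of the two sets (same-sample containment).
#'
#' @param pairs Tibble of gene-cancer pairs to summarize (`gene`,
#'   `cancer_type`), e.g. significant co-occurrence calls.
#' @param events Tibble of co-occurring sample-gene events (`sample_id`,
#'   `gene`), one row per sample carrying both a mutation and a CNA in the
#'   gene; see [cooccurring_events()].
#' @param fragments eccDNA fragment tibble (`chrom`, `start`, `end`,
#'   `sample_id`).
#' @param genes Gene interval tibble (`chrom`, `start`, `end`, `label`).
#' @param clinical Clinical tibble mapping samples to cancer types.
#' @return Tibble with `gene`, `cancer_type`, `n_mut_cna`, `n_eccdna`,
#'   `n_both` and `fraction` (= `n_both / n_mut_cna`, `NA` when no
#'   co-occurring sample). Pairs whose gene has no coordinates are excluded
#'   with a warning and listed in the `"missing_genes"` attribute.
#' @export
count_overlap_samples <- function(pairs, events, fragments, genes, clinical) {
  pairs <- dplyr::distinct(pairs, .data$gene, .data$cancer_type)
  missing_genes <- setdiff(pairs$gene, genes$label)
  if (length(missing_genes) > 0) {
    warning("no coordinates for gene(s): ",
            paste(missing_genes, collapse = ", "), "; excluded")
    pairs <- dplyr::filter(pairs, !.data$gene %in% missing_genes)
  }
  out <- purrr::pmap_dfr(pairs, function(gene, cancer_type) {
    samples <- clinical$sample_id[clinical$cancer_type == cancer_type]
    gi <- genes[genes$label == gene, , drop = FALSE][1, ]
    ev_samples <- unique(events$sample_id[
      events$gene == gene & events$sample_id %in% samples
    ])
    fr <- fragments[fragments$sample_id %in% samples, , drop = FALSE]
    contains <- if (nrow(fr) > 0) {
      fragment_contains_gene(fr, gi[rep(1, nrow(fr)), ])
    } else {
      logical(0)
    }
    ecc_samples <- unique(fr$sample_id[contains])
    n_mut_cna <- length(ev_samples)
    tibble::tibble(
      gene = gene, cancer_type = cancer_type,
      n_mut_cna = n_mut_cna,
      n_eccdna = length(ecc_samples),
      n_both = length(intersect(ev_samples, ecc_samples)),
      fraction = ifelse(n_mut_cna > 0,
                        length(intersect(ev_samples, ecc_samples)) / n_mut_cna,
                        NA_real_)
    )
  })
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Samples with co-occurring mutation and CNV per gene
#'
#' Convenience extractor: one row per (sample, gene) where the sample carries
#' both a qualifying mutation and a copy-number event of the requested
#' direction in the gene.
#'
#' @param cohort Cohort list.
#' @param direction `"CNA"` or `"CND"`.
#' @param mode CNV classification mode passed to [classify_cnv()]
#'   (default `"any"`: single-copy events count as impacted).
#' @return Tibble with `sample_id`, `gene`.
#' @export
cooccurring_events <- function(cohort, direction = c("CNA", "CND"),
                               mode = c("any", "deep_only")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  cnv <- dplyr::filter(cohort$cnv,
                       classify_cnv(.data$gistic, mode) == direction)
  dplyr::distinct(
    dplyr::inner_join(
      dplyr::distinct(cohort$mutations, .data$sample_id, .data$gene),
      dplyr::distinct(cnv, .data$sample_id, .data$gene),
      by = c("sample_id", "gene")
    ),
    .data$sample_id, .data$gene
  )
}
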