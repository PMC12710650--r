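#' Observed mutation-CNV co-occurrence proportion per gene
#'
#' For each gene the proportion of mutated samples that also carry a CNV
#' event in the same gene: if 5 samples are mutated in a gene and 2 of those
#' are CNV-positive, the co-occurrence proportion is 2/5 = 0.4.
#'
#' @param mut,cnv Binary sample x gene incidence matrices over identical
#'   samples and genes (see [build_alteration_matrix()]).
#' @param gene Optional single gene symbol; when given, only that gene's row
#'   is returned and its absence from either matrix is an error.
#' @return Tibble with columns `gene`, `n_mut`, `n_co`, `proportion`
#'   (`NA` where no sample is mutated).
#' @export
observed_proportion <- function(mut, cnv, gene = NULL) {
  stopifnot(identical(dim(mut), dim(cnv)))
  if (!identical(colnames(mut), colnames(cnv)) ||
      !identical(rownames(mut), rownames(cnv))) {
    stop("MUT and CNV matrices must share samples and genes in the same order")
  }
  if (!is.null(gene)) {
    if (!gene %in% colnames(mut)) {
      stop("gene not present in both matrices: ", gene)
    }
  }
  n_mut <- colSums(mut)
  n_co <- colSums(mut * cnv)
  out <- tibble::tibble(
    gene = colnames(mut),
    n_mut = as.integer(n_mut),
    n_co = as.integer(n_co),
    proportion = ifelse(n_mut > 0, n_co / n_mut, NA_real_)
  )
  if (!is.null(gene)) out <- out[out$gene == gene, , drop = FALSE]
  out
}

#' Degree-preserving randomization of a binary incidence matrix
#'
#' Runs a checkerboard-trade Markov chain on the matrix: repeatedly pick two
#' 1-cells in distinct rows and columns whose opposite corners are 0, and
#' swap the 2x2 checkerboard. Every accepted trade preserves all row sums
#' (per-sample burden) and column sums (per-gene frequency), so the chain
#' samples from the fixed-margin null. Matrices admitting no trade (e.g. all
#' ones) are returned unchanged. Successive calls continue the chain; results
#' are deterministic under [set.seed()].
#'
#' @param m Binary integer matrix.
#' @param n_trades Number of attempted trades; defaults to 20x the number of
#'   1-cells, a standard burn-in length.
#' @param count Whether `n_trades` counts `"attempts"` (default; failed picks
#'   included, matching the chain used in [run_cooccurrence()]) or
#'   `"swaps"` (successful trades only, bounded internally).
#' @return A randomized matrix with the same dimnames and margins.
#' @export
randomize_matrix <- function(m, n_trades = NULL,
                             count = c("attempts", "swaps")) {
  count <- match.arg(count)
  storage.mode(m) <- "integer"
  if (any(m != 0L & m != 1L)) stop("matrix must be binary")
  nnz <- sum(m)
  if (is.null(n_trades)) n_trades <- 20L * max(nnz, 1L)
  out <- if (count == "attempts") {
    cpp_checkerboard(m, as.integer(n_trades))
  } else {
    cpp_checkerboard_swaps(m, as.integer(n_trades),
                           as.integer(1000L * max(n_trades, 1L)))
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Permutation p-value from permuted co-occurrence proportions
#'
#' The p-value is the fraction of permutations whose proportion reaches or
#' exceeds the observed one. With `pseudocount` (default), one is added to
#' numerator and denominator so the p-value is never exactly zero and
#' Benjamini-Hochberg correction stays valid; without it the raw ratio is
#' returned.
#'
#' @param observed Observed proportion (scalar).
#' @param permuted Numeric vector of permuted proportions.
#' @param pseudocount Add-one correction (default `TRUE`).
#' @return The permutation p-value in `(0, 1]` (or `[0, 1]` raw).
#' @export
permutation_pvalue <- function(observed, permuted, pseudocount = TRUE) {
  if (length(permuted) < 1) stop("need at least one permutation")
  hits <- sum(permuted >= observed)
  if (pseudocount) (1 + hits) / (length(permuted) + 1) else hits / length(permuted)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving with
#' the input. Thin wrapper over [stats::p.adjust()] with input validation.
#'
#' @param ps Numeric vector of p-values in `[0,1]` (`NA` allowed).
#' @return Vector of q-values aligned with `ps`.
#' @export
bh_adjust <- function(ps) {
  if (any(!is.na(ps) & (ps < 0 | ps > 1))) stop("p-values must lie in [0,1]")
  p.adjust(ps, method = "BH")
}

#' Combine p-values by Edgington's method
#'
#' The combined p-value is the probability that a sum of `k` independent
#' Uniform(0,1) variables falls at or below the observed sum of the component
#' p-values, i.e. the Irwin-Hall CDF evaluated at `sum(ps)`. Unlike Fisher's
#' method it is well defined when a component p-value is exactly zero, which
#' permutation tests without a pseudocount can produce.
#'
#' @param ps Numeric vector of `k >= 1` p-values in `[0,1]`.
#' @return Combined p-value in `[0,1]`; equals `ps` when `k = 1`.
#' @export
edgington_combine <- function(ps) {
  if (length(ps) == 0) stop("cannot combine an empty set of p-values")
  if (any(is.na(ps)) || any(ps < 0 | ps > 1)) {
    stop("p-values must lie in [0,1] and be non-missing")
  }
  irwin_hall_cdf(sum(ps), length(ps))
}

# CDF of the sum of k iid Uniform(0,1) variables. Exact alternating series
# for small k (reflected into the lower tail to limit cancellation); for
# large k a normal approximation with an Edgeworth kurtosis correction (the
# distribution is symmetric, so the skewness term vanishes).
irwin_hall_cdf <- function(s, k) {
  stopifnot(k >= 1)
  if (s <= 0) return(0)
  if (s >= k) return(1)
  if (k == 1) return(s)
  if (k <= 20) {
    upper <- s > k / 2
    x <- if (upper) k - s else s
    j <- 0:floor(x)
    terms <- exp(lchoose(k, j) + k * log(x - j) - lfactorial(k))
    terms[x - j == 0] <- 0
    val <- sum(terms * (-1)^j)
    val <- min(max(val, 0), 1)
    if (upper) 1 - val else val
  } else {
    z <- (s - k / 2) / sqrt(k / 12)
    corr <- exp(-z^2 / 2) / sqrt(2 * pi) * (z^3 - 3 * z) / (20 * k)
    min(max(pnorm(z) + corr, 0), 1)
  }
}

#' Permutation test for positively selected mutation-CNV co-occurrence
#'
#' For each (cancer type, center) part, both the mutation and the CNV
#' incidence matrix are independently randomized by margin-preserving
#' checkerboard trades; the permuted per-gene co-occurrence proportion is
#' recorded for each of `n_perm` permutations, and the p-value is the
#' fraction of permutations reaching the observed proportion. Genes with zero
#' observed co-occurrence are removed before permuting. Per-center p-values
#' for the same gene-cancer pair are then combined with Edgington's method
#' and Benjamini-Hochberg correction is applied across all combined pairs.
#'
#' @param inputs Either a cohort list or the output of
#'   [cooccurrence_inputs()].
#' @param direction `"CNA"` or `"CND"` (deep events only).
#' @param n_perm Permutations per cohort part (study default 100000; reduce
#'   for exploratory runs).
#' @param pseudocount Add-one p-value correction, see [permutation_pvalue()].
#' @param q_threshold Significance flag threshold on the combined q-values
#'   (default 0.01).
#' @param burn_in,step Attempted trades before the first sample and between
#'   samples; default 20x and 1x the matrix's 1-cell count.
#' @param null `"checkerboard"` (both margins preserved, default) or
#'   `"shuffle"` (within-sample gene-label shuffle preserving row sums only,
#'   for sensitivity analysis).
#' @param driver_genes Passed to [cooccurrence_inputs()] when `inputs` is a
#'   cohort.
#' @return Tibble of combined results (`gene`, `cancer_type`, `n_centers`,
#'   `observed_proportion` averaged across centers, `edgington_p`, `q`,
#'   `significant`), sorted by `q`. The per-center table (with `n_mut_samples`,
#'   `n_co_samples`, `perm_p` and per-center `q_center`) is attached as the
#'   `"per_center"` attribute and available via [cooccurrence_centers()].
#' @export
run_cooccurrence <- function(inputs, direction = c("CNA", "CND"),
                             n_perm = 100000, pseudocount = TRUE,
                             q_threshold = 0.01, burn_in = NULL, step = NULL,
                             null = c("checkerboard", "shuffle"),
                             driver_genes = NULL) {
  direction <- match.arg(direction)
  null <- match.arg(null)
  if (n_perm < 1) stop("n_permutations must be >= 1")
  if (inherits(inputs, "comut_cohort") ||
      (is.list(inputs) && !is.null(inputs$clinical))) {
    inputs <- cooccurrence_inputs(inputs, direction, driver_genes)
  }

  per_center <- purrr::map_dfr(inputs, function(part) {
    mut <- part$mut
    cnv <- part$cnv
    common_samples <- intersect(rownames(mut), rownames(cnv))
    common_genes <- intersect(colnames(mut), colnames(cnv))
    if (length(common_samples) == 0) {
      stop("no overlapping samples between MUT and CNV matrices (",
           part$cancer_type, "/", part$center, ")")
    }
    mut <- mut[common_samples, common_genes, drop = FALSE]
    cnv <- cnv[common_samples, common_genes, drop = FALSE]
    obs <- observed_proportion(mut, cnv)
    obs <- obs[!is.na(obs$proportion) & obs$proportion > 0, , drop = FALSE]
    if (nrow(obs) == 0) return(NULL)
    mut <- mut[, obs$gene, drop = FALSE]
    cnv <- cnv[, obs$gene, drop = FALSE]
    storage.mode(mut) <- "integer"
    storage.mode(cnv) <- "integer"
    nnz <- max(sum(mut), sum(cnv), 1L)
    if (is.null(burn_in)) burn_in <- 20L * nnz
    if (is.null(step)) step <- nnz
    counts <- if (null == "checkerboard") {
      cpp_perm_cooc_counts(mut, cnv, as.integer(n_perm),
                           as.integer(burn_in), as.integer(step))
    } else {
      cpp_perm_cooc_counts_shuffle(mut, cnv, as.integer(n_perm))
    }
    # column sums are invariant, so comparing counts compares proportions
    hits <- colSums(sweep(counts, 2, obs$n_co, ">="))
    perm_p <- if (pseudocount) (1 + hits) / (n_perm + 1) else hits / n_perm
    tibble::tibble(
      gene = obs$gene,
      cancer_type = part$cancer_type,
      center = part$center,
      n_mut_samples = obs$n_mut,
      n_co_samples = obs$n_co,
      observed_proportion = obs$proportion,
      perm_p = unname(perm_p)
    )
  })

  if (nrow(per_center) == 0) {
    combined <- tibble::tibble(
      gene = character(), cancer_type = character(), n_centers = integer(),
      observed_proportion = numeric(), edgington_p = numeric(),
      q = numeric(), significant = logical()
    )
    attr(combined, "per_center") <- per_center
    attr(combined, "direction") <- direction
    return(combined)
  }

  per_center <- dplyr::mutate(
    dplyr::group_by(per_center, .data$center, .data$cancer_type),
    q_center = bh_adjust(.data$perm_p)
  )
  per_center <- dplyr::ungroup(per_center)

  combined <- dplyr::summarise(
    dplyr::group_by(per_center, .data$gene, .data$cancer_type),
    n_centers = dplyr::n(),
    observed_proportion = mean(.data$observed_proportion),
    edgington_p = edgington_combine(.data$perm_p),
    .groups = "drop"
  )
  combined$q <- bh_adjust(combined$edgington_p)
  combined$significant <- combined$q < q_threshold
  combined <- dplyr::arrange(combined, .data$q, .data$edgington_p)
  attr(combined, "per_center") <- per_center
  attr(combined, "direction") <- direction
  combined
}

#' Per-center co-occurrence table from a combined result
#'
#' @param result A tibble returned by [run_cooccurrence()].
#' @return The per-center result tibble.
#' @export
cooccurrence_centers <- function(result) {
  attr(result, "per_center")
}

#' Two-hit mechanism comparison: mutation+deletion vs homozygous deletion
#'
#' For genes whose mutations significantly co-occur with deletions, compares
#' two routes to biallelic inactivation within each cancer cohort: the
#' fraction of samples carrying a mutation together with a deep deletion of
#' the same gene, and the fraction carrying a homozygous (GISTIC -2)
#' deletion.
#'
#' @param results Tibble of gene-cancer pairs (e.g. significant CND results
#'   from [run_cooccurrence()]); only `gene` and `cancer_type` are used.
#' @param cohort Cohort list providing mutations, CNV calls and clinical
#'   sample-to-cancer mapping.
#' @return Tibble with `gene`, `cancer_type`, `freq_mut_cnd`, `freq_homdel`
#'   and `predominant` in `{"mut_cnd", "homdel", "tie"}`.
#' @export
summarize_two_hit <- function(results, cohort) {
  pairs <- dplyr::distinct(results, .data$gene, .data$cancer_type)
  cl <- cohort$clinical
  homdel <- dplyr::filter(cohort$cnv, .data$gistic == -2L)
  purrr::pmap_dfr(pairs, function(gene, cancer_type) {
    samples <- cl$sample_id[cl$cancer_type == cancer_type]
    n <- length(samples)
    mut_samples <- unique(cohort$mutations$sample_id[
      cohort$mutations$gene == gene &
        cohort$mutations$sample_id %in% samples
    ])
    cnd_samples <- unique(cohort$cnv$sample_id[
      cohort$cnv$gene == gene & cohort$cnv$sample_id %in% samples &
        classify_cnv(cohort$cnv$gistic, "deep_only") == "CND"
    ])
    homdel_samples <- unique(homdel$sample_id[
      homdel$gene == gene & homdel$sample_id %in% samples
    ])
    f_co <- length(intersect(mut_samples, cnd_samples)) / n
    f_hd <- length(homdel_samples) / n
    tibble::tibble(
      gene = gene, cancer_type = cancer_type,
      freq_mut_cnd = f_co, freq_homdel = f_hd,
      predominant = dplyr::case_when(
        f_co > f_hd ~ "mut_cnd",
        f_hd > f_co ~ "homdel",
        TRUE ~ "tie"
      )
    )
  })
}
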