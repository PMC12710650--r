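#' Read a somatic mutation table
#'
#' Reads a tab-separated mutation table into the per-mutation tibble used by
#' every downstream stage. One row is one somatic mutation observed in one
#' sample, with DNA (and optionally RNA) alt/ref read counts and the sample's
#' gene-level GISTIC copy-number call at the mutated locus.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Optional named character vector mapping the standard column
#'   names (`sample_id`, `gene`, `protein_change`, `mutation_class`,
#'   `is_functional_driver`, `dna_alt`, `dna_ref`, `rna_alt`, `rna_ref`,
#'   `gistic`) to the names used in the file. Unmapped standard names are
#'   looked up verbatim.
#'
#' @return A tibble with the standard mutation columns. Missing RNA counts are
#'   `NA` and treated as absent downstream.
#'
#' @details Required columns are `sample_id`, `gene`, `mutation_class`,
#'   `dna_alt`, `dna_ref` and `gistic`; a missing required column is a schema
#'   error. Negative read counts or GISTIC values outside `{-2,...,2}` raise a
#'   validation error naming the offending rows.
#'
#' @export
read_mutation_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  std <- c("sample_id", "gene", "protein_change", "mutation_class",
           "is_functional_driver", "dna_alt", "dna_ref",
           "rna_alt", "rna_ref", "gistic")
  map <- setNames(std, std)
  if (!is.null(schema)) map[names(schema)] <- unname(schema)

  required <- c("sample_id", "gene", "mutation_class", "dna_alt", "dna_ref",
                "gistic")
  missing_req <- required[!map[required] %in% names(raw)]
  if (length(missing_req) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(map[missing_req], collapse = ", "))
  }

  out <- tibble::tibble(
    sample_id = as.character(raw[[map["sample_id"]]]),
    gene = toupper(as.character(raw[[map["gene"]]])),
    protein_change = if (map["protein_change"] %in% names(raw))
      as.character(raw[[map["protein_change"]]]) else NA_character_,
    mutation_class = as.character(raw[[map["mutation_class"]]]),
    is_functional_driver = if (map["is_functional_driver"] %in% names(raw))
      as.logical(raw[[map["is_functional_driver"]]]) else NA,
    dna_alt = as.integer(raw[[map["dna_alt"]]]),
    dna_ref = as.integer(raw[[map["dna_ref"]]]),
    rna_alt = if (map["rna_alt"] %in% names(raw))
      as.integer(raw[[map["rna_alt"]]]) else NA_integer_,
    rna_ref = if (map["rna_ref"] %in% names(raw))
      as.integer(raw[[map["rna_ref"]]]) else NA_integer_,
    gistic = as.integer(raw[[map["gistic"]]])
  )
  validate_mutations(out)
  out
}

validate_mutations <- function(muts) {
  bad_counts <- which(
    (!is.na(muts$dna_alt) & muts$dna_alt < 0) |
      (!is.na(muts$dna_ref) & muts$dna_ref < 0) |
      (!is.na(muts$rna_alt) & muts$rna_alt < 0) |
      (!is.na(muts$rna_ref) & muts$rna_ref < 0)
  )
  if (length(bad_counts) > 0) {
    stop("negative read counts in mutation row(s): ",
         paste(head(bad_counts, 10), collapse = ", "))
  }
  bad_gistic <- which(!is.na(muts$gistic) & !(muts$gistic %in% -2:2))
  if (length(bad_gistic) > 0) {
    stop("GISTIC value outside {-2..2} in mutation row(s): ",
         paste(head(bad_gistic, 10), collapse = ", "))
  }
  invisible(muts)
}

#' Read a GISTIC-style gene-level copy-number matrix
#'
#' The file has genes as rows and samples as columns, with the first column
#' holding gene symbols and integer cells in `{-2,...,2}`. Returned in long
#' form with one row per non-neutral (sample, gene) call; neutral (0) cells
#' are implicit.
#'
#' @param path Path to the TSV matrix.
#' @return Tibble with columns `sample_id`, `gene`, `gistic`.
#' @export
read_gistic_matrix <- function(path) {
  if (!file.exists(path)) stop("GISTIC matrix not found: ", path)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_col <- names(wide)[1]
  long <- tidyr::pivot_longer(wide, -dplyr::all_of(gene_col),
                              names_to = "sample_id", values_to = "gistic")
  out <- tibble::tibble(
    sample_id = as.character(long$sample_id),
    gene = toupper(as.character(long[[gene_col]])),
    gistic = as.integer(long$gistic)
  )
  if (any(!is.na(out$gistic) & !(out$gistic %in% -2:2))) {
    stop("GISTIC matrix contains values outside {-2..2}")
  }
  dplyr::filter(out, !is.na(.data$gistic), .data$gistic != 0L)
}

#' Read a per-sample clinical/purity table
#'
#' @param path Path to a TSV keyed by `sample_id`, with columns
#'   `cancer_type`, `center`, `purity`, `ploidy`, `gender`,
#'   `age_at_diagnosis` and optionally `subtype`, `ethnicity`, `stage`.
#' @return Tibble of sample profiles.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  cl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "cancer_type", "center")
  missing_req <- setdiff(required, names(cl))
  if (length(missing_req) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  for (opt in c("purity", "ploidy", "age_at_diagnosis")) {
    if (!opt %in% names(cl)) cl[[opt]] <- NA_real_
  }
  for (opt in c("gender", "subtype", "ethnicity", "stage")) {
    if (!opt %in% names(cl)) cl[[opt]] <- NA_character_
  }
  cl <- tibble::as_tibble(cl)
  if (anyDuplicated(cl$sample_id)) {
    stop("duplicated sample_id in clinical table")
  }
  ok_purity <- is.na(cl$purity) | (cl$purity >= 0 & cl$purity <= 1)
  if (!all(ok_purity)) stop("purity outside [0,1] in clinical table")
  if (!all(is.na(cl$ploidy) | cl$ploidy > 0)) {
    stop("non-positive ploidy in clinical table")
  }
  cl
}

#' Read a gene x sample expression matrix (log2 scale)
#'
#' @param path TSV with genes as rows (first column = gene symbol) and
#'   samples as columns; values are on a log2 expression scale.
#' @return Long tibble with columns `sample_id`, `gene`, `expression`.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_col <- names(wide)[1]
  long <- tidyr::pivot_longer(wide, -dplyr::all_of(gene_col),
                              names_to = "sample_id", values_to = "expression")
  tibble::tibble(
    sample_id = as.character(long$sample_id),
    gene = toupper(as.character(long[[gene_col]])),
    expression = as.numeric(long$expression)
  )
}

#' Read a BED file of genomic intervals
#'
#' Coordinates are 0-based half-open throughout the package (BED convention).
#'
#' @param path BED file: chrom, start, end, label, and (for eccDNA fragment
#'   files) a fifth column carrying the sample id.
#' @param has_sample If `TRUE`, column 5 is read as `sample_id`.
#' @return Tibble with columns `chrom`, `start`, `end`, `label` and
#'   optionally `sample_id`.
#' @export
read_bed <- function(path, has_sample = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  n_col <- if (has_sample) 5L else 4L
  bed <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "label", "sample_id")[seq_len(n_col)],
    show_col_types = FALSE, progress = FALSE
  )
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  if (any(bed$start >= bed$end)) {
    stop("malformed interval(s) with start >= end in ", path)
  }
  tibble::as_tibble(bed)
}

#' Write a cohort to a directory of plain-text tables
#'
#' Writes `mutations.tsv`, `gistic.tsv` (genes x samples, neutral cells 0),
#' `clinical.tsv`, `expression.tsv` (genes x samples), `genes.bed`,
#' `eccdna.bed` and, when present, the truth tables of a simulated cohort.
#'
#' @param cohort A cohort list as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"),
                   progress = FALSE)

  samples <- cohort$clinical$sample_id
  genes <- sort(unique(c(cohort$cnv$gene, cohort$genes$label)))
  gw <- tidyr::pivot_wider(cohort$cnv,
                           id_cols = "gene", names_from = "sample_id",
                           values_from = "gistic", values_fill = 0L)
  # ensure every sample column and gene row is present, neutral-filled
  for (s in setdiff(samples, names(gw))) gw[[s]] <- 0L
  gw <- dplyr::full_join(tibble::tibble(gene = genes), gw, by = "gene")
  gw <- dplyr::mutate(gw, dplyr::across(-"gene", ~ tidyr::replace_na(.x, 0L)))
  readr::write_tsv(gw[, c("gene", samples)], file.path(dir, "gistic.tsv"),
                   progress = FALSE)

  if (!is.null(cohort$expression) && nrow(cohort$expression) > 0) {
    ew <- tidyr::pivot_wider(cohort$expression,
                             id_cols = "gene", names_from = "sample_id",
                             values_from = "expression")
    readr::write_tsv(ew, file.path(dir, "expression.tsv"), progress = FALSE)
  }
  if (!is.null(cohort$genes) && nrow(cohort$genes) > 0) {
    readr::write_tsv(cohort$genes[, c("chrom", "start", "end", "label")],
                     file.path(dir, "genes.bed"), col_names = FALSE,
                     progress = FALSE)
  }
  if (!is.null(cohort$eccdna) && nrow(cohort$eccdna) > 0) {
    readr::write_tsv(
      cohort$eccdna[, c("chrom", "start", "end", "label", "sample_id")],
      file.path(dir, "eccdna.bed"), col_names = FALSE, progress = FALSE
    )
  }
  if (!is.null(cohort$truth)) {
    for (nm in names(cohort$truth)) {
      readr::write_tsv(cohort$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       progress = FALSE)
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort tables.
#' @return A cohort list with elements `mutations`, `cnv`, `clinical`,
#'   `expression`, `genes`, `eccdna` and (if truth tables are present)
#'   `truth`.
#' @export
read_cohort <- function(dir) {
  cohort <- list(
    mutations = read_mutation_table(file.path(dir, "mutations.tsv")),
    cnv = read_gistic_matrix(file.path(dir, "gistic.tsv")),
    clinical = read_clinical_table(file.path(dir, "clinical.tsv"))
  )
  expr_path <- file.path(dir, "expression.tsv")
  cohort$expression <- if (file.exists(expr_path)) {
    read_expression_matrix(expr_path)
  } else {
    tibble::tibble(sample_id = character(), gene = character(),
                   expression = numeric())
  }
  genes_path <- file.path(dir, "genes.bed")
  if (file.exists(genes_path)) cohort$genes <- read_bed(genes_path)
  ecc_path <- file.path(dir, "eccdna.bed")
  cohort$eccdna <- if (file.exists(ecc_path)) {
    read_bed(ecc_path, has_sample = TRUE)
  } else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   label = character(), sample_id = character())
  }
  truth_files <- list.files(dir, pattern = "^truth_.*\\.tsv$")
  if (length(truth_files) > 0) {
    cohort$truth <- lapply(truth_files, function(f) {
      readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                      progress = FALSE)
    })
    names(cohort$truth) <- sub("^truth_(.*)\\.tsv$", "\\1", truth_files)
  }
  class(cohort) <- c("comut_cohort", "list")
  cohort
}

#' Check a cohort's schemas and invariants
#'
#' Collects violations of the package's data contracts: purity range, ploidy
#' positivity, unique sample ids, read-count non-negativity, GISTIC range,
#' interval well-formedness, and referential integrity between mutation rows
#' and the clinical table.
#'
#' @param cohort A cohort list (or a directory path, which is read first).
#' @return A tibble of issues with columns `table`, `check`, `detail`;
#'   zero rows means the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  issues <- list()
  add <- function(table, check, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      table = table, check = check, detail = detail
    )
  }
  cl <- cohort$clinical
  if (anyDuplicated(cl$sample_id)) {
    add("clinical", "unique_sample_id", "duplicated sample_id")
  }
  if (any(!is.na(cl$purity) & (cl$purity < 0 | cl$purity > 1))) {
    add("clinical", "purity_range", "purity outside [0,1]")
  }
  if (any(!is.na(cl$ploidy) & cl$ploidy <= 0)) {
    add("clinical", "ploidy_positive", "non-positive ploidy")
  }
  mu <- cohort$mutations
  cnt <- c(mu$dna_alt, mu$dna_ref, mu$rna_alt, mu$rna_ref)
  if (any(!is.na(cnt) & cnt < 0)) {
    add("mutations", "nonnegative_counts", "negative read counts")
  }
  if (any(!is.na(mu$gistic) & !(mu$gistic %in% -2:2))) {
    add("mutations", "gistic_range", "GISTIC outside {-2..2}")
  }
  orphan <- setdiff(mu$sample_id, cl$sample_id)
  if (length(orphan) > 0) {
    add("mutations", "sample_in_clinical",
        paste("samples missing from clinical:",
              paste(head(orphan, 5), collapse = ", ")))
  }
  if (any(!is.na(cohort$cnv$gistic) & !(cohort$cnv$gistic %in% -2:2))) {
    add("cnv", "gistic_range", "GISTIC outside {-2..2}")
  }
  for (tbl in c("genes", "eccdna")) {
    iv <- cohort[[tbl]]
    if (!is.null(iv) && nrow(iv) > 0 && any(iv$start >= iv$end)) {
      add(tbl, "interval_wellformed", "start >= end")
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(table = character(), check = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
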