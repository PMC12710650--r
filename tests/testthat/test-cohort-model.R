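test_that("a synthetic cohort round-trips through the on-disk table formats", {
  co <- small_cohort(seed = 7)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)

  expect_equal(as.data.frame(back$mutations), as.data.frame(co$mutations))
  expect_equal(as.data.frame(back$clinical), as.data.frame(co$clinical))
  sort_cnv <- function(x) {
    x <- x[order(x$sample_id, x$gene), ]
    rownames(x) <- NULL
    as.data.frame(x)
  }
  expect_equal(sort_cnv(back$cnv), sort_cnv(co$cnv))
  sort_expr <- function(x) {
    x <- x[order(x$sample_id, x$gene), c("sample_id", "gene", "expression")]
    rownames(x) <- NULL
    as.data.frame(x)
  }
  expect_equal(sort_expr(back$expression), sort_expr(co$expression))
  expect_equal(as.data.frame(back$genes), as.data.frame(co$genes))
  expect_equal(as.data.frame(back$eccdna),
               as.data.frame(co$eccdna[, names(back$eccdna)]))
  expect_equal(as.data.frame(back$truth$pairs),
               as.data.frame(co$truth$pairs))
  expect_equal(nrow(validate_cohort(back)), 0)
})

test_that("malformed mutation tables are rejected with named rows", {
  dir <- withr::local_tempdir()
  ok <- tibble::tibble(
    sample_id = c("S1", "S2", "S3"), gene = c("G01", "G01", "G02"),
    protein_change = "p.V600E", mutation_class = "missense",
    is_functional_driver = TRUE, dna_alt = c(5L, 3L, 8L),
    dna_ref = c(5L, 7L, 2L), rna_alt = NA_integer_, rna_ref = NA_integer_,
    gistic = c(0L, 2L, -1L)
  )
  f <- file.path(dir, "muts.tsv")
  readr::write_tsv(ok, f)
  expect_equal(nrow(read_mutation_table(f)), 3)

  bad_gistic <- ok
  bad_gistic$gistic[2] <- 3L
  readr::write_tsv(bad_gistic, f)
  expect_error(read_mutation_table(f), "GISTIC.*2")

  bad_count <- ok
  bad_count$dna_alt[3] <- -1L
  readr::write_tsv(bad_count, f)
  expect_error(read_mutation_table(f), "negative read counts.*3")

  readr::write_tsv(ok[, setdiff(names(ok), "gistic")], f)
  expect_error(read_mutation_table(f), "missing required column.*gistic")
})

test_that("driver filtering keeps truncations and functional missense only", {
  muts <- tibble::tibble(
    sample_id = paste0("S", 1:10),
    gene = c(rep("TP53", 6), rep("OTHER", 2), "KRAS", "KRAS"),
    protein_change = NA_character_,
    mutation_class = c("truncating", "missense", "missense", "other",
                       "truncating", "missense", "truncating", "missense",
                       "missense", "truncating"),
    is_functional_driver = c(NA, TRUE, FALSE, TRUE, TRUE, NA,
                             TRUE, TRUE, TRUE, FALSE),
    dna_alt = 5L, dna_ref = 5L, rna_alt = NA_integer_,
    rna_ref = NA_integer_, gistic = 0L
  )
  # hand-applied rule: driver gene AND (truncating OR functional missense)
  expect_message(
    kept <- filter_driver_mutations(muts, c("TP53", "KRAS")),
    "dropped"
  )
  expect_equal(kept$sample_id, c("S1", "S2", "S5", "S9", "S10"))
  expect_error(filter_driver_mutations(muts, character(0)), "empty driver")
})

test_that("CNV classification partitions every GISTIC code in both modes", {
  expect_equal(classify_cnv(-2:2, "deep_only"),
               c("CND", "neutral", "neutral", "neutral", "CNA"))
  expect_equal(classify_cnv(-2:2, "any"),
               c("CND", "CND", "neutral", "CNA", "CNA"))
  expect_error(classify_cnv(3L, "any"), "GISTIC")
  # exhaustive: every code maps to exactly one class in each mode
  for (mode in c("deep_only", "any")) {
    cls <- classify_cnv(-2:2, mode)
    expect_false(any(is.na(cls)))
    expect_true(all(cls %in% c("CNA", "CND", "neutral")))
  }
})

test_that("carrier groups label the four mutation/CNV combinations", {
  got <- label_carrier_group(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(as.character(got),
               c("none", "mutation_only", "cnv_only", "both"))
  expect_equal(levels(got), c("none", "mutation_only", "cnv_only", "both"))
})

test_that("purity adjustment follows the capped dilution model", {
  expect_equal(adjust_vaf_for_purity(0.3, 0.6), 0.5)
  expect_equal(adjust_vaf_for_purity(0.5, 1.0), 0.5)
  expect_equal(adjust_vaf_for_purity(0.8, 0.6), 1.0)
  v <- seq(0, 1, by = 0.05)
  expect_equal(adjust_vaf_for_purity(v, 1), v) # identity at full purity
  expect_true(all(diff(adjust_vaf_for_purity(v, 0.7)) >= 0)) # monotone
  expect_error(adjust_vaf_for_purity(0.5, 0), "purity")
})

test_that("alteration matrices binarize repeated events", {
  ev <- tibble::tibble(sample_id = c("S1", "S1", "S2"),
                       gene = c("G01", "G01", "G02"))
  m <- build_alteration_matrix(ev, samples = c("S1", "S2", "S3"),
                               genes = c("G01", "G02"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(m), 2)
  expect_equal(m["S1", "G01"], 1L)
  expect_equal(m["S3", ], c(G01 = 0L, G02 = 0L))
})
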