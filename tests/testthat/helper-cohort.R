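# Shared fixtures and independent oracles, all built in code.

small_cohort <- function(seed = 42, n_samples = 60, n_genes = 12, ...) {
  suppressWarnings(simulate_cohort(sim_config(
    n_samples = n_samples, n_genes = n_genes, seed = seed, ...
  )))
}

# independent step-up BH oracle (literal definition, no p.adjust)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force two-sided exact binomial p by literal enumeration
binom_two_sided_oracle <- function(alt, total, p0) {
  obs <- dbinom(alt, total, p0)
  s <- 0
  for (k in 0:total) {
    pk <- dbinom(k, total, p0)
    if (pk <= obs * (1 + 1e-7)) s <- s + pk
  }
  min(1, s)
}

# brute-force per-gene co-occurrence recount by explicit sample loops
cooc_oracle <- function(mut, cnv) {
  genes <- colnames(mut)
  out <- data.frame(gene = genes, n_mut = 0L, n_co = 0L)
  for (j in seq_along(genes)) {
    for (i in seq_len(nrow(mut))) {
      if (mut[i, j] == 1) {
        out$n_mut[j] <- out$n_mut[j] + 1L
        if (cnv[i, j] == 1) out$n_co[j] <- out$n_co[j] + 1L
      }
    }
  }
  out$proportion <- ifelse(out$n_mut > 0, out$n_co / out$n_mut, NA_real_)
  out
}

random_binary_matrix <- function(nr, nc, p = 0.2) {
  m <- matrix(rbinom(nr * nc, 1L, p), nr, nc,
              dimnames = list(paste0("S", seq_len(nr)),
                              paste0("G", seq_len(nc))))
  storage.mode(m) <- "integer"
  m
}

# hand-built background table with a distinct rate per aggregation level
fake_background <- function(present = c(gcs = TRUE, sample = TRUE,
                                        gc = TRUE, cancer = TRUE)) {
  mk <- function(df, on) if (on) df else df[0, ]
  structure(list(
    level = "DNA",
    gene_cancer_sample = mk(tibble::tibble(
      gene = "G01", cancer_type = "LUAD", sample_id = "S1",
      alt_sum = 1L, total_sum = 10L, p0 = 0.1
    ), present[["gcs"]]),
    sample = mk(tibble::tibble(
      sample_id = "S1", alt_sum = 2L, total_sum = 10L, p0 = 0.2
    ), present[["sample"]]),
    gene_cancer = mk(tibble::tibble(
      gene = "G01", cancer_type = "LUAD",
      alt_sum = 3L, total_sum = 10L, p0 = 0.3
    ), present[["gc"]]),
    cancer = mk(tibble::tibble(
      cancer_type = "LUAD", alt_sum = 4L, total_sum = 10L, p0 = 0.4
    ), present[["cancer"]])
  ), class = "background_table")
}
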