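# Build small synthetic methylation studies as on-disk TSV fixtures (written
# to tempfiles at test time) and as in-memory objects.

write_study_files <- function(beta, metadata,
                              dir = {d <- tempfile("study"); dir.create(d); d}) {
  beta_path <- file.path(dir, "beta.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  df <- data.frame(locus_id = rownames(beta), beta, check.names = FALSE)
  write.table(df, beta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(metadata, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(beta = beta_path, metadata = meta_path)
}

# A clean toy study: n_loci x (n_ctl + n_case) beta matrix, one age group per
# `ages` entry pattern.
toy_study <- function(n_loci = 3, n_ctl = 4, n_case = 4, seed = 42,
                      ages = NULL, qc = FALSE) {
  set.seed(seed)
  n <- n_ctl + n_case
  beta <- matrix(runif(n_loci * n, 0.2, 0.8), n_loci, n,
                 dimnames = list(paste0("cg", seq_len(n_loci)),
                                 paste0("s", seq_len(n))))
  md <- data.frame(sample_id = colnames(beta),
                   group = rep(c("control", "case"), c(n_ctl, n_case)),
                   age = if (is.null(ages)) rep(60, n) else ages,
                   stringsAsFactors = FALSE)
  if (qc) {
    md$bs_conversion <- 5000
    md$coverage <- 0.99
  }
  list(beta = beta, metadata = md)
}

# In-memory study generated from a simulation scenario: K age groups mapped
# to ages edges[k] + 2, `n_signal` loci carry a strong case mean shift.
simulated_study <- function(n_loci = 50, n_signal = 0, K = 3, n_per_arm = 15,
                            edges = c(50, 55, 60), seed = 7, shift = 0.3) {
  set.seed(seed)
  n <- K * 2 * n_per_arm
  ages <- rep(edges + 2, each = 2 * n_per_arm)
  group <- rep(rep(c("control", "case"), each = n_per_arm), K)
  beta <- matrix(runif(n_loci * n, 0.1, 0.6), n_loci, n)
  if (n_signal > 0)
    beta[seq_len(n_signal), group == "case"] <-
      pmin(beta[seq_len(n_signal), group == "case"] + shift, 1)
  dimnames(beta) <- list(sprintf("cg%04d", seq_len(n_loci)),
                         sprintf("s%03d", seq_len(n)))
  md <- data.frame(sample_id = colnames(beta), group = group, age = ages,
                   stringsAsFactors = FALSE)
  structure(list(beta = beta, metadata = md), class = "methylation_study")
}
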