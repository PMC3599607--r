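#' Load a beta-value matrix and sample metadata
#'
#' Reads a loci x samples beta-value table (first column = locus identifiers,
#' one column per sample) and a metadata table with at least `sample_id`,
#' `group` (`case`/`control`) and `age` columns. The sample sets of the two
#' files must match exactly; beta-values must lie in `[0, 1]` within 1e-9
#' (values inside the tolerance band are snapped to the boundary). Loci
#' containing missing beta-values are counted and flagged; testing later uses
#' per-stratum complete cases.
#'
#' @param beta_path,metadata_path TSV/CSV file paths.
#' @return object of class `methylation_study`: list with the numeric matrix
#'   `beta` (rownames = locus ids, columns ordered as the metadata) and the
#'   data frame `metadata`.
#' @export
load_study <- function(beta_path, metadata_path) {
  bt <- data.table::fread(beta_path, data.table = FALSE)
  md <- data.table::fread(metadata_path, data.table = FALSE)
  need <- c("sample_id", "group", "age")
  if (!all(need %in% names(md)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(md$group %in% c("case", "control")))
    stop("`group` must be 'case' or 'control'", call. = FALSE)
  if (!is.numeric(md$age) || any(!is.finite(md$age)))
    stop("`age` must be finite numeric", call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)

  locus_id <- as.character(bt[[1L]])
  mat <- as.matrix(bt[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- locus_id

  extra <- setdiff(colnames(mat), md$sample_id)
  missing <- setdiff(md$sample_id, colnames(mat))
  if (length(extra) || length(missing))
    stop("sample sets differ between matrix and metadata",
         if (length(missing)) paste0("; absent from matrix: ",
                                     paste(head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; absent from metadata: ",
                                   paste(head(extra, 5), collapse = ", ")),
         call. = FALSE)
  mat <- mat[, md$sample_id, drop = FALSE]

  bad <- which(!is.na(mat) & (mat < -1e-9 | mat > 1 + 1e-9), arr.ind = TRUE)
  if (nrow(bad)) {
    b1 <- bad[1L, ]
    stop(sprintf("beta-value out of [0,1]: locus '%s', sample '%s' (%g)%s",
                 rownames(mat)[b1[1L]], colnames(mat)[b1[2L]],
                 mat[b1[1L], b1[2L]],
                 if (nrow(bad) > 1L) sprintf(" and %d more", nrow(bad) - 1L)
                 else ""),
         call. = FALSE)
  }
  mat[!is.na(mat)] <- pmin(pmax(mat[!is.na(mat)], 0), 1)

  n_na <- sum(rowSums(is.na(mat)) > 0L)
  if (n_na > 0L)
    message(n_na, " of ", nrow(mat),
            " loci contain missing beta-values; tests use per-stratum complete cases")
  structure(list(beta = mat, metadata = md), class = "methylation_study")
}

#' @export
print.methylation_study <- function(x, ...) {
  cat("Methylation study:", nrow(x$beta), "loci x", ncol(x$beta), "samples (",
      sum(x$metadata$group == "control"), "control,",
      sum(x$metadata$group == "case"), "case )\n")
  if (!is.null(x$metadata$age_group))
    cat("  age groups:",
        paste(sort(unique(x$metadata$age_group)), collapse = ", "), "\n")
  invisible(x)
}

#' Default sample quality-control thresholds
#'
#' Bisulfite conversion efficiency at least 4000 and array coverage rate at
#' least 95%.
#'
#' @return named numeric vector of per-field minimum thresholds.
#' @export
default_qc_rules <- function() c(bs_conversion = 4000, coverage = 0.95)

parse_threshold <- function(x) {
  if (is.character(x)) {
    if (grepl("%$", x)) return(as.numeric(sub("%$", "", x)) / 100)
    return(as.numeric(x))
  }
  as.numeric(x)
}

#' Remove samples failing quality-control thresholds
#'
#' Drops every sample whose metadata value falls below any rule's minimum;
#' removal counts per arm are messaged and attached as the `"qc_removed"`
#' attribute. Thresholds may be given as numbers or percent strings
#' (`"95%"`). An empty rule set is the identity.
#'
#' @param study a `methylation_study`.
#' @param rules named vector/list of per-field minima; names must be metadata
#'   columns.
#' @return the filtered study.
#' @export
qc_filter <- function(study, rules = default_qc_rules()) {
  stopifnot(inherits(study, "methylation_study"))
  if (length(rules) == 0L) return(study)
  md <- study$metadata
  absent <- setdiff(names(rules), names(md))
  if (length(absent))
    stop("QC rule refers to missing metadata field(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  keep <- rep(TRUE, nrow(md))
  for (f in names(rules))
    keep <- keep & (md[[f]] >= parse_threshold(rules[[f]]))
  removed <- table(factor(md$group[!keep], levels = c("control", "case")))
  message("QC removed ", sum(!keep), " samples (",
          removed[["control"]], " control, ", removed[["case"]], " case)")
  out <- structure(list(beta = study$beta[, keep, drop = FALSE],
                        metadata = md[keep, , drop = FALSE]),
                   class = "methylation_study")
  attr(out, "qc_removed") <- removed
  out
}

#' Assign samples to age groups
#'
#' Bins ages by left-closed, right-open intervals at `edges`, the last bin
#' open-ended (so with edges `c(50, 55, ...)` an age of exactly 55 falls in
#' the second bin). Samples younger than the first edge are dropped with a
#' message, as are samples in `max_age_arm` older than `max_age` when set.
#'
#' @param study a `methylation_study`.
#' @param edges strictly ascending age boundaries.
#' @param max_age optional age cap.
#' @param max_age_arm arm(s) the cap applies to (default `"case"`).
#' @return the study with an `age_group` metadata column (bin index 1..K).
#' @export
assign_age_groups <- function(study, edges = c(50, 55, 60, 65, 70, 75),
                              max_age = NULL,
                              max_age_arm = c("case", "control", "both")) {
  stopifnot(inherits(study, "methylation_study"))
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) stop("`edges` must be strictly ascending",
                                  call. = FALSE)
  max_age_arm <- match.arg(max_age_arm)
  md <- study$metadata
  keep <- rep(TRUE, nrow(md))
  below <- md$age < edges[1L]
  if (any(below)) {
    message("dropping ", sum(below), " samples below age ", edges[1L])
    keep <- keep & !below
  }
  if (!is.null(max_age)) {
    arm_sel <- if (max_age_arm == "both") rep(TRUE, nrow(md))
               else md$group == max_age_arm
    over <- arm_sel & md$age > max_age
    if (any(over))
      message("dropping ", sum(over), " ", max_age_arm,
              " samples above age ", max_age)
    keep <- keep & !over
  }
  md <- md[keep, , drop = FALSE]
  md$age_group <- findInterval(md$age, edges)
  structure(list(beta = study$beta[, keep, drop = FALSE], metadata = md,
                 age_edges = edges),
            class = "methylation_study")
}

# Per-locus strata for a stratified study; complete-case within stratum.
locus_strata <- function(x, md, min_per_arm = 2L) {
  ks <- sort(unique(md$age_group))
  strata <- lapply(ks, function(k) {
    sel <- md$age_group == k
    list(control = x[sel & md$group == "control" & !is.na(x)],
         case = x[sel & md$group == "case" & !is.na(x)])
  })
  usable <- vapply(strata, function(s)
    length(s$control) >= min_per_arm && length(s$case) >= min_per_arm,
    logical(1))
  list(strata = strata[usable], n_dropped = sum(!usable))
}

#' Locus-wise combined testing of a stratified study
#'
#' For every locus, builds per-age-group two-sample data (complete cases
#' within each stratum), drops strata with fewer than `min_per_arm`
#' observations in either arm, and computes the requested methods' combined
#' p-values. `"regression"` pools the usable strata into one age-adjusted
#' design. Deterministic given the inputs (and `seed` under permutation
#' calibration).
#'
#' @param study a `methylation_study` with assigned age groups.
#' @param methods subset of `"bws"`, `"t"`, `"wilcoxon"`, `"regression"`.
#' @param calibration `"approx"` or `"permutation"` (combined methods).
#' @param n_perm,seed permutation settings for `calibration =
#'   "permutation"`.
#' @param fit null-tail fit for the BWS stratum test.
#' @param min_per_arm minimum per-arm stratum size.
#' @return data frame with one row per locus: `locus_id`, `k_used`,
#'   `n_used`, one `p_<method>` column per method, and a `flags` column
#'   (`""`, `missing_values`, `dropped_strata:<n>`, `no_usable_strata`).
#' @export
run_locuswise <- function(study, methods = c("bws", "t", "wilcoxon", "regression"),
                          calibration = c("approx", "permutation"),
                          n_perm = 2000L, seed = NULL, fit = bws_null_fit(),
                          min_per_arm = 2L) {
  stopifnot(inherits(study, "methylation_study"))
  calibration <- match.arg(calibration)
  methods <- match.arg(methods, c("bws", "t", "wilcoxon", "regression"),
                       several.ok = TRUE)
  md <- study$metadata
  if (is.null(md$age_group))
    stop("assign age groups first (assign_age_groups())", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  combined_p <- function(strata, m) {
    if (calibration == "approx")
      locus_p_value(strata, m, fit)
    else
      combined_test(strata, method = m, calibration = "permutation",
                    n_perm = n_perm, fit = fit)$p_value
  }

  n_loci <- nrow(study$beta)
  pmat <- matrix(NA_real_, n_loci, length(methods),
                 dimnames = list(NULL, paste0("p_", methods)))
  k_used <- integer(n_loci)
  n_used <- integer(n_loci)
  flags <- character(n_loci)
  for (i in seq_len(n_loci)) {
    x <- study$beta[i, ]
    fl <- character(0)
    if (anyNA(x)) fl <- "missing_values"
    ls <- locus_strata(x, md, min_per_arm)
    if (ls$n_dropped > 0L) fl <- c(fl, paste0("dropped_strata:", ls$n_dropped))
    k_used[i] <- length(ls$strata)
    n_used[i] <- sum(vapply(ls$strata, function(s)
      length(s$control) + length(s$case), integer(1)))
    if (k_used[i] == 0L) {
      flags[i] <- paste(c(fl, "no_usable_strata"), collapse = ";")
      next
    }
    for (m in methods) {
      pmat[i, paste0("p_", m)] <- if (m == "regression") {
        tryCatch(locus_p_value(ls$strata, "regression"),
                 error = function(e) NA_real_)
      } else combined_p(ls$strata, m)
    }
    flags[i] <- paste(fl, collapse = ";")
  }
  cbind(data.frame(locus_id = rownames(study$beta), k_used = k_used,
                   n_used = n_used, stringsAsFactors = FALSE),
        as.data.frame(pmat), data.frame(flags = flags, stringsAsFactors = FALSE))
}

#' Count significant loci per method and pairwise overlaps
#'
#' For each cutoff, counts the loci below the cutoff for every method present
#' in `results`, and the overlap (loci below the cutoff in both) between the
#' `reference` method and each other method.
#'
#' @param results output of [run_locuswise()].
#' @param cutoffs significance cutoffs.
#' @param reference method whose overlaps are reported.
#' @return long data frame: `cutoff`, `method`, `n_significant`,
#'   `n_overlap_reference` (`NA` for the reference row itself).
#' @export
count_significant <- function(results, cutoffs = c(1e-3, 1e-4, 1e-5, 1e-6),
                              reference = "bws") {
  pcols <- grep("^p_", names(results), value = TRUE)
  if (length(pcols) == 0L) stop("no p_<method> columns in `results`",
                                call. = FALSE)
  methods <- sub("^p_", "", pcols)
  ref_col <- paste0("p_", reference)
  out <- do.call(rbind, lapply(cutoffs, function(ct) {
    sig <- lapply(pcols, function(pc) !is.na(results[[pc]]) & results[[pc]] < ct)
    names(sig) <- methods
    data.frame(cutoff = ct, method = methods,
               n_significant = vapply(sig, sum, integer(1)),
               n_overlap_reference = if (ref_col %in% pcols)
                 vapply(methods, function(m)
                   if (m == reference) NA_integer_
                   else sum(sig[[m]] & sig[[reference]]), integer(1))
               else NA_integer_,
               row.names = NULL)
  }))
  out
}

#' Pseudo case-control split of one arm
#'
#' Within each age bin, randomly halves the chosen arm's samples (odd counts
#' give the extra sample to the pseudo-control side), relabels the halves as
#' `control`/`case`, and discards the other arm. Applying the combined test
#' to the result probes the null behaviour of the method on real data, since
#' both pseudo-arms come from the same population.
#'
#' @param study a `methylation_study` with assigned age groups.
#' @param arm arm to split (default `"control"`).
#' @param seed optional integer seed.
#' @return a new `methylation_study` containing only the relabeled samples.
#' @export
pseudo_split <- function(study, arm = c("control", "case"), seed = NULL) {
  stopifnot(inherits(study, "methylation_study"))
  arm <- match.arg(arm)
  md <- study$metadata
  if (is.null(md$age_group))
    stop("assign age groups first (assign_age_groups())", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sel <- md$group == arm
  md <- md[sel, , drop = FALSE]
  new_group <- character(nrow(md))
  for (k in sort(unique(md$age_group))) {
    idx <- which(md$age_group == k)
    if (length(idx) < 4L)
      stop("age group ", k, " has fewer than 4 ", arm,
           " samples; cannot split", call. = FALSE)
    shuffled <- sample(idx)
    n_ctl <- ceiling(length(idx) / 2)
    new_group[shuffled[seq_len(n_ctl)]] <- "control"
    new_group[shuffled[-seq_len(n_ctl)]] <- "case"
  }
  md$group <- new_group
  structure(list(beta = study$beta[, sel, drop = FALSE], metadata = md,
                 age_edges = study$age_edges),
            class = "methylation_study")
}

#' Write locus-wise results as a TSV with stable formatting
#'
#' p-value columns are rendered in scientific notation with 6 significant
#' digits so repeated runs produce byte-identical files.
#'
#' @param results output of [run_locuswise()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_locus_results <- function(results, path) {
  out <- results
  for (pc in grep("^p_", names(out), value = TRUE))
    out[[pc]] <- ifelse(is.na(out[[pc]]), "NA",
                        formatC(out[[pc]], digits = 6, format = "e"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
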