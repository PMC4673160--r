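#' Construct a Ct table
#'
#' Long-format table of threshold-cycle values, one row per technical
#' replicate of a (sample, assay) reaction. Assay roles distinguish the
#' target gene, reference (housekeeping) genes, and the internal control of
#' single-tube co-amplification assays. Replicate pairs whose Ct spread
#' exceeds the concordance window are flagged (not dropped).
#'
#' @param df Data frame with columns `sample`, `assay`, `role`
#'   (`target`/`reference`/`internal_control`), `replicate`, `ct`.
#' @param concordance_window Maximum tolerated within-(sample, assay) Ct
#'   range in cycles before flagging (default 1.0).
#' @return A `ct_table` data frame with a `discordant` attribute listing
#'   flagged (sample, assay) pairs.
#' @export
ct_table <- function(df, concordance_window = 1.0) {
  required <- c("sample", "assay", "role", "replicate", "ct")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(df$role %in% c("target", "reference", "internal_control")))
    stop("assay role must be target, reference or internal_control",
         call. = FALSE)
  df$ct <- as.numeric(df$ct)
  if (anyNA(df$ct) || any(df$ct <= 0))
    stop("all Ct values must be positive numbers", call. = FALSE)
  spread <- stats::aggregate(ct ~ sample + assay, df,
                             function(x) diff(range(x)))
  bad <- spread[spread$ct > concordance_window, c("sample", "assay")]
  if (nrow(bad))
    warning(nrow(bad), " (sample, assay) replicate set(s) exceed the ",
            concordance_window, "-cycle concordance window")
  structure(df[required], discordant = bad,
            class = c("ct_table", "data.frame"))
}

## replicate-averaged Ct for one assay in each sample; errors if absent
mean_ct <- function(ct, assay, samples) {
  vapply(samples, function(s) {
    v <- ct$ct[ct$sample == s & ct$assay == assay]
    if (!length(v))
      stop("assay ", assay, " not measured in sample ", s, call. = FALSE)
    mean(v)
  }, numeric(1))
}

#' Relative quantification by 2^-ddCt with a reference-gene index
#'
#' Replicate Ct values are averaged per (sample, assay). The reference
#' index is the arithmetic mean of the reference-gene Ct values (the Ct
#' analogue of a geometric mean of linear quantities), following the
#' three-gene index GAPDH/ACTB/RPLP0. Then per sample
#' dCt = Ct_target - index, ddCt = dCt - mean(dCt over the calibrator
#' samples), fold = 2^-ddCt. Amplification efficiency is fixed at 2 per
#' cycle. The geometric mean fold over the calibrator set is exactly 1.
#'
#' @param ct A [ct_table()].
#' @param target Target assay id.
#' @param references Character vector of reference assay ids.
#' @param calibrator Character vector of calibrator sample ids.
#' @return A `fold_change` data frame: `sample`, `ct_target`,
#'   `reference_index_ct`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @examples
#' ct <- ct_table(data.frame(
#'   sample = "s1", assay = c("SPP1", "GAPDH", "ACTB", "RPLP0"),
#'   role = c("target", "reference", "reference", "reference"),
#'   replicate = 1L, ct = c(25, 20, 21, 22)))
#' ddct_fold_change(ct, "SPP1", c("GAPDH", "ACTB", "RPLP0"), "s1")
#' @export
ddct_fold_change <- function(ct, target, references, calibrator) {
  if (!length(calibrator)) stop("calibrator set is empty", call. = FALSE)
  samples <- unique(ct$sample)
  missing_cal <- setdiff(calibrator, samples)
  if (length(missing_cal))
    stop("calibrator sample(s) absent from Ct table: ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  ct_t <- mean_ct(ct, target, samples)
  ref_mat <- matrix(vapply(references, function(a) mean_ct(ct, a, samples),
                           numeric(length(samples))),
                    nrow = length(samples))
  ref_idx <- stats::setNames(rowMeans(ref_mat), samples)
  d_ct <- ct_t - ref_idx
  dd_ct <- d_ct - mean(d_ct[match(calibrator, samples)])
  structure(data.frame(sample = samples,
                       ct_target = unname(ct_t),
                       reference_index_ct = unname(ref_idx),
                       delta_ct = unname(d_ct),
                       delta_delta_ct = unname(dd_ct),
                       fold = unname(2^(-dd_ct))),
            class = c("fold_change", "data.frame"))
}

#' Call tumor overexpression by the "2-fold plus one SD" rule
#'
#' The threshold is derived from the fold changes of the reference classes
#' (by default Normal and Barrett's metaplasia combined): with m and s the
#' mean and sample standard deviation (n-1 denominator) of the reference
#' folds, a sample is called overexpressing when its fold strictly exceeds
#' T = 2 m + s. An alternative reading of the rule — fold > 2 and
#' fold > m + s — is available via `rule = "both"`.
#'
#' @param folds A [ddct_fold_change()] result.
#' @param labels Data frame with columns `sample`, `class`.
#' @param reference_classes Classes forming the reference group.
#' @param rule `"2m_plus_s"` (default, T = 2 m + s) or `"both"`.
#' @return An `overexpression_calls` data frame: `sample`, `class`, `fold`,
#'   `threshold`, `called`, plus attributes `reference_mean`,
#'   `reference_sd`.
#' @export
call_overexpression <- function(folds, labels,
                                reference_classes = c("Normal", "BE"),
                                rule = c("2m_plus_s", "both")) {
  rule <- match.arg(rule)
  df <- merge(folds, labels, by = "sample", sort = FALSE)
  ref <- df$fold[df$class %in% reference_classes]
  if (length(ref) < 2L)
    stop("need at least 2 reference-class samples to form a threshold",
         call. = FALSE)
  m <- mean(ref); s <- stats::sd(ref)
  if (rule == "2m_plus_s") {
    threshold <- 2 * m + s
    called <- df$fold > threshold
  } else {
    threshold <- pmax(2, m + s)
    called <- df$fold > 2 & df$fold > m + s
  }
  structure(data.frame(sample = df$sample, class = df$class, fold = df$fold,
                       threshold = threshold, called = called),
            reference_mean = m, reference_sd = s,
            class = c("overexpression_calls", "data.frame"))
}

#' Copy-number ratio from single-tube co-amplification
#'
#' For each matched tumor/normal pair, the target gene and an internal
#' control gene are measured in both members;
#' ratio = 2^-\[(Ct_t,target - Ct_t,control) - (Ct_n,target - Ct_n,control)\].
#' Status bounds (gain at >= 1.5, loss at <= 0.67 by default, "unchanged"
#' between) are analysis conveniences, not biology.
#'
#' @param ct A [ct_table()].
#' @param target,internal_control Assay ids.
#' @param pairs Data frame with columns `tumor`, `normal` (sample ids).
#' @param gain_bound,loss_bound Ratio bounds for status calls.
#' @return Data frame: `tumor`, `normal`, `ratio`, `status`.
#' @export
copy_number_ratio <- function(ct, target, internal_control, pairs,
                              gain_bound = 1.5, loss_bound = 0.67) {
  samples <- unique(c(pairs$tumor, pairs$normal))
  missing <- setdiff(samples, unique(ct$sample))
  if (length(missing))
    stop("pair member(s) absent from Ct table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ct_t <- mean_ct(ct, target, samples)
  ct_c <- mean_ct(ct, internal_control, samples)
  d <- ct_t - ct_c
  ratio <- 2^(-(d[pairs$tumor] - d[pairs$normal]))
  status <- ifelse(ratio >= gain_bound, "gain",
                   ifelse(ratio <= loss_bound, "loss", "unchanged"))
  data.frame(tumor = pairs$tumor, normal = pairs$normal,
             ratio = unname(ratio), status = unname(status))
}

#' Stage-wise expression comparison across histology classes
#'
#' Per-class summaries of fold change plus Welch two-sample t-tests of each
#' non-reference class against the pooled reference classes and between
#' every pair of classes. Tests are run on log2 fold values by default
#' (fold changes are log-normal-ish; the log scale symmetrizes them).
#' Classes with fewer than 2 samples are summarized but flagged and
#' excluded from testing.
#'
#' @param folds A [ddct_fold_change()] result.
#' @param labels Data frame with columns `sample`, `class`.
#' @param reference_classes Classes pooled into the comparison baseline.
#' @param log2_scale Test on log2(fold) (default TRUE) or linear fold.
#' @return List with `summary` (class, n, mean, sd, degenerate flag) and
#'   `tests` (class_a, class_b, p_value; `class_b == "<reference>"` rows
#'   are class-vs-pooled-reference tests).
#' @export
compare_classes <- function(folds, labels,
                            reference_classes = c("Normal", "BE"),
                            log2_scale = TRUE) {
  df <- merge(folds, labels, by = "sample", sort = FALSE)
  df$y <- if (log2_scale) log2(df$fold) else df$fold
  classes <- unique(df$class)
  summ <- do.call(rbind, lapply(classes, function(cl) {
    y <- df$y[df$class == cl]
    data.frame(class = cl, n = length(y), mean = mean(y),
               sd = if (length(y) > 1) stats::sd(y) else NA_real_,
               degenerate = length(y) < 2L)
  }))
  if (sum(!summ$degenerate) < 2L)
    stop("need at least 2 classes with >= 2 samples each", call. = FALSE)
  ok <- summ$class[!summ$degenerate]
  welch_p <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }
  ref_y <- df$y[df$class %in% reference_classes]
  tests <- list()
  if (length(ref_y) >= 2L) {
    for (cl in setdiff(ok, reference_classes))
      tests[[length(tests) + 1L]] <- data.frame(
        class_a = cl, class_b = "<reference>",
        p_value = welch_p(df$y[df$class == cl], ref_y))
  }
  if (length(ok) >= 2L) {
    cmb <- utils::combn(ok, 2)
    for (j in seq_len(ncol(cmb)))
      tests[[length(tests) + 1L]] <- data.frame(
        class_a = cmb[1, j], class_b = cmb[2, j],
        p_value = welch_p(df$y[df$class == cmb[1, j]],
                          df$y[df$class == cmb[2, j]]))
  }
  list(summary = summ, tests = do.call(rbind, tests))
}
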