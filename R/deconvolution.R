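#' Construct an exon-level expression matrix
#'
#' Container for summarized probe-set expression on the log2 scale with a
#' probe-set-to-exon map. Missing values are rejected: imputation, if any,
#' must happen explicitly upstream.
#'
#' @param values Numeric matrix, samples x probe sets, log2 units, with
#'   sample ids as rownames and probe-set ids as colnames.
#' @param probe_to_exon Named integer vector mapping every probe-set id to
#'   an exon ordinal.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, probe_to_exon) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need sample rownames and probe-set colnames",
         call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values; impute or drop them ",
         "explicitly before loading", call. = FALSE)
  unmapped <- setdiff(colnames(values), names(probe_to_exon))
  if (length(unmapped))
    stop("probe set(s) without exon mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  structure(list(values = values,
                 probe_to_exon = stats::setNames(
                   as.integer(probe_to_exon[colnames(values)]),
                   colnames(values))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Exon-level expression matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " probe sets (log2), exons ",
      paste(sort(unique(x$probe_to_exon)), collapse = ","), "\n", sep = "")
  invisible(x)
}

## Mean linear-scale (2^log2) signal per exon, averaging probe sets that
## map to the same exon.
exon_linear_signal <- function(X, exon_ids) {
  n <- nrow(X$values)
  out <- vapply(exon_ids, function(e) {
    ps <- names(X$probe_to_exon)[X$probe_to_exon == e]
    if (!length(ps))
      stop("no probe set maps to exon ", e, call. = FALSE)
    rowMeans(2^X$values[, ps, drop = FALSE])
  }, numeric(n))
  matrix(out, nrow = n, dimnames = list(rownames(X$values), exon_ids))
}

#' Select common-exon probe sets as the total-expression proxy
#'
#' Candidate probe sets are those mapping to common exons (exons contained
#' in every isoform, i.e. inclusion frequency equal to the number of
#' isoforms); any of them measures total gene output. Each candidate gets a
#' deviation score: the cross-sample standard deviation of its log2 signal
#' after centering each sample at the median of all common-exon probe sets
#' (robust to sample-level expression differences, so the score captures
#' probe-level inconsistency only). The `k` lowest-scoring probe sets are
#' selected (ties broken by input probe-set order) and the per-sample total
#' is their mean linear-scale (2^log2) signal.
#'
#' @param X An [expression_matrix()].
#' @param M An [build_incidence()] matrix.
#' @param k Number of probe sets to select (default 3, as in the
#'   three-probe-set total used on exon arrays).
#' @return A `total_proxy` list: `selected_probesets`, `total` (per-sample
#'   linear-scale values), `deviation_scores` (all candidates).
#' @export
select_total_proxy <- function(X, M, k = 3L) {
  common_exons <- attr(M, "exon_ids")[attr(M, "frequency") == nrow(M)]
  cand <- names(X$probe_to_exon)[X$probe_to_exon %in% common_exons]
  if (!length(cand))
    stop("no probe sets map to common exons; cannot form a total proxy",
         call. = FALSE)
  V <- X$values[, cand, drop = FALSE]
  centered <- V - apply(V, 1, stats::median)
  scores <- apply(centered, 2, stats::sd)
  if (k > length(cand)) {
    warning("k = ", k, " exceeds the ", length(cand),
            " available common-exon probe sets; selecting all")
    k <- length(cand)
  }
  sel <- cand[order(scores, seq_along(cand))][seq_len(k)]
  structure(list(selected_probesets = sel,
                 total = rowMeans(2^X$values[, sel, drop = FALSE]),
                 deviation_scores = scores),
            class = "total_proxy")
}

#' @export
print.total_proxy <- function(x, ...) {
  cat("Total-expression proxy from probe sets: ",
      paste(x$selected_probesets, collapse = ", "), "\n", sep = "")
  invisible(x)
}

new_group_estimate <- function(label, coef, raw) {
  structure(list(group_label = label,
                 coefficients = coef,
                 abundances = pmax(raw, 0),
                 clipped = raw < 0),
            class = "group_estimate")
}

#' @export
print.group_estimate <- function(x, ...) {
  cat("Group ", x$group_label, ": ", length(x$abundances), " samples, ",
      sum(x$clipped), " clipped\n", sep = "")
  invisible(x)
}

## Order the non-common design patterns into a nested subtraction chain,
## or return NULL if the design is not triangular.
subtraction_chain <- function(A) {
  sub <- A[rowSums(A) < ncol(A), , drop = FALSE]
  if (!nrow(sub)) return(list())
  sub <- sub[order(rowSums(sub)), , drop = FALSE]
  for (i in seq_len(nrow(sub) - 1L)) {
    if (any(sub[i, ] > sub[i + 1L, ])) return(NULL)
    if (all(sub[i, ] == sub[i + 1L, ])) return(NULL)
  }
  lapply(seq_len(nrow(sub)), function(i)
    list(pattern = rownames(sub)[i], members = sub[i, ]))
}

#' Estimate identifiable isoform groups by successive subtraction
#'
#' Implements the subtraction scheme used on exon arrays lacking an exon 6
#' probe set: starting from the isoform-specific exon with the fewest
#' carriers, each identifiable group is obtained by subtracting the
#' previous exon signal from the next (linear scale), and the final
#' remainder group by subtracting the largest sub-total from the total
#' proxy. For the SPP1 design this yields OPN5 = S(exon4),
#' OPNa+OPNb = S(exon5) - S(exon4), OPNc+OPN4 = S(total) - S(exon5).
#' Signals are linearized (2^log2) before arithmetic since isoform
#' abundances add on the linear scale. Negative estimates are clipped to 0
#' and flagged.
#'
#' @param proxy A [select_total_proxy()] result.
#' @param X An [expression_matrix()].
#' @param M An [build_incidence()] matrix.
#' @param observed_exons Exon ordinals with measured signal.
#' @return List of `group_estimate` objects (labels, coefficient vectors,
#'   per-sample non-negative abundances, clipping flags).
#' @export
subtraction_estimates <- function(proxy, X, M, observed_exons) {
  d <- design_from_incidence(M, observed_exons)
  chain <- subtraction_chain(d$A)
  if (is.null(chain))
    stop("observed exon patterns do not form a nested subtraction chain; ",
         "use lsq_estimates()", call. = FALSE)
  n_iso <- ncol(d$A)
  signal_of <- function(pattern)
    rowMeans(as.matrix(exon_linear_signal(X, d$pattern_exons[[pattern]])))
  out <- list()
  prev_members <- rep(0, n_iso)
  prev_signal <- 0
  for (step in chain) {
    coef <- step$members - prev_members
    sig <- signal_of(step$pattern)
    out[[length(out) + 1L]] <- new_group_estimate(
      group_label(coef, d$isoforms), stats::setNames(coef, d$isoforms),
      sig - prev_signal)
    prev_members <- step$members
    prev_signal <- sig
  }
  if (any(prev_members == 0)) {
    coef <- 1 - prev_members
    out[[length(out) + 1L]] <- new_group_estimate(
      group_label(coef, d$isoforms), stats::setNames(coef, d$isoforms),
      proxy$total - prev_signal)
  }
  out
}

#' Estimate identifiable isoform groups by non-negative least squares
#'
#' Generalization of [subtraction_estimates()] to arbitrary designs: per
#' sample, isoform abundances are fit by non-negative least squares on the
#' pattern-level linear signals, and the estimable group functionals
#' reported by [identifiable_groups()] are evaluated on the fit. Estimable
#' functionals depend only on the fitted signal, so their values are
#' well defined even when individual isoform abundances are not.
#'
#' @inheritParams subtraction_estimates
#' @param X An [expression_matrix()].
#' @return List of `group_estimate` objects, one per estimable functional.
#' @export
lsq_estimates <- function(X, M, observed_exons) {
  rep_id <- identifiable_groups(M, observed_exons)
  if (rep_id$design_rank == 0L)
    stop("design has rank 0; nothing is estimable", call. = FALSE)
  A <- rep_id$design
  ## isoforms with identical observed-exon patterns are indistinguishable:
  ## collapse them into one design column each (estimable functionals are
  ## constant within such a class, so they evaluate on class totals)
  col_key <- apply(A, 2, paste, collapse = "/")
  class_rep <- match(unique(col_key), col_key)
  ## classes absent from every observed pattern carry no signal: their
  ## coefficient in any estimable functional is 0, so drop them from the fit
  nonzero <- colSums(A[, class_rep, drop = FALSE]) > 0
  class_rep <- class_rep[nonzero]
  A_red <- A[, class_rep, drop = FALSE]
  ## lsqnonneg needs at least as many rows as columns; for wide reduced
  ## designs a negligible ridge picks one optimum without moving the
  ## estimable functionals beyond ~1e-12 relative
  if (nrow(A_red) < ncol(A_red)) {
    ridge <- diag(1e-6, ncol(A_red))
    fit_fun <- function(b) pracma::lsqnonneg(rbind(A_red, ridge),
                                             c(b, numeric(ncol(A_red))))$x
  } else {
    fit_fun <- function(b) pracma::lsqnonneg(A_red, b)$x
  }
  B <- sapply(names(rep_id$pattern_exons), function(p)
    rowMeans(exon_linear_signal(X, rep_id$pattern_exons[[p]])))
  B <- matrix(B, ncol = nrow(A),
              dimnames = list(rownames(X$values), rownames(A)))
  fits_red <- t(apply(B, 1, fit_fun))
  lapply(seq_len(nrow(rep_id$estimable)), function(i) {
    coef <- rep_id$estimable[i, ]
    class_coef <- vapply(seq_along(class_rep), function(j) {
      members <- which(col_key == col_key[class_rep[j]])
      cc <- coef[members]
      if (diff(range(cc)) > 1e-9)
        stop("functional not constant on an indistinguishable isoform ",
             "class; design inconsistent", call. = FALSE)
      cc[1]
    }, numeric(1))
    new_group_estimate(rep_id$group_labels[i], coef,
                       stats::setNames(as.numeric(fits_red %*% class_coef),
                                       rownames(fits_red)))
  })
}

#' Correlate group abundances with total expression
#'
#' Pearson correlation (with the standard t-based two-sided p-value) of
#' each identifiable group's abundance against the total-expression proxy
#' across the cohort. No multiple-testing correction is applied. Groups
#' with zero variance are flagged and reported as not computable (`NA`),
#' never as r = 0.
#'
#' @param estimates List of `group_estimate` objects.
#' @param proxy A [select_total_proxy()] result.
#' @return Data frame with columns `group_label`, `pearson_r`, `p_value`,
#'   `n`, `computable`.
#' @export
correlate_groups <- function(estimates, proxy) {
  n <- length(proxy$total)
  if (n < 3L) stop("need at least 3 samples for correlation", call. = FALSE)
  rows <- lapply(estimates, function(g) {
    if (stats::sd(g$abundances) == 0) {
      warning("group ", g$group_label, " has zero variance; ",
              "correlation not computable")
      return(data.frame(group_label = g$group_label, pearson_r = NA_real_,
                        p_value = NA_real_, n = n, computable = FALSE))
    }
    ct <- stats::cor.test(g$abundances, proxy$total, method = "pearson")
    data.frame(group_label = g$group_label,
               pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n = n, computable = TRUE)
  })
  do.call(rbind, rows)
}
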