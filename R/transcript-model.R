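#' @keywords internal
"_PACKAGE"

#' Define an exon
#'
#' Exons are identified by their ordinal position within the gene (1-based),
#' the convention used throughout isoform nomenclature for *SPP1*/OPN.
#' Genomic coordinates are optional metadata; identity is by ordinal.
#'
#' @param exon_id Positive integer ordinal (1-based index within the gene).
#' @param length Exon length in base pairs (>= 1).
#' @param genomic_start,genomic_end Optional 1-based inclusive genomic
#'   coordinates; if given, `end - start + 1` must equal `length`.
#' @return An object of class `exon_def`.
#' @export
exon_def <- function(exon_id, length, genomic_start = NULL, genomic_end = NULL) {
  exon_id <- as.integer(exon_id)
  length <- as.integer(length)
  if (is.na(exon_id) || exon_id < 1L)
    stop("exon_id must be a positive integer", call. = FALSE)
  if (is.na(length) || length < 1L)
    stop("exon length must be >= 1 bp (exon ", exon_id, ")", call. = FALSE)
  if (!is.null(genomic_start) || !is.null(genomic_end)) {
    if (is.null(genomic_start) || is.null(genomic_end))
      stop("both genomic_start and genomic_end must be given, or neither",
           call. = FALSE)
    if (genomic_end - genomic_start + 1L != length)
      stop("coordinates of exon ", exon_id, " are inconsistent with its length",
           call. = FALSE)
  }
  structure(list(exon_id = exon_id, length = length,
                 genomic_start = genomic_start, genomic_end = genomic_end),
            class = "exon_def")
}

#' Define a splice isoform
#'
#' @param isoform_id Isoform name (e.g. `"OPNa"`).
#' @param exons Strictly increasing vector of exon ordinals the isoform
#'   contains.
#' @return An object of class `isoform_def`.
#' @export
isoform_def <- function(isoform_id, exons) {
  exons <- as.integer(exons)
  if (length(exons) == 0L)
    stop("isoform ", isoform_id, " has no exons", call. = FALSE)
  if (anyNA(exons) || any(diff(exons) <= 0L))
    stop("exons of isoform ", isoform_id,
         " must be strictly increasing ordinals", call. = FALSE)
  structure(list(isoform_id = as.character(isoform_id), exons = exons),
            class = "isoform_def")
}

#' The packaged SPP1/OPN five-isoform gene model
#'
#' Exon structure of the five osteopontin splice isoforms: OPNa carries
#' exons 1,2,3,5,6,7,8; OPNb lacks exon 6; OPNc lacks exon 5; OPN4 lacks
#' exons 4, 5 and 6; OPN5 is the only isoform containing exon 4 (all eight
#' exons). Exon lengths are a reconstruction chosen so that primers
#' anchored in exons 3 and 7 yield the observed single-tube RT-PCR ladder
#' OPNa 253 bp, OPNb 211 bp, OPNc 172 bp (exon 5 = 81 bp, exon 6 = 42 bp).
#'
#' @return A list with elements `exons` (list of [exon_def()]), `isoforms`
#'   (list of [isoform_def()]) and `primers` (a [primer_pair()] anchored in
#'   exons 3 and 7).
#' @export
spp1_gene <- function() {
  lengths <- c(170L, 54L, 93L, 84L, 81L, 42L, 129L, 1200L)
  exons <- lapply(seq_along(lengths), function(i) exon_def(i, lengths[i]))
  isoforms <- list(
    isoform_def("OPNa", c(1, 2, 3, 5, 6, 7, 8)),
    isoform_def("OPNb", c(1, 2, 3, 5, 7, 8)),
    isoform_def("OPNc", c(1, 2, 3, 6, 7, 8)),
    isoform_def("OPN4", c(1, 2, 3, 7, 8)),
    isoform_def("OPN5", 1:8)
  )
  primers <- primer_pair(forward_exon = 3, forward_offset = 24,
                         reverse_exon = 7, reverse_offset = 60)
  list(exons = exons, isoforms = isoforms, primers = primers)
}

#' Build the exon-isoform incidence matrix
#'
#' Binary matrix with one row per isoform and one column per exon; entry 1
#' means the isoform contains the exon. The per-exon column sum is the
#' exon's inclusion frequency (the number of isoforms expressing it), the
#' quantity that determines which exon-level signals inform which isoform
#' sums.
#'
#' @param gene_exons List of [exon_def()] for the whole gene.
#' @param isoforms Non-empty list of [isoform_def()].
#' @return An `incidence_matrix`: a binary matrix (isoforms x exons) with
#'   attributes `frequency` (per-exon column sums) and `exon_lengths`.
#' @examples
#' g <- spp1_gene()
#' M <- build_incidence(g$exons, g$isoforms)
#' attr(M, "frequency")
#' @export
build_incidence <- function(gene_exons, isoforms) {
  if (length(isoforms) == 0L)
    stop("at least one isoform is required", call. = FALSE)
  exon_ids <- vapply(gene_exons, function(e) e$exon_id, integer(1))
  if (anyDuplicated(exon_ids))
    stop("duplicate exon ids in gene model", call. = FALSE)
  iso_ids <- vapply(isoforms, function(i) i$isoform_id, character(1))
  if (anyDuplicated(iso_ids))
    stop("duplicate isoform ids", call. = FALSE)
  M <- matrix(0L, nrow = length(isoforms), ncol = length(exon_ids),
              dimnames = list(iso_ids, paste0("exon", exon_ids)))
  for (i in seq_along(isoforms)) {
    unknown <- setdiff(isoforms[[i]]$exons, exon_ids)
    if (length(unknown))
      stop("isoform ", iso_ids[i], " refers to undefined exon(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    M[i, match(isoforms[[i]]$exons, exon_ids)] <- 1L
  }
  structure(M,
            exon_ids = exon_ids,
            frequency = colSums(M),
            exon_lengths = stats::setNames(
              vapply(gene_exons, function(e) e$length, integer(1)),
              colnames(M)),
            class = c("incidence_matrix", class(M)))
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("Exon-isoform incidence matrix (", nrow(x), " isoforms x ",
      ncol(x), " exons)\n", sep = "")
  m <- rbind(unclass(x)[, , drop = FALSE], frequency = attr(x, "frequency"))
  print(m)
  invisible(x)
}

## Design matrix over distinct observed exon-membership patterns.
## Exons whose membership columns coincide carry identical information and
## are merged into one equation; their signals are averaged downstream.
design_from_incidence <- function(M, observed_exons) {
  exon_ids <- attr(M, "exon_ids")
  observed_exons <- as.integer(observed_exons)
  if (length(observed_exons) == 0L)
    stop("observed_exons must be non-empty", call. = FALSE)
  missing <- setdiff(observed_exons, exon_ids)
  if (length(missing))
    stop("observed exon(s) not in the incidence matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cols <- match(observed_exons, exon_ids)
  pat_key <- apply(unclass(M)[, cols, drop = FALSE], 2, paste, collapse = "")
  keys <- unique(pat_key)
  A <- t(vapply(keys, function(k) {
    unclass(M)[, cols[which(pat_key == k)[1]], drop = TRUE]
  }, numeric(nrow(M))))
  rownames(A) <- vapply(keys, function(k) {
    paste(colnames(M)[cols[pat_key == k]], collapse = "|")
  }, character(1))
  colnames(A) <- rownames(M)
  pattern_exons <- lapply(keys, function(k) observed_exons[pat_key == k])
  names(pattern_exons) <- rownames(A)
  list(A = A, pattern_exons = pattern_exons, isoforms = rownames(M))
}

## Reduced row echelon form by Gauss-Jordan elimination with partial
## pivoting; tolerant of any shape, including single-row designs.
gauss_rref <- function(A, tol = 1e-10) {
  A <- as.matrix(A) * 1.0
  m <- nrow(A); n <- ncol(A)
  lead <- 1L
  for (r in seq_len(m)) {
    if (lead > n) break
    repeat {
      i <- which.max(abs(A[r:m, lead])) + r - 1L
      if (abs(A[i, lead]) >= tol) break
      lead <- lead + 1L
      if (lead > n) {
        A[abs(A) < tol] <- 0
        return(A)
      }
    }
    A[c(r, i), ] <- A[c(i, r), ]
    A[r, ] <- A[r, ] / A[r, lead]
    others <- setdiff(seq_len(m), r)
    if (length(others))
      A[others, ] <- A[others, , drop = FALSE] -
        outer(A[others, lead], A[r, ])
    lead <- lead + 1L
  }
  A[abs(A) < tol] <- 0
  A
}

## Scale a real-valued coefficient row to smallest integer coefficients
## when an integer multiple up to `max_den` exists (tolerance 1e-8).
integerize <- function(v, max_den = 64L) {
  nz <- abs(v) > 1e-10
  if (!any(nz)) return(v)
  for (d in seq_len(max_den)) {
    w <- v * d
    if (all(abs(w - round(w)) < 1e-8)) {
      w <- round(w)
      g <- Reduce(function(a, b) {
        while (b) { t <- b; b <- a %% b; a <- t }; a
      }, abs(w[w != 0]))
      return(w / g)
    }
  }
  v
}

group_label <- function(coef, isoforms) {
  nz <- which(abs(coef) > 1e-10)
  if (all(abs(coef[nz] - 1) < 1e-10))
    return(paste(isoforms[nz], collapse = "+"))
  paste(sprintf("%+g*%s", coef[nz], isoforms[nz]), collapse = " ")
}

#' Which isoform combinations are identifiable from an observed exon set?
#'
#' Each distinct observed exon-membership pattern contributes one linear
#' equation: signal = sum of abundances of the isoforms containing that
#' exon. The row space of this design is the space of estimable linear
#' functionals of isoform abundances; its null space describes the
#' abundance combinations the observed exons cannot distinguish. When an
#' estimable basis functional is a 0/1 sum of isoforms it is reported as a
#' "+"-joined identifiable group (e.g. `"OPNa+OPNb"`).
#'
#' For the SPP1 five-isoform model with exon 6 unobserved (the situation on
#' arrays lacking an exon 6 probe set), the identifiable groups are exactly
#' `OPNa+OPNb`, `OPNc+OPN4` and `OPN5`.
#'
#' @param M An [build_incidence()] matrix.
#' @param observed_exons Non-empty set of exon ordinals with measured
#'   signal.
#' @return An `identifiability_report` list: `observed_exons`,
#'   `design` (the pattern x isoform design matrix), `design_rank`,
#'   `estimable` (matrix of canonical estimable-functional coefficients,
#'   one row per functional, labelled), `group_labels`,
#'   `null_space` (matrix whose rows span the null space),
#'   `fully_identifiable`.
#' @examples
#' g <- spp1_gene()
#' M <- build_incidence(g$exons, g$isoforms)
#' identifiable_groups(M, c(1, 2, 3, 4, 5, 7, 8))$group_labels
#' @export
identifiable_groups <- function(M, observed_exons) {
  d <- design_from_incidence(M, observed_exons)
  A <- d$A
  p <- ncol(A)
  r <- qr(A)$rank
  ## canonical estimable basis: reduced row echelon over the row space,
  ## scaled to smallest integers, ordered by first nonzero isoform index
  R <- gauss_rref(A)
  R <- R[rowSums(abs(R) > 1e-9) > 0, , drop = FALSE]
  R <- t(apply(R, 1, integerize))
  if (nrow(R) > 1) {
    first_nz <- apply(R, 1, function(v) which(abs(v) > 1e-10)[1])
    R <- R[order(first_nz), , drop = FALSE]
  }
  colnames(R) <- d$isoforms
  labels <- apply(R, 1, group_label, isoforms = d$isoforms)
  rownames(R) <- labels
  ## null space via SVD (right singular vectors of negligible singular value)
  s <- svd(A, nu = 0, nv = p)
  tol <- max(dim(A)) * max(s$d, 0) * .Machine$double.eps * 100
  null_idx <- which(c(s$d, rep(0, p - length(s$d))) <= tol)
  N <- t(s$v[, null_idx, drop = FALSE])
  if (nrow(N)) N <- t(apply(N, 1, function(v) {
    v <- integerize(v)
    if (v[which(abs(v) > 1e-10)[1]] < 0) v <- -v
    v
  }))
  colnames(N) <- d$isoforms
  structure(list(observed_exons = sort(as.integer(observed_exons)),
                 design = A,
                 pattern_exons = d$pattern_exons,
                 design_rank = r,
                 estimable = R,
                 group_labels = unname(labels),
                 null_space = N,
                 fully_identifiable = nrow(N) == 0L),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("Identifiability from exons {",
      paste(x$observed_exons, collapse = ", "), "}\n", sep = "")
  cat("  design rank:", x$design_rank, "of", ncol(x$design), "isoforms\n")
  cat("  estimable functionals:",
      paste(x$group_labels, collapse = "; "), "\n")
  cat("  fully identifiable:", x$fully_identifiable, "\n")
  invisible(x)
}

#' Define a primer pair by exon anchors
#'
#' @param forward_exon,reverse_exon Exon ordinals hosting each primer;
#'   forward must not lie downstream of reverse.
#' @param forward_offset 1-based position within the forward exon at which
#'   the amplified product starts.
#' @param reverse_offset 1-based position within the reverse exon at which
#'   the product ends (bp contributed by the reverse-anchor exon).
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(forward_exon, forward_offset, reverse_exon,
                        reverse_offset) {
  if (forward_exon > reverse_exon)
    stop("forward anchor exon lies downstream of reverse anchor", call. = FALSE)
  if (forward_offset < 1L || reverse_offset < 1L)
    stop("primer offsets are 1-based and must be >= 1", call. = FALSE)
  structure(list(forward_exon = as.integer(forward_exon),
                 forward_offset = as.integer(forward_offset),
                 reverse_exon = as.integer(reverse_exon),
                 reverse_offset = as.integer(reverse_offset)),
            class = "primer_pair")
}

#' Predict per-isoform RT-PCR amplicon lengths
#'
#' For every isoform containing both anchor exons, the product length is
#' the remainder of the forward-anchor exon (from the primer position to
#' the exon end), plus the lengths of all intervening exons the isoform
#' retains, plus the reverse offset. Isoforms missing either anchor exon
#' yield no product (reported as `NA`, a distinct state from zero length).
#' Exon skipping between the anchors shortens the product by exactly the
#' skipped exon's length, which is how a single primer pair flanking exons
#' 5 and 6 resolves OPNa/OPNb/OPNc as a 253/211/172 bp ladder.
#'
#' @param M An [build_incidence()] matrix (carries exon lengths).
#' @param primers A [primer_pair()].
#' @return Named integer vector of product lengths per isoform; `NA` where
#'   the isoform lacks an anchor exon.
#' @examples
#' g <- spp1_gene()
#' M <- build_incidence(g$exons, g$isoforms)
#' predict_amplicons(M, g$primers)
#' @export
predict_amplicons <- function(M, primers) {
  exon_ids <- attr(M, "exon_ids")
  lens <- attr(M, "exon_lengths")
  fe <- primers$forward_exon; re <- primers$reverse_exon
  if (!(fe %in% exon_ids) || !(re %in% exon_ids))
    stop("primer anchor exon not present in the gene model", call. = FALSE)
  fi <- match(fe, exon_ids); ri <- match(re, exon_ids)
  if (primers$forward_offset > lens[fi])
    stop("forward offset exceeds anchor exon length", call. = FALSE)
  if (primers$reverse_offset > lens[ri])
    stop("reverse offset exceeds anchor exon length", call. = FALSE)
  fwd_remainder <- lens[fi] - primers$forward_offset + 1L
  between <- if (ri - fi > 1L) seq(fi + 1L, ri - 1L) else integer(0)
  out <- vapply(seq_len(nrow(M)), function(i) {
    if (M[i, fi] == 0L || M[i, ri] == 0L) return(NA_integer_)
    as.integer(fwd_remainder + sum(lens[between] * unclass(M)[i, between]) +
                 primers$reverse_offset)
  }, integer(1))
  stats::setNames(out, rownames(M))
}
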