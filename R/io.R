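## File formats are fixed dialects: UTF-8, tab/comma separated, "." decimal,
## no quoting in ids — so fixtures and outputs are bit-reproducible.

atomic_write <- function(write_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

write_tsv_atomic <- function(df, path, row_names = FALSE) {
  atomic_write(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = row_names, col.names = TRUE,
                       fileEncoding = "UTF-8")
  }, path)
}

#' Read isoform definitions from GTF/GFF3 or a simple TSV
#'
#' GTF/GFF3: exon features grouped by `transcript_id`; gene exons are the
#' distinct exon intervals, assigned 1-based ordinals in genomic order
#' along the gene strand (reverse strand numbers from the rightmost exon),
#' with lengths from the coordinates. TSV: two columns,
#' `isoform_id<TAB>comma-separated exon ordinals`, no header required a
#' priori (a header line `isoform_id` is skipped); the TSV carries no exon
#' lengths, so exons default to `default_exon_length` unless
#' `exon_lengths` is supplied.
#'
#' @param path Annotation file; format chosen by extension
#'   (`.gtf`/`.gff`/`.gff3` vs anything else = TSV).
#' @param exon_lengths Optional vector of exon lengths (bp) by ordinal, for
#'   TSV input.
#' @param default_exon_length Exon length assumed for TSV input when
#'   `exon_lengths` is not given.
#' @return List with `exons` (list of [exon_def()]) and `isoforms` (list of
#'   [isoform_def()]).
#' @export
read_annotation <- function(path, exon_lengths = NULL,
                            default_exon_length = 100L) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE))
    return(read_annotation_gtf(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^isoform_id\\b", lines[1])) lines <- lines[-1]
  if (!length(lines))
    stop("annotation TSV is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  isoforms <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != 2L)
      stop("annotation TSV line ", i, ": expected 2 tab-separated fields",
           call. = FALSE)
    ex <- suppressWarnings(as.integer(strsplit(p[2], ",")[[1]]))
    if (anyNA(ex))
      stop("annotation TSV line ", i, ": non-integer exon id", call. = FALSE)
    isoform_def(p[1], sort(ex))
  })
  all_ex <- sort(unique(unlist(lapply(isoforms, function(i) i$exons))))
  if (is.null(exon_lengths))
    exon_lengths <- stats::setNames(rep(default_exon_length,
                                        length(all_ex)), all_ex)
  exons <- lapply(all_ex, function(e)
    exon_def(e, exon_lengths[[as.character(e)]]))
  list(exons = exons, isoforms = isoforms)
}

read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF/GFF requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path)
  grdf <- as.data.frame(gr)
  grdf <- grdf[as.character(grdf$type) == "exon", , drop = FALSE]
  if (!nrow(grdf))
    stop("no exon features in ", path, call. = FALSE)
  df <- data.frame(start = grdf$start, end = grdf$end,
                   strand = as.character(grdf$strand),
                   transcript = as.character(grdf$transcript_id),
                   stringsAsFactors = FALSE)
  minus <- any(df$strand == "-")
  key <- paste(df$start, df$end)
  uniq <- df[!duplicated(key), , drop = FALSE]
  uniq <- uniq[order(uniq$start, decreasing = minus), , drop = FALSE]
  ord <- stats::setNames(seq_len(nrow(uniq)),
                         paste(uniq$start, uniq$end))
  exons <- lapply(seq_len(nrow(uniq)), function(i)
    exon_def(i, uniq$end[i] - uniq$start[i] + 1L,
             genomic_start = uniq$start[i], genomic_end = uniq$end[i]))
  tx_ids <- unique(df$transcript)
  isoforms <- lapply(tx_ids, function(tx)
    isoform_def(tx, sort(unname(ord[key[df$transcript == tx]]))))
  list(exons = exons, isoforms = isoforms)
}

#' Write / read an incidence matrix as TSV (with trailing frequency row)
#'
#' @param M An [build_incidence()] matrix.
#' @param path Output TSV.
#' @export
write_incidence <- function(M, path) {
  df <- as.data.frame(rbind(unclass(M), frequency = attr(M, "frequency")))
  df <- cbind(isoform = rownames(df), df)
  write_tsv_atomic(df, path)
}

#' Read an exon-level expression matrix plus probe map
#'
#' Expression TSV: first column the sample id, remaining header columns the
#' probe-set ids, cells log2 signals. Probe-map TSV: `probeset<TAB>exon_id`
#' with a header line.
#'
#' @param path Expression TSV.
#' @param probe_map_path Probe-map TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, probe_map_path) {
  for (p in c(path, probe_map_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(df[[1]], colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at sample ", rownames(num)[bad[1]],
         ", probe set ", colnames(num)[bad[2]], " in ", path, call. = FALSE)
  }
  pm <- utils::read.table(probe_map_path, sep = "\t", header = TRUE,
                          fileEncoding = "UTF-8")
  expression_matrix(num, stats::setNames(as.integer(pm[[2]]),
                                         as.character(pm[[1]])))
}

#' @rdname read_expression
#' @param X An [expression_matrix()].
#' @param probe_map_path Probe-map TSV to write alongside.
#' @export
write_expression <- function(X, path, probe_map_path) {
  df <- cbind(data.frame(sample = rownames(X$values)),
              as.data.frame(X$values, check.names = FALSE))
  write_tsv_atomic(df, path)
  write_tsv_atomic(data.frame(probeset = names(X$probe_to_exon),
                              exon_id = unname(X$probe_to_exon)),
                   probe_map_path)
}

#' Read / write a Ct table CSV
#'
#' CSV columns: `sample,assay,role,replicate,ct`.
#'
#' @param path CSV file.
#' @param ... Passed to [ct_table()] (e.g. `concordance_window`).
#' @export
read_ct <- function(path, ...) {
  if (!file.exists(path)) stop("Ct file not found: ", path, call. = FALSE)
  ct_table(utils::read.csv(path, fileEncoding = "UTF-8"), ...)
}

#' @rdname read_ct
#' @param ct A [ct_table()].
#' @export
write_ct <- function(ct, path) {
  atomic_write(function(tmp) {
    utils::write.csv(as.data.frame(ct), tmp, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }, path)
}

#' Read / write cohort labels TSV
#'
#' TSV columns `sample<TAB>class` with a header; classes restricted to the
#' vocabulary in [COHORT_CLASSES].
#'
#' @param path Labels TSV.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8")
  names(df)[1:2] <- c("sample", "class")
  bad <- setdiff(unique(df$class), COHORT_CLASSES)
  if (length(bad))
    stop("unknown class token(s) in ", path, ": ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(COHORT_CLASSES, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in ", path, call. = FALSE)
  df
}

#' @rdname read_labels
#' @param labels Data frame with columns `sample`, `class`.
#' @export
write_labels <- function(labels, path) {
  write_tsv_atomic(labels[, c("sample", "class")], path)
}

#' Write group-abundance and correlation tables
#'
#' @param estimates List of `group_estimate` objects.
#' @param path Output TSV (samples x groups, plus a `clipped_any` column).
#' @export
write_groups <- function(estimates, path) {
  samples <- names(estimates[[1]]$abundances)
  df <- data.frame(sample = samples)
  for (g in estimates) df[[g$group_label]] <- unname(g$abundances)
  df$clipped_any <- Reduce(`|`, lapply(estimates, function(g)
    unname(g$clipped)))
  write_tsv_atomic(df, path)
}

#' @rdname write_groups
#' @param correlations A [correlate_groups()] data frame.
#' @export
write_correlations <- function(correlations, path) {
  write_tsv_atomic(correlations, path)
}
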