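PIPELINE_KEYS <- list(
  top = c("seed", "out_dir", "simulate", "inputs", "deconvolution",
          "qpcr", "plots"),
  simulate = c("n_per_class", "classes", "baseline_log2",
               "class_log2_shift", "dirichlet", "sample_factor_sd",
               "probe_noise_sd", "probesets_per_exon", "ct_intercept",
               "ct_noise_sd", "n_replicates"),
  inputs = c("annotation", "expression", "probe_map", "ct", "labels"),
  deconvolution = c("k_proxies", "observed_exons", "method"),
  qpcr = c("target", "references", "calibrator_classes",
           "reference_classes", "rule")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
}

#' Load and validate a pipeline configuration
#'
#' @param config Path to a YAML file, or an equivalent named list. Unknown
#'   keys are rejected. Either a `simulate` block (inputs are generated) or
#'   an `inputs` block with file paths must be present.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  check_keys(config, PIPELINE_KEYS$top, "configuration")
  for (b in c("simulate", "inputs", "deconvolution", "qpcr"))
    if (!is.null(config[[b]]))
      check_keys(config[[b]], PIPELINE_KEYS[[b]], b)
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("configuration needs a 'simulate' or an 'inputs' block",
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir))
    stop("configuration needs 'out_dir'", call. = FALSE)
  if (is.null(config$plots)) config$plots <- FALSE
  dec <- config$deconvolution
  if (is.null(dec$k_proxies)) dec$k_proxies <- 3L
  if (is.null(dec$method)) dec$method <- "subtraction"
  if (!dec$method %in% c("subtraction", "lsq"))
    stop("deconvolution method must be 'subtraction' or 'lsq'",
         call. = FALSE)
  config$deconvolution <- dec
  qp <- config$qpcr
  if (is.null(qp$target)) qp$target <- "SPP1"
  if (is.null(qp$references)) qp$references <- c("GAPDH", "ACTB", "RPLP0")
  if (is.null(qp$calibrator_classes)) qp$calibrator_classes <- "Normal"
  if (is.null(qp$reference_classes)) qp$reference_classes <- c("Normal", "BE")
  if (is.null(qp$rule)) qp$rule <- "2m_plus_s"
  config$qpcr <- qp
  structure(config, class = "pipeline_config")
}

sim_config_from_block <- function(block, seed) {
  args <- block
  if (!is.null(args$class_log2_shift))
    args$class_log2_shift <- unlist(args$class_log2_shift)
  if (!is.null(args$dirichlet)) args$dirichlet <- unlist(args$dirichlet)
  if (!is.null(args$classes)) args$classes <- unlist(args$classes)
  args$seed <- seed
  do.call(sim_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' incidence, deconvolve (proxy selection, group estimation, correlation),
#' qpcr (fold changes, overexpression calls, class comparison) — writing
#' every table atomically under `out_dir` and returning a run report. A
#' rerun with the same configuration produces byte-identical tables.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [pipeline_config()]).
#' @param stages Stages to execute (default all).
#' @return A `run_report` list (also written as `report.json` and
#'   `report.md`); see the `correlations` and `calls` elements for the
#'   headline results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "incidence", "deconvolve",
                                    "qpcr")) {
  cfg <- pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  report <- list(package_version = as.character(utils::packageVersion("opnsplice")),
                 config = unclass(cfg), stages = list(), warnings = character(0))
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }

  ## --- gene model ------------------------------------------------------
  ann_path <- cfg$inputs$annotation
  gene <- if (!is.null(ann_path)) read_annotation(ann_path) else spp1_gene()
  M <- build_incidence(gene$exons, gene$isoforms)

  ## --- simulate or load inputs ----------------------------------------
  if ("simulate" %in% stages && !is.null(cfg$simulate)) {
    scfg <- sim_config_from_block(cfg$simulate, cfg$seed)
    sim <- simulate_cohort(scfg)
    obs <- cfg$deconvolution$observed_exons
    if (is.null(obs)) obs <- attr(M, "exon_ids")
    X <- simulate_exon_signals(sim$truth, M, scfg, observed_exons = obs)
    ct <- simulate_ct(stats::setNames(attr(sim$truth, "total"),
                                      rownames(sim$truth)), scfg,
                      target = cfg$qpcr$target,
                      references = cfg$qpcr$references)
    labels <- sim$labels
    write_labels(labels, out("labels.tsv"))
    truth_df <- cbind(data.frame(sample = rownames(sim$truth)),
                      as.data.frame(unclass(sim$truth)))
    write_tsv_atomic(truth_df, out("truth.tsv"))
    write_expression(X, out("expression.tsv"), out("probe_map.tsv"))
    write_ct(ct, out("ct.csv"))
    note("simulate", n_samples = nrow(labels),
         classes = table(labels$class))
  } else {
    inp <- cfg$inputs
    for (f in c("expression", "probe_map", "ct", "labels")) {
      if (is.null(inp[[f]]))
        stop("inputs block lacks '", f, "'", call. = FALSE)
      if (!file.exists(inp[[f]]))
        stop("input file not found: ", inp[[f]], call. = FALSE)
    }
    X <- read_expression(inp$expression, inp$probe_map)
    ct <- read_ct(inp$ct)
    labels <- read_labels(inp$labels)
    disjoint <- c(setdiff(rownames(X$values), labels$sample),
                  setdiff(labels$sample, rownames(X$values)))
    if (length(disjoint))
      stop("sample ids differ between expression and labels: ",
           paste(disjoint, collapse = ", "), call. = FALSE)
    note("simulate", skipped = TRUE)
  }

  ## --- incidence -------------------------------------------------------
  if ("incidence" %in% stages) {
    write_incidence(M, out("incidence.tsv"))
    note("incidence", n_isoforms = nrow(M), n_exons = ncol(M),
         frequency = as.list(attr(M, "frequency")))
  }

  ## --- deconvolution ---------------------------------------------------
  if ("deconvolve" %in% stages) {
    obs <- cfg$deconvolution$observed_exons
    if (is.null(obs)) obs <- sort(unique(X$probe_to_exon))
    ident <- identifiable_groups(M, obs)
    proxy <- select_total_proxy(X, M, k = cfg$deconvolution$k_proxies)
    est <- if (cfg$deconvolution$method == "subtraction") {
      subtraction_estimates(proxy, X, M, obs)
    } else {
      lsq_estimates(X, M, obs)
    }
    correlations <- correlate_groups(est, proxy)
    write_groups(est, out("groups.tsv"))
    write_correlations(correlations, out("correlations.tsv"))
    if (isTRUE(cfg$plots)) {
      for (g in est)
        plot_group_scatter(g, proxy,
                           file = out(paste0("scatter_",
                                             gsub("[^A-Za-z0-9]+", "_",
                                                  g$group_label), ".png")))
      plot_exon_heatmap(X, file = out("heatmap.png"))
    }
    note("deconvolve",
         observed_exons = obs,
         design_rank = ident$design_rank,
         groups = ident$group_labels,
         fully_identifiable = ident$fully_identifiable,
         proxy_probesets = proxy$selected_probesets,
         n_clipped = sum(vapply(est, function(g) sum(g$clipped),
                                integer(1))))
    report$correlations <- correlations
  }

  ## --- qpcr ------------------------------------------------------------
  if ("qpcr" %in% stages) {
    calib <- labels$sample[labels$class %in% cfg$qpcr$calibrator_classes]
    if (!length(calib))
      stop("no samples in calibrator class(es) ",
           paste(cfg$qpcr$calibrator_classes, collapse = ", "),
           call. = FALSE)
    folds <- ddct_fold_change(ct, cfg$qpcr$target, cfg$qpcr$references,
                              calibrator = calib)
    calls <- call_overexpression(folds, labels,
                                 reference_classes = cfg$qpcr$reference_classes,
                                 rule = cfg$qpcr$rule)
    comparison <- compare_classes(folds, labels,
                                  reference_classes = cfg$qpcr$reference_classes)
    write_tsv_atomic(as.data.frame(folds), out("folds.tsv"))
    write_tsv_atomic(as.data.frame(calls), out("calls.tsv"))
    write_tsv_atomic(comparison$tests, out("class_comparison.tsv"))
    note("qpcr", n_samples = nrow(folds),
         n_called = sum(calls$called),
         threshold = calls$threshold[1])
    report$calls <- calls
  }

  report <- write_report(report, cfg$out_dir)
  invisible(structure(report, class = "run_report"))
}

write_report <- function(report, out_dir) {
  json_report <- report
  json_report$config <- rapply(json_report$config, unclass, how = "replace")
  if (!is.null(json_report$correlations))
    json_report$correlations <- as.data.frame(json_report$correlations)
  if (!is.null(json_report$calls))
    json_report$calls <- as.data.frame(json_report$calls)
  atomic_write(function(tmp) {
    jsonlite::write_json(json_report, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }, file.path(out_dir, "report.json"))
  atomic_write(function(tmp) {
    con <- file(tmp, "w", encoding = "UTF-8")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    w("# Pipeline run report")
    w("")
    w("- package version: ", report$package_version)
    for (s in names(report$stages)) {
      w("")
      w("## Stage: ", s)
      rec <- report$stages[[s]]
      for (k in names(rec))
        w("- ", k, ": ", paste(format(unlist(rec[[k]])), collapse = ", "))
    }
    if (!is.null(report$correlations)) {
      w("")
      w("## Group correlations with total expression")
      df <- report$correlations
      for (i in seq_len(nrow(df)))
        w("- ", df$group_label[i], ": r = ",
          sprintf("%.4f", df$pearson_r[i]), ", p = ",
          format(df$p_value[i], digits = 3), ", n = ", df$n[i])
    }
    if (!is.null(report$calls)) {
      w("")
      w("## Overexpression calls")
      w("- called: ", sum(report$calls$called), " of ",
        nrow(report$calls), " (threshold ",
        sprintf("%.3f", report$calls$threshold[1]), ")")
    }
  }, file.path(out_dir, "report.md"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("opnsplice run report; stages:",
      paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$correlations)) print(x$correlations)
  invisible(x)
}
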