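#' Histology class vocabulary
#' @export
COHORT_CLASSES <- c("Normal", "BE", "Dysplasia",
                    "EAC_I", "EAC_II", "EAC_III", "EAC_IV")

#' Simulation configuration
#'
#' Defaults encode the qualitative cohort structure the analysis assumes:
#' tumor (EAC) classes share a +3 log2 (8-fold) shift in total gene output
#' over Normal/Barrett's; a shared per-sample log-normal factor makes all
#' isoforms co-vary within a sample; Dirichlet concentrations put mean
#' isoform proportions at 6:6:2:1:1 (OPNa ~ OPNb dominant, OPNc clearly
#' scarcer, OPN4/OPN5 minor) with a concentration scale under which splice
#' proportions are moderately stable across samples (per-isoform CV around
#' 30-45%), so that every isoform group tracks total gene output — the
#' observed cohort behavior. The concentrations are qualitative
#' reconstructions (tunable), not measured values.
#'
#' @param n_per_class Samples per class (single integer, or named vector
#'   over `classes`).
#' @param classes Histology classes to simulate (subset of
#'   [COHORT_CLASSES]).
#' @param baseline_log2 Normal-class mean log2 total abundance.
#' @param class_log2_shift Named per-class additive shift of mean log2
#'   total abundance relative to Normal.
#' @param dirichlet Named positive Dirichlet concentrations per isoform.
#' @param sample_factor_sd log2 SD of the shared per-sample factor.
#' @param probe_noise_sd log2 SD of probe-level measurement noise.
#' @param probesets_per_exon Probe sets simulated per exon: `NULL` (default)
#'   means 4 for common exons and 1 otherwise; or a single integer for all
#'   exons.
#' @param ct_intercept Ct of a unit quantity (cycles).
#' @param ct_noise_sd Per-replicate Ct noise SD (cycles).
#' @param n_replicates Technical qPCR replicates per reaction.
#' @param seed Integer seed; all randomness flows through it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_class = 30L,
                       classes = COHORT_CLASSES,
                       baseline_log2 = 5,
                       class_log2_shift = c(Normal = 0, BE = 0,
                                            Dysplasia = 0.5, EAC_I = 3,
                                            EAC_II = 3, EAC_III = 3,
                                            EAC_IV = 3),
                       dirichlet = c(OPNa = 48, OPNb = 48, OPNc = 16,
                                     OPN4 = 8, OPN5 = 8),
                       sample_factor_sd = 1.0,
                       probe_noise_sd = 0.1,
                       probesets_per_exon = NULL,
                       ct_intercept = 30,
                       ct_noise_sd = 0.2,
                       n_replicates = 2L,
                       seed = 1L) {
  bad_class <- setdiff(classes, COHORT_CLASSES)
  if (length(bad_class))
    stop("classes: unknown class(es) ", paste(bad_class, collapse = ", "),
         "; allowed: ", paste(COHORT_CLASSES, collapse = ", "),
         call. = FALSE)
  if (is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(as.integer(n_per_class),
                                       length(classes)), classes)
  if (any(n_per_class < 1L))
    stop("n_per_class: all counts must be >= 1", call. = FALSE)
  missing_shift <- setdiff(classes, names(class_log2_shift))
  if (length(missing_shift))
    stop("class_log2_shift: no shift for class(es) ",
         paste(missing_shift, collapse = ", "), call. = FALSE)
  if (any(dirichlet <= 0))
    stop("dirichlet: concentrations must be > 0", call. = FALSE)
  for (f in c("sample_factor_sd", "probe_noise_sd", "ct_noise_sd")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop(f, ": must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(probesets_per_exon) &&
      (length(probesets_per_exon) != 1L || probesets_per_exon < 1L))
    stop("probesets_per_exon: must be NULL or a single integer >= 1",
         call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed: must be an integer", call. = FALSE)
  structure(list(n_per_class = n_per_class[classes], classes = classes,
                 baseline_log2 = baseline_log2,
                 class_log2_shift = class_log2_shift,
                 dirichlet = dirichlet,
                 sample_factor_sd = sample_factor_sd,
                 probe_noise_sd = probe_noise_sd,
                 probesets_per_exon = probesets_per_exon,
                 ct_intercept = ct_intercept,
                 ct_noise_sd = ct_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = seed),
            class = "sim_config")
}

## Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Simulate cohort labels and true isoform abundances
#'
#' Per sample: total abundance = 2^(baseline + class shift + N(0,
#' sample_factor_sd)); isoform abundances = total x Dirichlet proportions.
#' The shared per-sample factor is what induces co-overexpression of all
#' isoforms in the same samples. Reproducible under a fixed seed; the
#' global RNG state is untouched.
#'
#' @param cfg A [sim_config()].
#' @return List with `labels` (data frame `sample`, `class`) and `truth`
#'   (sample x isoform matrix of positive linear-scale abundances, plus a
#'   `total` attribute).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    classes <- rep(cfg$classes, times = cfg$n_per_class[cfg$classes])
    n <- length(classes)
    ids <- sprintf("S%03d", seq_len(n))
    shift <- cfg$class_log2_shift[classes]
    total <- 2^(cfg$baseline_log2 + shift +
                  stats::rnorm(n, 0, cfg$sample_factor_sd))
    props <- rdirichlet(n, cfg$dirichlet)
    truth <- props * total
    rownames(truth) <- ids
    list(labels = data.frame(sample = ids, class = classes,
                             stringsAsFactors = FALSE),
         truth = structure(truth, total = stats::setNames(total, ids)))
  })
}

#' Simulate exon-level probe-set signals from true abundances
#'
#' Each probe set maps to one exon; its log2 signal is log2 of the summed
#' abundance of the isoforms containing that exon, plus N(0,
#' probe_noise_sd) noise. By default common exons get 4 probe sets and all
#' others 1, mimicking the redundancy of common-exon coverage on exon
#' arrays.
#'
#' @param truth Sample x isoform abundance matrix from [simulate_cohort()].
#' @param M An [build_incidence()] matrix; isoforms must match `truth`
#'   columns.
#' @param cfg A [sim_config()].
#' @param observed_exons Exons for which probe sets exist (default: all
#'   exons of `M`). Exons contained in no isoform are rejected.
#' @return An [expression_matrix()].
#' @export
simulate_exon_signals <- function(truth, M, cfg,
                                  observed_exons = attr(M, "exon_ids")) {
  if (!identical(colnames(truth), rownames(M)))
    stop("truth isoforms do not match incidence-matrix rows", call. = FALSE)
  freq <- attr(M, "frequency")[match(observed_exons, attr(M, "exon_ids"))]
  if (any(freq == 0))
    stop("exon(s) contained in no isoform cannot be measured: ",
         paste(observed_exons[freq == 0], collapse = ", "), call. = FALSE)
  n_common <- nrow(M)
  withr::with_seed(cfg$seed + 1L, {
    cols <- list(); map <- integer(0)
    for (i in seq_along(observed_exons)) {
      e <- observed_exons[i]
      k <- if (is.null(cfg$probesets_per_exon)) {
        if (freq[i] == n_common) 4L else 1L
      } else as.integer(cfg$probesets_per_exon)
      members <- unclass(M)[, match(e, attr(M, "exon_ids"))] == 1L
      sig <- log2(rowSums(truth[, members, drop = FALSE]))
      for (j in seq_len(k)) {
        ps <- sprintf("ps_e%d_%d", e, j)
        cols[[ps]] <- sig + stats::rnorm(length(sig), 0, cfg$probe_noise_sd)
        map[ps] <- e
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- rownames(truth)
    expression_matrix(values, map)
  })
}

#' Simulate a qPCR Ct table from gene quantities
#'
#' Ct = ct_intercept - log2(quantity) + N(0, ct_noise_sd) per replicate
#' (perfect doubling per cycle). Reference genes are generated at constant
#' quantity across samples; replicates are independent.
#'
#' @param quantities Named positive vector of per-sample target quantities,
#'   or a samples x assays matrix (rownames = samples, colnames = assays)
#'   to simulate several target/control assays with one noise stream.
#' @param cfg A [sim_config()].
#' @param target Assay id used when `quantities` is a plain vector.
#' @param references Reference assay ids simulated at `reference_quantity`.
#' @param reference_quantity Constant linear quantity of each reference
#'   gene.
#' @param roles Named roles per assay column when `quantities` is a matrix
#'   (default `"target"` for every column).
#' @return A [ct_table()].
#' @export
simulate_ct <- function(quantities, cfg, target = "SPP1",
                        references = c("GAPDH", "ACTB", "RPLP0"),
                        reference_quantity = 1000,
                        roles = NULL) {
  if (!is.matrix(quantities)) {
    if (is.null(names(quantities)))
      stop("quantities must be named by sample id", call. = FALSE)
    quantities <- matrix(quantities, ncol = 1,
                         dimnames = list(names(quantities), target))
  }
  if (any(quantities <= 0))
    stop("all quantities must be > 0", call. = FALSE)
  if (is.null(roles))
    roles <- stats::setNames(rep("target", ncol(quantities)),
                             colnames(quantities))
  withr::with_seed(cfg$seed + 2L, {
    rows <- list()
    emit <- function(sample, assay, arole, q) {
      for (r in seq_len(cfg$n_replicates)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          sample = sample, assay = assay, role = arole, replicate = r,
          ct = cfg$ct_intercept - log2(q) +
            stats::rnorm(1, 0, cfg$ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    for (s in rownames(quantities)) {
      for (a in colnames(quantities))
        emit(s, a, roles[[a]], quantities[s, a])
      for (g in references) emit(s, g, "reference", reference_quantity)
    }
    ct_table(do.call(rbind, rows))
  })
}
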