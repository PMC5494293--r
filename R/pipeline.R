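#' PCA of samples on normalized expression
#'
#' Samples are observations; features are the -delta-Cq values of miRNAs
#' with complete detection across all samples (complete-case, no
#' imputation). Features are mean-centered and decomposed by SVD; variance
#' fractions per component are reported.
#'
#' @param norm \code{normalized_table}.
#' @return list of class \code{pca_result}: \code{scores} (samples x
#'   components), \code{variance_explained}, \code{n_features}.
#' @export
pca_samples <- function(norm) {
  stopifnot(inherits(norm, "normalized_table"))
  if (length(norm$sample_ids) < 2) stop("PCA needs >= 2 samples")
  complete <- rowSums(norm$detected) == ncol(norm$delta_cq)
  if (sum(complete) < 2)
    stop("fewer than 2 complete-case miRNAs; cannot run PCA")
  X <- t(-norm$delta_cq[complete, , drop = FALSE])  # samples x features
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, variance_explained = ve,
                 n_features = sum(complete)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d features; PC1 %.1f%%, PC2 %.1f%% variance\n",
              x$n_features, 100 * x$variance_explained[1],
              100 * ifelse(length(x$variance_explained) > 1,
                           x$variance_explained[2], 0)))
  invisible(x)
}

#' Two-dimensional hierarchical clustering for a heatmap
#'
#' Clusters miRNAs (rows) and samples (columns) of the -delta-Cq matrix.
#' Rows with no detected value are dropped with a warning (as a failed
#' amplification is dropped from display). Missing cells are tolerated:
#' distances use pairwise-complete coordinates (via \code{stats::dist},
#' which rescales for missingness). Defaults: Euclidean distance, average
#' linkage, no row scaling — the heatmap colors are -delta-Cq directly.
#'
#' @param norm \code{normalized_table}.
#' @param panel optional \code{mirna_list} restricting the rows.
#' @param dist_method distance for \code{stats::dist}.
#' @param linkage agglomeration method for \code{stats::hclust}.
#' @return list of class \code{heatmap_clustering}: \code{matrix}
#'   (-delta-Cq, rows/cols in clustered order), \code{row_order},
#'   \code{col_order}, \code{row_hclust}, \code{col_hclust},
#'   \code{dropped_rows}.
#' @export
hierarchical_heatmap <- function(norm, panel = NULL,
                                 dist_method = "euclidean",
                                 linkage = "average") {
  stopifnot(inherits(norm, "normalized_table"))
  M <- -norm$delta_cq
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "mirna_list"))
    idx <- match(panel$members, canonical_mirna(norm$mirna_ids))
    if (anyNA(idx))
      stop("panel miRNA(s) absent from table: ",
           paste(panel$members[is.na(idx)], collapse = ", "))
    M <- M[idx, , drop = FALSE]
  }
  empty <- rowSums(!is.na(M)) == 0
  dropped <- rownames(M)[empty]
  if (any(empty)) {
    warning("dropping all-missing row(s): ", paste(dropped, collapse = ", "))
    M <- M[!empty, , drop = FALSE]
  }
  if (nrow(M) < 2 || ncol(M) < 2)
    stop("need >= 2 rows and >= 2 columns after dropping empty rows")
  rh <- stats::hclust(stats::dist(M, method = dist_method), method = linkage)
  ch <- stats::hclust(stats::dist(t(M), method = dist_method), method = linkage)
  structure(list(matrix = M[rh$order, ch$order, drop = FALSE],
                 row_order = rownames(M)[rh$order],
                 col_order = colnames(M)[ch$order],
                 row_hclust = rh, col_hclust = ch,
                 dropped_rows = dropped),
            class = "heatmap_clustering")
}

#' Volcano-plot coordinates from a differential table
#'
#' Regenerates the volcano data (-ddcq vs -log10 q) from the
#' \code{diff_exp_table} alone; no hidden state.
#'
#' @param table \code{diff_exp_table}.
#' @return data.frame with \code{mirna_id}, \code{neg_ddcq},
#'   \code{neg_log10_q}, \code{passes}.
#' @export
volcano_data <- function(table) {
  stopifnot(inherits(table, "diff_exp_table"))
  data.frame(mirna_id = table$mirna_id, neg_ddcq = table$neg_ddcq,
             neg_log10_q = -log10(table$q_value), passes = table$passes,
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Describes a full two-stage run: a discovery dataset analyzed with
#' global-mean normalization and a validation dataset analyzed with
#' multi-reference normalization (references either supplied or selected by
#' stability ranking with \code{k} references). Each dataset is either a
#' pair of input files (\code{cq}, \code{samples}) or a \code{sim} spec (a
#' list of \code{\link{sim_config}} arguments) generated at run time.
#'
#' @param discovery,validation dataset specs: either
#'   \code{list(cq = path, samples = path)} or \code{list(sim = list(...))}.
#' @param refs optional \code{mirna_list} (or path) of validation
#'   references; \code{NULL} selects them by stability ranking.
#' @param k number of references to auto-select (default 5).
#' @param q_max,ddcq_min selection thresholds.
#' @param t_variant \code{"welch"} or \code{"student"}.
#' @param normalization_discovery,normalization_validation method names;
#'   validated before any computation.
#' @param seed integer seed used for any simulated dataset (offsets the
#'   per-dataset sim seeds deterministically).
#' @param out_dir output directory.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(discovery, validation = NULL, refs = NULL, k = 5,
                            q_max = 0.05, ddcq_min = 1.0,
                            t_variant = c("welch", "student"),
                            normalization_discovery = "global_mean",
                            normalization_validation = "multi_reference",
                            seed = 1, out_dir = tempfile("gcfmir_run_")) {
  t_variant <- match.arg(t_variant)
  if (!normalization_discovery %in% c("global_mean", "multi_reference"))
    stop("unknown normalization: ", normalization_discovery)
  if (!normalization_validation %in% c("global_mean", "multi_reference"))
    stop("unknown normalization: ", normalization_validation)
  if (q_max <= 0 || ddcq_min <= 0) stop("thresholds must be positive")
  for (ds in list(discovery, validation))
    if (!is.null(ds)) {
      if (!is.list(ds) || !(("sim" %in% names(ds)) ||
                            all(c("cq", "samples") %in% names(ds))))
        stop("dataset spec needs either sim = list(...) or cq =/samples = paths")
      if (is.null(ds$sim))
        for (f in c(ds$cq, ds$samples))
          if (!file.exists(f)) stop("input file not found: ", f)
    }
  structure(list(discovery = discovery, validation = validation, refs = refs,
                 k = as.integer(k), q_max = q_max, ddcq_min = ddcq_min,
                 t_variant = t_variant,
                 normalization_discovery = normalization_discovery,
                 normalization_validation = normalization_validation,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_dataset <- function(spec, seed_offset, base_seed, panel_id) {
  if (!is.null(spec$sim)) {
    args <- spec$sim
    if (is.null(args$seed)) args$seed <- base_seed + seed_offset
    res <- do.call(generate_cq_dataset, list(config = do.call(sim_config, args)))
    res$source <- list(type = "simulated",
                       config = unclass(do.call(sim_config, args)))
    res
  } else {
    list(table = read_cq_table(spec$cq, panel_id = panel_id),
         sheet = read_sample_sheet(spec$samples), truth = NULL,
         source = list(type = "files", cq = spec$cq, samples = spec$samples,
                       md5 = as.vector(tools::md5sum(c(spec$cq, spec$samples)))))
  }
}

normalize_stage <- function(table, method, refs, k) {
  if (method == "global_mean") {
    list(norm = global_mean_normalize(table), ranking = NULL,
         refs = mirna_list(character(), "none"))
  } else {
    ranking <- NULL
    if (is.null(refs)) {
      ranking <- rank_stability(table, k = k)
      refs <- ranking$selected_references
    } else if (!inherits(refs, "mirna_list")) {
      refs <- if (is.character(refs) && length(refs) == 1 && file.exists(refs))
        read_mirna_list(refs) else mirna_list(refs, "references")
    }
    list(norm = multi_reference_normalize(table, refs), ranking = ranking,
         refs = refs)
  }
}

#' Run the full two-stage pipeline
#'
#' Discovery stage: detection filter, normalization, differential table,
#' candidate up/down lists, PCA. Validation stage (if configured):
#' detection filter on the candidate panel data, reference selection (if
#' not supplied), multi-reference normalization, differential table,
#' hierarchical clustering, and a direction-concordance report between the
#' two stages over the candidate panel. All tables are written as CSV under
#' \code{out_dir} together with a provenance JSON recording package
#' version, parameters and input hashes (no timestamps — reruns with the
#' same config and seed are byte-identical). A stage failure aborts the run
#' with a stage-named error and removes partial outputs.
#'
#' @param config \code{pipeline_config}.
#' @return list of class \code{pipeline_result} with the in-memory objects
#'   and \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wrote <- character(0)
  fail <- function(stage, e) {
    unlink(file.path(out_dir, wrote))
    if (created) unlink(out_dir, recursive = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  emit <- function(fname, writer) {
    writer(file.path(out_dir, fname))
    wrote <<- c(wrote, fname)
  }
  res <- list(out_dir = out_dir)

  ## discovery stage
  tryCatch({
    dsc <- load_dataset(config$discovery, 101L, config$seed, "discovery")
    dsc_filt <- filter_detected(dsc$table, dsc$sheet)
    stage1 <- normalize_stage(dsc_filt, config$normalization_discovery,
                              config$refs, config$k)
    diff1 <- diff_exp(stage1$norm, dsc$sheet, variant = config$t_variant,
                      q_max = config$q_max, ddcq_min = config$ddcq_min)
    cand <- select_candidates(diff1, config$q_max, config$ddcq_min)
    pca <- pca_samples(stage1$norm)
    res$discovery <- list(data = dsc, filtered = dsc_filt,
                          norm = stage1$norm, diff = diff1,
                          candidates = cand, pca = pca)
    emit("discovery_cq.csv", function(p) write_cq_table(dsc_filt, p))
    emit("discovery_diff.csv", function(p) write_diff_exp(diff1, p))
    emit("up.txt", function(p) write_mirna_list(cand$up, p))
    emit("down.txt", function(p) write_mirna_list(cand$down, p))
    emit("discovery_pca.csv", function(p)
      utils::write.csv(data.frame(sample_id = rownames(pca$scores),
                                  round(pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                                   drop = FALSE], 6)),
                       p, row.names = FALSE, quote = FALSE))
  }, error = function(e) fail("discovery", e))

  ## validation stage
  if (!is.null(config$validation)) {
    tryCatch({
      panel <- mirna_list(c(res$discovery$candidates$up$members,
                            res$discovery$candidates$down$members),
                          name = "candidate_panel")
      val <- load_dataset(config$validation, 202L, config$seed, "validation")
      val_filt <- filter_detected(val$table, val$sheet)
      stage2 <- normalize_stage(val_filt, config$normalization_validation,
                                config$refs, config$k)
      diff2 <- diff_exp(stage2$norm, val$sheet, variant = config$t_variant,
                        q_max = config$q_max, ddcq_min = config$ddcq_min)
      panel_present <- mirna_list(
        intersect(panel$members, canonical_mirna(diff2$mirna_id)),
        name = panel$name)
      conc <- if (length(panel_present$members) >= 2)
        direction_concordance(res$discovery$diff, diff2, panel_present)
      else NULL
      heat <- tryCatch(hierarchical_heatmap(stage2$norm,
                                            panel = panel_present),
                       error = function(e) NULL)
      res$validation <- list(data = val, filtered = val_filt,
                             norm = stage2$norm, refs = stage2$refs,
                             ranking = stage2$ranking, diff = diff2,
                             concordance = conc, heatmap = heat,
                             panel = panel_present)
      emit("validation_diff.csv", function(p) write_diff_exp(diff2, p))
      if (length(stage2$refs$members))
        emit("references.txt", function(p) write_mirna_list(stage2$refs, p))
      if (!is.null(conc))
        emit("concordance.json", function(p)
          jsonlite::write_json(list(n_compared = conc$n_compared,
                                    n_agree = conc$n_agree,
                                    n_up_both = conc$n_up_both,
                                    n_down_both = conc$n_down_both,
                                    spearman_rho = conc$spearman_rho,
                                    non_comparable = conc$non_comparable),
                               p, auto_unbox = TRUE, digits = NA))
    }, error = function(e) fail("validation", e))
  }

  tryCatch({
    prov <- list(
      package = "gcfmir",
      version = as.character(utils::packageVersion("gcfmir")),
      parameters = list(q_max = config$q_max, ddcq_min = config$ddcq_min,
                        t_variant = config$t_variant, k = config$k,
                        normalization_discovery = config$normalization_discovery,
                        normalization_validation = config$normalization_validation,
                        seed = config$seed),
      inputs = list(discovery = res$discovery$data$source,
                    validation = if (!is.null(res$validation))
                      res$validation$data$source else NULL))
    emit("provenance.json", function(p)
      jsonlite::write_json(prov, p, auto_unbox = TRUE, digits = NA,
                           null = "null"))
  }, error = function(e) fail("provenance", e))

  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> outputs in", x$out_dir, "\n")
  cand <- x$discovery$candidates
  cat(sprintf("  discovery: %d miRNAs analyzed, %d up / %d down selected\n",
              nrow(x$discovery$diff), length(cand$up$members),
              length(cand$down$members)))
  if (!is.null(x$validation) && !is.null(x$validation$concordance)) {
    co <- x$validation$concordance
    cat(sprintf("  validation: %d/%d directions concordant, rho = %.3f\n",
                co$n_agree, co$n_compared, co$spearman_rho))
  }
  invisible(x)
}
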