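#' @title Normalization of Cq matrices
#' @description Two normalization routes produce delta-Cq values. Global-mean
#'   normalization (the standard for dense miRNA panels profiling hundreds of
#'   assays per sample) subtracts each sample's average Cq from each of its
#'   Cq values. Multi-reference normalization subtracts the per-sample mean
#'   Cq of a fixed reference-probe set, so the reference average becomes
#'   identical (zero) across samples — the route used for small focused
#'   panels where the global mean is no longer stable.
#' @name normalization
NULL

new_normalized_table <- function(delta_cq, detected, method, reference_set) {
  structure(list(mirna_ids = rownames(delta_cq),
                 sample_ids = colnames(delta_cq),
                 delta_cq = delta_cq, detected = detected,
                 method = method, reference_set = reference_set),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table> %s: %d miRNAs x %d samples\n",
              x$method, length(x$mirna_ids), length(x$sample_ids)))
  if (length(x$reference_set$members))
    cat("  references:", paste(x$reference_set$members, collapse = ", "), "\n")
  invisible(x)
}

#' Global-mean normalization
#'
#' delta-Cq(i, s) = Cq(i, s) - mean Cq of sample s, the mean taken over the
#' sample's own detected miRNAs (set \code{common_only = TRUE} to restrict
#' the mean to miRNAs detected in every sample). Undetected cells stay
#' missing.
#'
#' @param table \code{cq_table}.
#' @param common_only use only miRNAs detected in all samples for the mean.
#' @return \code{normalized_table} with method \code{"global_mean"}.
#' @export
global_mean_normalize <- function(table, common_only = FALSE) {
  stopifnot(inherits(table, "cq_table"))
  cq <- table$cq
  if (common_only) {
    complete <- rowSums(table$detected) == ncol(cq)
    if (!any(complete))
      stop("common_only = TRUE but no miRNA is detected in all samples")
    means <- colMeans(cq[complete, , drop = FALSE])
  } else {
    n_det <- colSums(table$detected)
    if (any(n_det == 0))
      stop("sample(s) with zero detected miRNAs: ",
           paste(table$sample_ids[n_det == 0], collapse = ", "))
    means <- colMeans(cq, na.rm = TRUE)
  }
  dcq <- sweep(cq, 2, means, "-")
  new_normalized_table(dcq, table$detected, "global_mean",
                       mirna_list(character(), name = "none"))
}

# M(j) = mean over other candidates k of SD across samples of (Cq_j - Cq_k).
# Pairwise SDs come from the candidate covariance matrix:
# Var(Cq_j - Cq_k) = C[j,j] + C[k,k] - 2 C[j,k], with the n-1 denominator.

#' Rank candidate reference miRNAs by expression stability
#'
#' Implements the pairwise-variation stability scheme: each candidate's M
#' value is the mean, over the other remaining candidates, of the standard
#' deviation across samples of their pairwise Cq differences (lower M =
#' more stable). The least stable candidate (largest M) is removed and all M
#' values are recomputed, iterating until \code{k} candidates remain; those
#' form the selected reference set. Ties at the maximum are resolved by
#' removing the lexicographically last canonical name, so the retained set
#' is deterministic.
#'
#' Only candidates detected in every sample are eligible; partially detected
#' candidates are excluded rather than imputed. M is invariant to adding a
#' per-sample constant, so ranking on raw Cq and on normalized delta-Cq
#' gives identical results.
#'
#' @param table \code{cq_table}.
#' @param candidates \code{mirna_list} of candidate names, or \code{NULL}
#'   for all miRNAs detected in 100\% of samples.
#' @param k number of references to retain (default 5).
#' @return object of class \code{stability_ranking}: \code{candidate_ids}
#'   ordered most-stable-first, \code{m_value} (final-iteration M for the
#'   retained set, at-removal M for excluded candidates),
#'   \code{exclusion_order}, and \code{selected_references} (a
#'   \code{mirna_list} of size \code{k}).
#' @export
rank_stability <- function(table, candidates = NULL, k = 5) {
  stopifnot(inherits(table, "cq_table"))
  if (!is.numeric(k) || k < 2) stop("k must be an integer >= 2")
  k <- as.integer(k)
  if (length(table$sample_ids) < 3)
    stop("stability ranking needs >= 3 samples")
  complete <- table$mirna_ids[rowSums(table$detected) == ncol(table$cq)]
  if (is.null(candidates)) {
    cand <- complete
  } else {
    stopifnot(inherits(candidates, "mirna_list"))
    canon <- canonical_mirna(table$mirna_ids)
    idx <- match(candidates$members, canon)
    if (anyNA(idx))
      stop("candidate(s) absent from table: ",
           paste(candidates$members[is.na(idx)], collapse = ", "))
    cand <- intersect(table$mirna_ids[idx], complete)
  }
  if (length(cand) < k)
    stop(sprintf("only %d fully detected candidates; need >= k = %d",
                 length(cand), k))
  X <- table$cq[cand, , drop = FALSE]
  C <- stats::cov(t(X))  # candidate-by-candidate covariance across samples
  v <- diag(C)
  pairvar <- outer(v, v, "+") - 2 * C
  pairvar[pairvar < 0] <- 0  # guard tiny negatives from rounding
  sdm <- sqrt(pairvar)       # pairwise SDs are fixed; only the set shrinks
  rowsum_sd <- rowSums(sdm)
  remaining <- cand
  exclusion_order <- character(0)
  m_at_exit <- stats::setNames(numeric(length(cand)), cand)
  while (length(remaining) > k) {
    M <- rowsum_sd[remaining] / (length(remaining) - 1)
    worst <- which(M == max(M))
    if (length(worst) > 1) {
      nm <- canonical_mirna(remaining[worst])
      worst <- worst[order(nm, decreasing = TRUE)][1]
    }
    drop_name <- remaining[worst]
    m_at_exit[drop_name] <- M[[worst]]
    exclusion_order <- c(exclusion_order, drop_name)
    remaining <- setdiff(remaining, drop_name)
    rowsum_sd <- rowsum_sd - sdm[, drop_name]
  }
  M_final <- rowsum_sd[remaining] / (length(remaining) - 1)
  m_at_exit[remaining] <- M_final
  sel <- remaining[order(M_final, canonical_mirna(remaining))]
  ordered <- c(sel, rev(exclusion_order))
  structure(list(candidate_ids = ordered,
                 m_value = m_at_exit[ordered],
                 exclusion_order = exclusion_order,
                 selected_references = mirna_list(sel, name = "selected_references")),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("<stability_ranking>\n  selected:",
      paste(x$selected_references$members, collapse = ", "), "\n")
  cat(sprintf("  M range %.3f-%.3f over %d candidates\n",
              min(x$m_value), max(x$m_value), length(x$candidate_ids)))
  invisible(x)
}

#' Multi-reference normalization
#'
#' delta-Cq(i, s) = Cq(i, s) - r_s where r_s is the mean Cq of the reference
#' probes in sample s. Every sample must detect every reference probe. By
#' construction the per-sample average delta-Cq of the references is 0 in
#' all samples.
#'
#' @param table \code{cq_table}.
#' @param references \code{mirna_list} of reference probes (or character
#'   vector).
#' @return \code{normalized_table} with method \code{"multi_reference"}.
#' @export
multi_reference_normalize <- function(table, references) {
  stopifnot(inherits(table, "cq_table"))
  if (!inherits(references, "mirna_list"))
    references <- mirna_list(references, name = "references")
  if (length(references$members) == 0) stop("empty reference set")
  canon <- canonical_mirna(table$mirna_ids)
  idx <- match(references$members, canon)
  if (anyNA(idx))
    stop("reference probe(s) absent from table: ",
         paste(references$members[is.na(idx)], collapse = ", "))
  det <- table$detected[idx, , drop = FALSE]
  if (!all(det)) {
    bad <- which(!det, arr.ind = TRUE)
    msgs <- apply(bad, 1, function(b)
      sprintf("%s in sample %s", references$members[b[1]],
              table$sample_ids[b[2]]))
    stop("undetected reference probe(s): ", paste(msgs, collapse = "; "))
  }
  r <- colMeans(table$cq[idx, , drop = FALSE])
  dcq <- sweep(table$cq, 2, r, "-")
  new_normalized_table(dcq, table$detected, "multi_reference", references)
}
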