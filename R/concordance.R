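#' Spearman rank correlation (average ranks for ties)
#'
#' Ranks both vectors with average ties, then computes the Pearson
#' correlation of the ranks in closed form. Pairs with a missing value in
#' either vector are dropped. No p value is attached.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1]; \code{NA} if fewer than 2 complete pairs
#'   or a rank vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sx * sy)
}

lookup_neg_ddcq <- function(table, members) {
  canon <- canonical_mirna(table$mirna_id)
  table$neg_ddcq[match(members, canon)]
}

#' Direction concordance between two differential tables
#'
#' Compares the sign of neg_ddcq per panel miRNA across two independently
#' analyzed sample sets. A miRNA absent from either table (or with a missing
#' effect) is listed non-comparable and excluded from the agreement
#' denominator. Agreement requires equal nonzero signs; an exact zero
#' counts as disagreement with any nonzero sign and is tallied separately.
#' Spearman rho is computed on the paired neg_ddcq values of the comparable
#' miRNAs.
#'
#' @param t1,t2 \code{diff_exp_table}s for the two sample sets.
#' @param panel \code{mirna_list} of miRNAs to compare.
#' @return object of class \code{concordance_report}: per-miRNA data.frame
#'   (\code{detail}), \code{n_compared}, \code{n_agree}, \code{n_up_both},
#'   \code{n_down_both}, \code{n_zero}, \code{spearman_rho},
#'   \code{non_comparable}.
#' @export
direction_concordance <- function(t1, t2, panel) {
  stopifnot(inherits(t1, "diff_exp_table"), inherits(t2, "diff_exp_table"),
            inherits(panel, "mirna_list"))
  e1 <- lookup_neg_ddcq(t1, panel$members)
  e2 <- lookup_neg_ddcq(t2, panel$members)
  comparable <- !is.na(e1) & !is.na(e2)
  s1 <- sign(e1); s2 <- sign(e2)
  agree <- comparable & s1 == s2 & s1 != 0
  detail <- data.frame(mirna_id = panel$members,
                       neg_ddcq_1 = e1, neg_ddcq_2 = e2,
                       sign_1 = s1, sign_2 = s2,
                       comparable = comparable, agree = agree,
                       stringsAsFactors = FALSE)
  structure(list(detail = detail,
                 n_compared = sum(comparable),
                 n_agree = sum(agree),
                 n_up_both = sum(agree & s1 > 0),
                 n_down_both = sum(agree & s1 < 0),
                 n_zero = sum(comparable & (s1 == 0 | s2 == 0)),
                 spearman_rho = spearman_rho(e1[comparable], e2[comparable]),
                 non_comparable = panel$members[!comparable]),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d directions agree (%d up, %d down); rho = %.3f\n",
              x$n_agree, x$n_compared, x$n_up_both, x$n_down_both,
              x$spearman_rho))
  if (length(x$non_comparable))
    cat("  non-comparable:", paste(x$non_comparable, collapse = ", "), "\n")
  invisible(x)
}

#' Overlaps among named miRNA lists
#'
#' Exact-name set algebra on canonicalized lists: every region of the Venn
#' partition of the union is reported with its membership pattern, size and
#' members.
#'
#' @param lists named list of \code{mirna_list}s (or character vectors);
#'   at least 2.
#' @return data.frame with one logical column per input list plus \code{n}
#'   and comma-joined \code{members}; attribute \code{union_size}.
#' @export
list_overlap <- function(lists) {
  if (length(lists) < 2) stop("need at least 2 lists")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop("lists must be named")
  sets <- lapply(lists, function(l)
    if (inherits(l, "mirna_list")) l$members else canonical_mirna(l))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-2^length(sets), ,
                                                                   drop = FALSE]
  names(patterns) <- names(sets)
  rows <- lapply(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, , drop = TRUE])
    in_region <- apply(membership, 1, function(m) all(m == pat))
    mem <- universe[in_region]
    cbind(patterns[i, , drop = FALSE],
          data.frame(n = length(mem),
                     members = paste(sort(mem), collapse = ","),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "union_size") <- length(universe)
  out
}

#' Matched-pair expression differences
#'
#' Single-pair analogue of neg_ddcq: for each (healthy, periodontitis)
#' subject pair, delta-Cq(healthy) - delta-Cq(periodontitis) per panel
#' miRNA (positive = up-regulated in the periodontitis member). A cell
#' undetected in either member is non-comparable (\code{NA}) for that pair.
#'
#' @param norm \code{normalized_table}.
#' @param sheet \code{sample_sheet} (used to check pair group labels when
#'   available).
#' @param pairs list of length-2 character vectors
#'   \code{c(healthy_id, perio_id)}, or a 2-column matrix/data.frame.
#' @param panel \code{mirna_list}.
#' @return list: \code{diff} (miRNA-by-pair matrix of per-pair neg_ddcq),
#'   \code{sign_agreement} (per-miRNA: do all comparable pairs share a
#'   nonzero sign?), \code{agreement_fraction}.
#' @export
matched_pair_diff <- function(norm, sheet, pairs, panel) {
  stopifnot(inherits(norm, "normalized_table"), inherits(panel, "mirna_list"))
  if (is.matrix(pairs) || is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(unlist(pairs[i, 1:2])))
  canon <- canonical_mirna(norm$mirna_ids)
  ridx <- match(panel$members, canon)
  if (anyNA(ridx))
    stop("panel miRNA(s) absent from table: ",
         paste(panel$members[is.na(ridx)], collapse = ", "))
  cols <- vapply(pairs, function(pr) {
    i <- match(pr, norm$sample_ids)
    if (anyNA(i))
      stop("pair member(s) missing from table: ",
           paste(pr[is.na(i)], collapse = ", "))
    if (!is.null(sheet)) {
      g <- sheet$group[match(pr, sheet$sample_id)]
      if (!anyNA(g) && !identical(g, c("healthy", "periodontitis")))
        stop("pair (", paste(pr, collapse = ", "),
             ") must be (healthy, periodontitis)")
    }
    norm$delta_cq[ridx, i[1]] - norm$delta_cq[ridx, i[2]]
  }, numeric(length(ridx)))
  cols <- matrix(cols, nrow = length(ridx),
                 dimnames = list(panel$members,
                                 vapply(pairs, paste, "", collapse = "_vs_")))
  sgn <- sign(cols)
  agreement <- apply(sgn, 1, function(s) {
    s <- s[!is.na(s)]
    length(s) > 0 && all(s != 0) && length(unique(s)) == 1
  })
  list(diff = cols, sign_agreement = agreement,
       agreement_fraction = mean(agreement))
}
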