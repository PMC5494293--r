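#' Per-miRNA group effect on delta-Cq
#'
#' Group means over detected values only. The effect size is
#' ddcq = mean(periodontitis) - mean(healthy); because a lower Cq means a
#' higher abundance, the plotted relative expression ratio is its negation,
#' neg_ddcq = -ddcq, positive when the miRNA is up-regulated in
#' periodontitis.
#'
#' @param dcq_h,dcq_p numeric delta-Cq vectors for the healthy and
#'   periodontitis samples; \code{NA} = undetected.
#' @return list with \code{n_h}, \code{n_p}, \code{mean_dcq_h},
#'   \code{mean_dcq_p}, \code{ddcq}, \code{neg_ddcq}, \code{direction}
#'   (\code{"up"}, \code{"down"} or \code{"none"}); all effect fields
#'   \code{NA} when a group has no detected values.
#' @export
group_effect <- function(dcq_h, dcq_p) {
  h <- dcq_h[!is.na(dcq_h)]
  p <- dcq_p[!is.na(dcq_p)]
  if (length(h) == 0 || length(p) == 0)
    return(list(n_h = length(h), n_p = length(p),
                mean_dcq_h = NA_real_, mean_dcq_p = NA_real_,
                ddcq = NA_real_, neg_ddcq = NA_real_, direction = "none"))
  mh <- mean(h); mp <- mean(p)
  dd <- mp - mh
  ndd <- -dd
  list(n_h = length(h), n_p = length(p), mean_dcq_h = mh, mean_dcq_p = mp,
       ddcq = dd, neg_ddcq = ndd,
       direction = if (ndd > 0) "up" else if (ndd < 0) "down" else "none")
}

#' Two-sample t test on delta-Cq values
#'
#' Closed-form Student (pooled variance) or Welch t statistic with two-sided
#' p value. Degenerate inputs: fewer than 2 detected values in a group, or
#' both variances zero with equal means, yield \code{NA} (flagged not
#' testable); both variances zero with unequal means yields the limiting
#' p = 0 with a warning.
#'
#' @param x,y numeric vectors (detected delta-Cq per group); \code{NA}
#'   dropped.
#' @param variant \code{"welch"} (default) or \code{"student"}.
#' @return list with \code{t_stat}, \code{df}, \code{p_value}.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    return(list(t_stat = NA_real_, df = NA_real_, p_value = NA_real_))
  vx <- stats::var(x); vy <- stats::var(y)
  mdiff <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (mdiff == 0)
      return(list(t_stat = NA_real_, df = NA_real_, p_value = NA_real_))
    warning("zero variance in both groups with unequal means; p reported as 0")
    return(list(t_stat = sign(mdiff) * Inf, df = nx + ny - 2, p_value = 0))
  }
  if (variant == "student") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2x <- vx / nx; se2y <- vy / ny
    se <- sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  }
  t <- mdiff / se
  list(t_stat = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q values: q(i) = min over j with p(j) >= p(i) of m * p(j) /
#' rank(j), capped at 1, where m counts the non-missing p values. Missing p
#' values are excluded from m and returned missing.
#'
#' @param p numeric vector of p values in [0, 1] (\code{NA} allowed).
#' @return numeric vector of q values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(q)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)   # largest p first
  qv <- pmin(1, cummin(m * pv[o] / seq(m, 1)))
  q[ok] <- qv[order(o)]
  q
}

#' Per-miRNA differential expression table
#'
#' For each miRNA: available-case group means, ddcq / neg_ddcq, a two-sample
#' t test (minimum 2 detected values per group — below that the miRNA is
#' reported descriptively without p/q), BH-adjusted q values over all tested
#' miRNAs, direction, and a pass flag at the selection thresholds.
#' Rows are sorted by q value then canonical name (untested rows last).
#'
#' @param norm \code{normalized_table}.
#' @param sheet \code{sample_sheet} covering the samples.
#' @param variant t-test variant, \code{"welch"} (default) or
#'   \code{"student"}.
#' @param q_max,ddcq_min selection thresholds for the \code{passes} flag
#'   (strict inequalities: q < q_max and |ddcq| > ddcq_min).
#' @param min_n minimum detected values per group for testing (default 2).
#' @return data.frame of class \code{diff_exp_table}; attributes record the
#'   contrast metadata (set_id, normalization method, t variant).
#' @export
diff_exp <- function(norm, sheet, variant = c("welch", "student"),
                     q_max = 0.05, ddcq_min = 1.0, min_n = 2) {
  stopifnot(inherits(norm, "normalized_table"), inherits(sheet, "sample_sheet"))
  variant <- match.arg(variant)
  grp <- sheet$group[match(norm$sample_ids, sheet$sample_id)]
  if (anyNA(grp))
    stop("samples absent from sheet: ",
         paste(norm$sample_ids[is.na(grp)], collapse = ", "))
  for (g in GROUP_LEVELS)
    if (!any(grp == g)) stop("no samples in group '", g, "'")
  H <- norm$delta_cq[, grp == "healthy", drop = FALSE]
  P <- norm$delta_cq[, grp == "periodontitis", drop = FALSE]

  n_h <- rowSums(!is.na(H)); n_p <- rowSums(!is.na(P))
  mh <- rowMeans(H, na.rm = TRUE); mh[n_h == 0] <- NA_real_
  mp <- rowMeans(P, na.rm = TRUE); mp[n_p == 0] <- NA_real_
  dd <- mp - mh
  ndd <- -dd

  # vectorized t statistics on available cases
  row_var <- function(M, n, mu) {
    ss <- rowSums(sweep(M, 1, mu, "-")^2, na.rm = TRUE)
    v <- ss / (n - 1)
    v[n < 2] <- NA_real_
    v
  }
  vh <- row_var(H, n_h, mh); vp <- row_var(P, n_p, mp)
  testable <- n_h >= min_n & n_p >= min_n & !is.na(vh) & !is.na(vp) &
    (vh > 0 | vp > 0)
  t_stat <- df <- p <- rep(NA_real_, nrow(H))
  if (variant == "student") {
    sp2 <- ((n_h - 1) * vh + (n_p - 1) * vp) / (n_h + n_p - 2)
    se <- sqrt(sp2 * (1 / n_h + 1 / n_p))
    dof <- n_h + n_p - 2
  } else {
    se2h <- vh / n_h; se2p <- vp / n_p
    se <- sqrt(se2h + se2p)
    dof <- (se2h + se2p)^2 / (se2h^2 / (n_h - 1) + se2p^2 / (n_p - 1))
  }
  t_stat[testable] <- (mp - mh)[testable] / se[testable]
  df[testable] <- dof[testable]
  p[testable] <- 2 * stats::pt(-abs(t_stat[testable]), df[testable])
  degenerate <- n_h >= min_n & n_p >= min_n & !is.na(vh) & !is.na(vp) &
    vh == 0 & vp == 0 & dd != 0
  if (any(degenerate)) {
    warning(sum(degenerate), " miRNA(s) with zero variance in both groups ",
            "and unequal means; p reported as 0")
    t_stat[degenerate] <- sign(dd[degenerate]) * Inf
    p[degenerate] <- 0
  }
  q <- bh_adjust(p)

  direction <- ifelse(is.na(ndd) | ndd == 0, "none",
                      ifelse(ndd > 0, "up", "down"))
  passes <- !is.na(q) & !is.na(ndd) & q < q_max & abs(ndd) > ddcq_min

  out <- data.frame(mirna_id = norm$mirna_ids, n_healthy = n_h, n_perio = n_p,
                    mean_dcq_h = mh, mean_dcq_p = mp, ddcq = dd,
                    neg_ddcq = ndd, t_stat = t_stat, df = df, p_value = p,
                    q_value = q, direction = direction, passes = passes,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(is.na(out$q_value), out$q_value, canonical_mirna(out$mirna_id))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_id") <- unique(sheet$set_id[match(norm$sample_ids,
                                                   sheet$sample_id)])
  attr(out, "normalization") <- norm$method
  attr(out, "t_variant") <- variant
  attr(out, "q_max") <- q_max
  attr(out, "ddcq_min") <- ddcq_min
  class(out) <- c("diff_exp_table", "data.frame")
  out
}

#' Select up/down candidate miRNAs
#'
#' Strict thresholds matching the selection rule: q < \code{q_max} and
#' neg_ddcq > \code{ddcq_min} (up) or neg_ddcq < -\code{ddcq_min} (down).
#' A record at exactly the boundary is excluded.
#'
#' @param table \code{diff_exp_table}.
#' @param q_max FDR threshold (default 0.05).
#' @param ddcq_min absolute ddcq threshold in cycles (default 1.0).
#' @return list with \code{up} and \code{down} \code{mirna_list}s (disjoint).
#' @export
select_candidates <- function(table, q_max = 0.05, ddcq_min = 1.0) {
  stopifnot(inherits(table, "diff_exp_table"))
  sig <- !is.na(table$q_value) & table$q_value < q_max & !is.na(table$neg_ddcq)
  up <- table$mirna_id[sig & table$neg_ddcq > ddcq_min]
  down <- table$mirna_id[sig & table$neg_ddcq < -ddcq_min]
  list(up = mirna_list(up, name = "up"), down = mirna_list(down, name = "down"))
}

#' Write a differential-expression table to CSV
#'
#' @param table \code{diff_exp_table}.
#' @param path destination path.
#' @return invisibly, the path.
#' @export
write_diff_exp <- function(table, path) {
  stopifnot(inherits(table, "diff_exp_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
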