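#' Cq table: quantitation-cycle matrix with detection mask
#'
#' The universal input of the pipeline: a miRNA-by-sample matrix of
#' quantitation cycles together with a logical detection mask. Undetected
#' cells carry \code{NA} in the Cq matrix — they are never imputed at the
#' censoring cycle. All detected Cq values must lie strictly between 0 and
#' the censoring threshold (40 cycles by default: an amplification that has
#' not crossed threshold by cycle 40 is treated as not detected).
#'
#' @param cq numeric matrix, rows miRNAs (rownames required), columns samples
#'   (colnames required). \code{NA} marks undetected cells.
#' @param panel_id free-text panel label, e.g. \code{"discovery"} or
#'   \code{"custom40"}.
#' @param censor_at detection cutoff in cycles; values \code{>= censor_at}
#'   are marked undetected.
#' @return object of class \code{cq_table} with fields \code{mirna_ids},
#'   \code{sample_ids}, \code{cq}, \code{detected}, \code{panel_id},
#'   \code{censor_at}.
#' @export
cq_table <- function(cq, panel_id = "custom", censor_at = 40) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop("cq must be a numeric matrix")
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("cq must have rownames (miRNAs) and colnames (samples)")
  mirna_ids <- trimws(rownames(cq))
  sample_ids <- trimws(colnames(cq))
  dup_m <- duplicated(canonical_mirna(mirna_ids))
  if (any(dup_m))
    stop("duplicate miRNA ids: ", paste(unique(mirna_ids[dup_m]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  cq[!is.na(cq) & cq >= censor_at] <- NA_real_
  if (any(!is.na(cq) & cq <= 0))
    stop("detected Cq values must be positive")
  detected <- !is.na(cq)
  rownames(cq) <- rownames(detected) <- mirna_ids
  colnames(cq) <- colnames(detected) <- sample_ids
  structure(list(mirna_ids = mirna_ids, sample_ids = sample_ids,
                 cq = cq, detected = detected,
                 panel_id = as.character(panel_id)[1],
                 censor_at = censor_at),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> panel '%s': %d miRNAs x %d samples, %.1f%% detected\n",
              x$panel_id, length(x$mirna_ids), length(x$sample_ids),
              100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.cq_table <- function(x) dim(x$cq)

#' Read a Cq matrix from a delimited file
#'
#' Expects miRNA rows and sample columns: first column miRNA id, header row
#' sample ids. Blank cells, configured sentinels and numeric values at or
#' above the censoring cycle are marked undetected. Rows are always miRNAs;
#' use \code{transpose = TRUE} for sample-by-miRNA files (no orientation
#' auto-detection is attempted).
#'
#' @param path file path (.csv comma-separated, otherwise tab-separated; use
#'   \code{sep} to override).
#' @param panel_id panel label stored on the table.
#' @param censor_at detection cutoff in cycles (default 40).
#' @param na_strings cell values treated as undetected.
#' @param sep field separator; default chosen from the file extension.
#' @param transpose set \code{TRUE} if rows are samples.
#' @return \code{cq_table}.
#' @export
read_cq_table <- function(path, panel_id = "custom", censor_at = 40,
                          na_strings = c("", "NA", "Undetermined", "Undetermined Cq"),
                          sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("Cq file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           na.strings = character(0),  # sentinels handled below
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("Cq file must have an id column plus >= 1 sample column")
  hdr <- colnames(raw)[-1]  # data.frame subsetting would repair duplicates
  if (anyDuplicated(hdr))
    stop("duplicate sample ids: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  ids <- trimws(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (j in seq_len(ncol(vals))) {
    cell <- trimws(vals[, j])
    is_na <- cell %in% na_strings
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- !is_na & is.na(parsed)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("non-numeric Cq cell '%s' at row '%s', column '%s'",
                   cell[i], ids[i], colnames(vals)[j]))
    }
    parsed[is_na] <- NA_real_
    num[, j] <- parsed
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  cq_table(num, panel_id = panel_id, censor_at = censor_at)
}

#' Write a Cq table to CSV
#'
#' Undetected cells are written as empty fields, so a write/read round trip
#' reproduces both the values and the detection mask exactly.
#'
#' @param table \code{cq_table}.
#' @param path destination path.
#' @return invisibly, the path.
#' @export
write_cq_table <- function(table, path) {
  stopifnot(inherits(table, "cq_table"))
  out <- format(table$cq, trim = TRUE, digits = 15)
  out[!table$detected] <- ""
  df <- data.frame(mirna_id = table$mirna_ids, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("mirna_id", table$sample_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

GROUP_LEVELS <- c("healthy", "periodontitis")

#' Read a sample sheet
#'
#' A CSV with required columns \code{sample_id}, \code{group},
#' \code{set_id}; optional typed columns \code{age}, \code{gender},
#' \code{diagnosis}, \code{mean_pd_mm}, \code{bop}. Unknown extra columns
#' are preserved untouched. Group labels are case-normalized and must be
#' \code{healthy} or \code{periodontitis}; set labels are normalized to the
#' form \code{set1} (so \code{"Set #1"} is accepted).
#'
#' @param path file path.
#' @return data.frame of class \code{sample_sheet}.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        strip.white = TRUE)
  sample_sheet(df)
}

#' Construct a sample sheet from a data.frame
#'
#' @param df data.frame with at least \code{sample_id}, \code{group},
#'   \code{set_id}.
#' @return validated data.frame of class \code{sample_sheet}.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "group", "set_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no samples in sample sheet")
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  grp <- tolower(trimws(as.character(df$group)))
  bad <- !(grp %in% GROUP_LEVELS)
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(df$group[bad]), collapse = ", "),
         " (expected healthy/periodontitis)")
  df$group <- grp
  set <- tolower(gsub("[ #]", "", as.character(df$set_id)))
  if (any(!nzchar(set) | is.na(set))) stop("set_id must be non-missing")
  df$set_id <- set
  if ("age" %in% names(df)) df$age <- as.integer(df$age)
  if ("gender" %in% names(df)) {
    g <- toupper(substr(trimws(as.character(df$gender)), 1, 1))
    if (any(!is.na(g) & !(g %in% c("M", "F"))))
      stop("gender must be M or F")
    df$gender <- g
  }
  if ("mean_pd_mm" %in% names(df)) df$mean_pd_mm <- as.numeric(df$mean_pd_mm)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Summarize cohort metadata
#'
#' Per (set, group) counts, mean age (1 decimal) and gender composition.
#'
#' @param sheet \code{sample_sheet}.
#' @return data.frame with one row per (set_id, group).
#' @export
summarize_cohort <- function(sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  key <- interaction(sheet$set_id, sheet$group, drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- sheet[key == k, , drop = FALSE]
    data.frame(set_id = sub$set_id[1], group = sub$group[1], n = nrow(sub),
               mean_age = if ("age" %in% names(sub))
                 round(mean(sub$age, na.rm = TRUE), 1) else NA_real_,
               n_male = if ("gender" %in% names(sub))
                 sum(sub$gender == "M", na.rm = TRUE) else NA_integer_,
               n_female = if ("gender" %in% names(sub))
                 sum(sub$gender == "F", na.rm = TRUE) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$set_id, out$group), , drop = FALSE]
}

#' Restrict a Cq table to analyzable miRNAs
#'
#' Keeps exactly those miRNAs detected in at least one healthy AND at least
#' one periodontitis sample; all others are dropped. The retained/dropped
#' counts are attached as attributes. Idempotent.
#'
#' @param table \code{cq_table}.
#' @param sheet \code{sample_sheet} covering the table's samples.
#' @return filtered \code{cq_table} with attributes \code{n_retained} and
#'   \code{n_dropped}.
#' @export
filter_detected <- function(table, sheet) {
  stopifnot(inherits(table, "cq_table"), inherits(sheet, "sample_sheet"))
  grp <- sheet$group[match(table$sample_ids, sheet$sample_id)]
  if (anyNA(grp))
    stop("samples absent from sheet: ",
         paste(table$sample_ids[is.na(grp)], collapse = ", "))
  for (g in GROUP_LEVELS)
    if (!any(grp == g)) stop("no samples in group '", g, "'")
  in_h <- rowSums(table$detected[, grp == "healthy", drop = FALSE]) >= 1
  in_p <- rowSums(table$detected[, grp == "periodontitis", drop = FALSE]) >= 1
  keep <- in_h & in_p
  out <- cq_table(table$cq[keep, , drop = FALSE], panel_id = table$panel_id,
                  censor_at = table$censor_at)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
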