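#' Canonicalize miRNA names
#'
#' Maps assay labels to a canonical form used for all cross-table matching:
#' whitespace is trimmed, the name is lower-cased, and a missing
#' \code{"hsa-"} species prefix is prepended. Star names (e.g.
#' \code{"miR-205*"}) are kept verbatim apart from these rules and match only
#' by exact canonical string; no miRBase version remapping is attempted.
#'
#' @param x character vector of miRNA names.
#' @return character vector of canonical names.
#' @examples
#' canonical_mirna(c("  hsa-miR-223-3p", "miR-21-5p", "HSA-MIR-205*"))
#' @export
canonical_mirna <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  x <- trimws(x)
  x <- tolower(x)
  no_prefix <- !startsWith(x, "hsa-") & nzchar(x)
  x[no_prefix] <- paste0("hsa-", x[no_prefix])
  x
}

#' Create an ordered miRNA list
#'
#' An ordered set of canonical miRNA names with a label. Duplicates after
#' canonicalization are collapsed, keeping first occurrence order.
#'
#' @param members character vector of miRNA names (canonicalized on entry).
#' @param name label for the list.
#' @return object of class \code{mirna_list}.
#' @export
mirna_list <- function(members, name = "mirna_list") {
  members <- canonical_mirna(members)
  members <- members[nzchar(members)]
  members <- members[!duplicated(members)]
  structure(list(name = as.character(name)[1], members = members),
            class = "mirna_list")
}

#' @export
print.mirna_list <- function(x, ...) {
  cat(sprintf("<mirna_list> %s: %d miRNAs\n", x$name, length(x$members)))
  if (length(x$members)) {
    shown <- utils::head(x$members, 8L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$members) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.mirna_list <- function(x) length(x$members)

#' @export
as.character.mirna_list <- function(x, ...) x$members

#' Read a miRNA list from a plain-text file
#'
#' One name per line; blank lines and lines starting with \code{#} are
#' ignored.
#'
#' @param path file path.
#' @param name label; defaults to the file name without extension.
#' @return \code{mirna_list}.
#' @export
read_mirna_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("miRNA list file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mirna_list(lines, name = name)
}

#' Write a miRNA list to a plain-text file
#'
#' @param x \code{mirna_list}.
#' @param path destination path.
#' @return invisibly, the path.
#' @export
write_mirna_list <- function(x, path) {
  stopifnot(inherits(x, "mirna_list"))
  writeLines(x$members, path)
  invisible(path)
}
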