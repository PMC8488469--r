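#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file of amino-acid
#' sequences. The record identifier is the first whitespace-delimited token
#' of the header; sequences are upper-cased and record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector: names are protein identifiers,
#'   values are amino-acid sequences.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("malformed header: record ", which(is.na(ids) | !nzchar(ids))[1L],
         " has an empty identifier")
  seqs <- toupper(as.character(set))
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("empty sequence for ", ids[empty[1L]])
  if (anyDuplicated(ids))
    warning("duplicate identifiers in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: the write-then-read round trip preserves
#' identifiers and sequences exactly.
#'
#' @param records Named character vector of sequences (names = identifiers).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.character(records), !is.null(names(records)))
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a labelled protein-pair list
#'
#' Reads a headerless tab- or comma-separated file with three columns:
#' first protein id, second protein id, and a binary interaction label
#' (1 = interacting, 0 = non-interacting). Duplicate rows are kept with a
#' warning.
#'
#' @param path Path to the pair list.
#' @return A data.frame with columns `idA`, `idB` (character) and
#'   `label` (integer in \{0, 1\}), in file order.
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) stop("pair list not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pair list: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("pair list line ", bad[1L], ": expected 3 ",
         if (sep == "\t") "tab" else "comma", "-separated fields")
  idA <- trimws(vapply(parts, `[`, character(1), 1L))
  idB <- trimws(vapply(parts, `[`, character(1), 2L))
  lab <- trimws(vapply(parts, `[`, character(1), 3L))
  if (!all(lab %in% c("0", "1")))
    stop("pair list line ", which(!lab %in% c("0", "1"))[1L],
         ": label must be 0 or 1, got '",
         lab[!lab %in% c("0", "1")][1L], "'")
  pairs <- data.frame(idA = idA, idB = idB, label = as.integer(lab),
                      stringsAsFactors = FALSE)
  ndup <- sum(duplicated(pairs))
  if (ndup > 0)
    warning(ndup, " duplicate pair row(s) in ", path, "; kept")
  pairs
}

#' Write a labelled protein-pair list
#'
#' @param pairs data.frame with columns `idA`, `idB`, `label`.
#' @param path Output path; written tab-separated without a header.
#' @return Invisibly, `path`.
#' @export
write_pair_list <- function(pairs, path) {
  stopifnot(all(c("idA", "idB", "label") %in% names(pairs)))
  utils::write.table(pairs[, c("idA", "idB", "label")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Parses the text matrix written by `psiblast -out_ascii_pssm`: header
#' lines, one row per sequence position carrying the position index, the
#' query residue, 20 integer log-odds columns and 20 weighted-percentage
#' columns, then trailing statistics. Only the first 20 numeric columns
#' (the log-odds block) are returned.
#'
#' @param path Path to the ASCII PSSM file.
#' @return A `ppi_profile`: numeric U x 20 matrix (one row per position,
#'   columns in [AA_ORDER]) with attributes `source = "pssm"` and
#'   `residues` (the per-position query residues).
#' @seealso [emit_ascii_pssm()] for the exact-round-trip fixture writer.
#' @export
parse_ascii_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  residues <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1L]]
    if (length(tok) < 2L) next
    if (!grepl("^[0-9]+$", tok[[1L]])) next
    if (!grepl("^[A-Za-z]$", tok[[2L]])) next
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    num <- num[!is.na(num)]
    if (length(num) < 40L)
      stop("PSSM file ", path, " line ", i, ": position row has ",
           length(num), " numeric columns, expected at least 40")
    rows[[length(rows) + 1L]] <- num[1:20]
    residues[[length(residues) + 1L]] <- toupper(tok[[2L]])
  }
  if (!length(rows))
    stop("PSSM file ", path, ": no position rows found")
  values <- do.call(rbind, rows)
  new_profile(values, source = "pssm", residues = residues)
}

#' Construct a protein profile object
#'
#' A profile is a U x 20 real matrix with one row per sequence position and
#' one column per amino acid in the canonical order [AA_ORDER].
#'
#' @param values Numeric U x 20 matrix with finite entries.
#' @param source One of `"pssm"`, `"smr"`, `"synthetic"`.
#' @param residues Optional character vector of per-position residues.
#' @return A numeric matrix of class `ppi_profile`.
#' @export
new_profile <- function(values, source = c("pssm", "smr", "synthetic"),
                        residues = NULL) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (ncol(values) != 20L)
    stop("profile must have exactly 20 columns, got ", ncol(values))
  if (nrow(values) < 1L) stop("profile must have at least one row")
  if (!all(is.finite(values))) stop("profile contains non-finite entries")
  storage.mode(values) <- "double"
  colnames(values) <- AA_ORDER
  structure(values, class = c("ppi_profile", class(values)),
            source = source, residues = residues)
}

#' @export
print.ppi_profile <- function(x, ...) {
  cat(sprintf("<ppi_profile> %d x 20 (source: %s)\n",
              nrow(x), attr(x, "source")))
  invisible(x)
}

fmt_pct <- function(x) sprintf("%.2f", 100 * x)
fmt_auc <- function(x) sprintf("%.4f", x)

#' Format a cross-validation report as an aligned table
#'
#' Renders per-fold rows plus an `Average` row. Percentage metrics
#' (Acc/PR/Sens/Spec/MCC) are shown to two decimals, AUC to four; the
#' average row shows `mean +/- sample SD` (n-1 denominator).
#'
#' @param report A `cv_report` from [run_cv()].
#' @return Character vector of table lines.
#' @export
format_cv_table <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  f <- report$folds
  if (is.null(f) || nrow(f) == 0L) stop("empty report: no fold rows")
  hdr <- c("Testing set", "Acc (%)", "PR (%)", "Sens (%)", "Spec (%)",
           "MCC (%)", "AUC")
  body <- lapply(seq_len(nrow(f)), function(i) {
    c(as.character(f$fold[i]),
      fmt_pct(f$acc[i]), fmt_pct(f$pr[i]), fmt_pct(f$sens[i]),
      fmt_pct(f$spec[i]), fmt_pct(f$mcc[i]), fmt_auc(f$auc[i]))
  })
  avg <- c("Average",
           paste0(fmt_pct(report$mean[["acc"]]),  " +/- ", fmt_pct(report$sd[["acc"]])),
           paste0(fmt_pct(report$mean[["pr"]]),   " +/- ", fmt_pct(report$sd[["pr"]])),
           paste0(fmt_pct(report$mean[["sens"]]), " +/- ", fmt_pct(report$sd[["sens"]])),
           paste0(fmt_pct(report$mean[["spec"]]), " +/- ", fmt_pct(report$sd[["spec"]])),
           paste0(fmt_pct(report$mean[["mcc"]]),  " +/- ", fmt_pct(report$sd[["mcc"]])),
           paste0(fmt_auc(report$mean[["auc"]]),  " +/- ", fmt_auc(report$sd[["auc"]])))
  rows <- c(list(hdr), body, list(avg))
  widths <- apply(matrix(nchar(unlist(rows)), ncol = 7, byrow = TRUE), 2, max)
  vapply(rows, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "),
    character(1))
}

#' Write a cross-validation report to disk
#'
#' Writes two renderings: a machine-readable `key = value` block (per-fold
#' and aggregate metrics) followed by the aligned human-readable table of
#' [format_cv_table()].
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  f <- report$folds
  if (is.null(f) || nrow(f) == 0L) stop("empty report: no fold rows")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write report to ", path))
  on.exit(close(con))
  kv <- character()
  metrics <- c("acc", "pr", "sens", "spec", "mcc", "auc")
  for (i in seq_len(nrow(f)))
    for (m in metrics)
      kv <- c(kv, sprintf("fold%d.%s = %.10g", f$fold[i], m, f[[m]][i]))
  for (m in metrics) {
    kv <- c(kv, sprintf("mean.%s = %.10g", m, report$mean[[m]]))
    kv <- c(kv, sprintf("sd.%s = %.10g", m, report$sd[[m]]))
  }
  writeLines(c(kv, "", format_cv_table(report)), con)
  invisible(path)
}

#' Write ROC points to a CSV file
#'
#' @param points data.frame with columns `fpr`, `tpr`, `threshold`
#'   (as produced by [roc_auc()]).
#' @param path Output path; written as CSV with header `fpr,tpr,threshold`.
#' @return Invisibly, `path`.
#' @export
write_roc <- function(points, path) {
  stopifnot(all(c("fpr", "tpr", "threshold") %in% names(points)))
  utils::write.csv(points[, c("fpr", "tpr", "threshold")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
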