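#' PSI-BLAST configuration
#'
#' Bundles the settings used to derive a PSSM profile for one protein:
#' three search iterations against a formatted protein database with the
#' profile-inclusion E-value threshold cut off at 0.001.
#'
#' @param db_path Path to a formatted protein BLAST database (e.g.
#'   SwissProt); supplied by the user, never bundled.
#' @param iterations Number of PSI-BLAST iterations (default 3).
#' @param evalue Profile inclusion threshold (`-inclusion_ethresh`,
#'   default 0.001).
#' @param executable Name or path of the `psiblast` program.
#' @return A list of class `psiblast_config`.
#' @export
psiblast_config <- function(db_path, iterations = 3L, evalue = 0.001,
                            executable = "psiblast") {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("iterations must be a positive integer")
  if (!is.numeric(evalue) || evalue <= 0) stop("evalue must be > 0")
  structure(list(db_path = db_path, iterations = iterations,
                 evalue = evalue, executable = executable),
            class = "psiblast_config")
}

#' Compute a PSSM profile with PSI-BLAST
#'
#' Invokes the external `psiblast` program on one protein sequence,
#' requesting an ASCII PSSM (`-out_ascii_pssm`), and parses it with
#' [parse_ascii_pssm()]. When the search finds no homologs and no PSSM is
#' produced, the BLOSUM62 substitution profile ([smr_profile()]) is
#' returned instead with a warning, so batch runs complete.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence.
#' @param cfg A [psiblast_config()].
#' @return A `ppi_profile` with one row per residue.
#' @export
run_psiblast <- function(id, sequence, cfg) {
  stopifnot(inherits(cfg, "psiblast_config"))
  exe <- Sys.which(cfg$executable)
  if (!nzchar(exe))
    stop("PSI-BLAST executable not found: '", cfg$executable,
         "'; install BLAST+ or set the executable path")
  tmp <- tempfile("psiblast_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  query <- file.path(tmp, "query.fasta")
  pssm <- file.path(tmp, "query.pssm")
  hits <- file.path(tmp, "hits.txt")
  seqs <- stats::setNames(sequence, id)
  write_fasta(seqs, query)
  args <- c("-query", query, "-db", cfg$db_path,
            "-num_iterations", cfg$iterations,
            "-inclusion_ethresh", format(cfg$evalue, scientific = FALSE),
            "-out_ascii_pssm", pssm, "-out", hits)
  res <- suppressWarnings(
    system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop("psiblast exited with status ", status, " for ", id, ":\n",
         paste(res, collapse = "\n"))
  if (!file.exists(pssm) || file.size(pssm) == 0) {
    warning("no PSSM produced for ", id,
            " (no hits); falling back to BLOSUM62 substitution profile")
    return(smr_profile(sequence))
  }
  prof <- parse_ascii_pssm(pssm)
  if (nrow(prof) != nchar(sequence))
    stop("PSSM for ", id, " has ", nrow(prof),
         " rows but sequence has ", nchar(sequence), " residues")
  prof
}

# BLOSUM62 rows in canonical column order, cached at first use.
blosum62_rows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_ORDER, AA_ORDER]
    }
    cache
  }
})

#' BLOSUM62 substitution-matrix representation (SMR) of a sequence
#'
#' Encodes a sequence as a U x 20 profile whose row t is the BLOSUM62
#' score row of the residue at position t (columns in [AA_ORDER]). This is
#' the alignment-free comparator to the PSI-BLAST PSSM. Ambiguity codes
#' (B, Z, X, U) map to an all-zero row.
#'
#' @param sequence Amino-acid sequence (non-empty).
#' @return A `ppi_profile` with `source = "smr"`.
#' @examples
#' smr_profile("ACD")[1, "A"]  # BLOSUM62 A->A score, 4
#' @export
smr_profile <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(res, c(AA_ORDER, AA_AMBIGUOUS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  B <- blosum62_rows()
  values <- matrix(0, nrow = length(res), ncol = 20L)
  known <- res %in% AA_ORDER
  values[known, ] <- B[res[known], , drop = FALSE]
  new_profile(values, source = "smr", residues = res)
}

#' Condense a variable-length profile to a 20 x 20 matrix
#'
#' Protein sequences differ in length, so their U x 20 profiles do too.
#' Before the 2-D transform every profile is condensed to a fixed 20 x 20
#' matrix by one of two rules:
#' \describe{
#'   \item{`crossproduct` (default)}{`M = t(P) %*% P / U`, the
#'     length-normalised amino-acid co-substitution matrix. Symmetric,
#'     positive semi-definite, and invariant to reordering of sequence
#'     positions.}
#'   \item{`padtrunc`}{The first 20 rows of `P`, zero-padded when
#'     `U < 20` (the pad/truncate convention of 2-D transform routines).}
#' }
#'
#' @param profile A `ppi_profile` (U x 20 matrix).
#' @param mode Condensation rule.
#' @return A 20 x 20 numeric matrix of class `condensed_matrix` with
#'   attribute `mode`.
#' @export
condense <- function(profile, mode = c("crossproduct", "padtrunc")) {
  mode <- match.arg(mode)
  P <- unclass(as.matrix(profile))
  if (ncol(P) != 20L)
    stop("profile must have 20 columns, got ", ncol(P))
  U <- nrow(P)
  M <- if (mode == "crossproduct") {
    crossprod(P) / U
  } else {
    out <- matrix(0, 20L, 20L)
    keep <- min(U, 20L)
    out[seq_len(keep), ] <- P[seq_len(keep), ]
    out
  }
  dimnames(M) <- list(AA_ORDER, AA_ORDER)
  structure(M, class = c("condensed_matrix", "matrix", "array"),
            mode_used = mode)
}

#' Logistic normalisation of profile scores
#'
#' Optionally maps raw log-odds scores x to 1 / (1 + exp(-x)), putting
#' every entry in (0, 1). Off by default (raw log-odds are used).
#'
#' @param profile A `ppi_profile`.
#' @return A `ppi_profile` with normalised entries.
#' @export
normalize_profile <- function(profile) {
  new_profile(1 / (1 + exp(-unclass(as.matrix(profile)))),
              source = attr(profile, "source") %||% "synthetic",
              residues = attr(profile, "residues"))
}
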