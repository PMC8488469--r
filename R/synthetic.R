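#' Synthetic-dataset configuration
#'
#' Settings for the self-contained planted-signal data generator that
#' stands in for curated plant interaction datasets: random protein
#' sequences, pseudo-profiles on the integer log-odds scale carrying a
#' rank-1 structure along a per-protein latent vector, and a balanced
#' labelled pair set whose ground truth is a latent dot-product rule.
#'
#' @param n_proteins Number of proteins (default 60).
#' @param length_range Min/max sequence length (default `c(50, 200)`).
#' @param n_pos,n_neg Positive / negative pair counts (default 150 each,
#'   a balanced 300-pair set).
#' @param signal_strength Scale of the planted rank-1 profile structure;
#'   0 makes profiles pure noise, independent of the labels (default 2).
#' @param seed Integer seed (default 7).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 60L, length_range = c(50L, 200L),
                         n_pos = 150L, n_neg = 150L,
                         signal_strength = 2, seed = 7L) {
  stopifnot(n_proteins >= 2L, length_range[1] >= 1L,
            length_range[1] <= length_range[2],
            n_pos >= 1L, n_neg >= 1L, signal_strength >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 signal_strength = signal_strength,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate random protein records
#'
#' Seeded i.i.d. sequences over the 20-letter amino-acid alphabet with
#' lengths uniform in `cfg$length_range`.
#'
#' @param cfg A [synth_config()].
#' @return Named character vector of sequences, ids `P0001`, `P0002`, ...
#' @export
gen_proteins <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    lens <- sample(cfg$length_range[1]:cfg$length_range[2],
                   cfg$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ORDER, L, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("P%04d", seq_len(cfg$n_proteins))
    seqs
  })
}

# Latent vectors: a common non-negative direction v0, jittered per
# protein, scaled by a per-protein "interaction propensity" magnitude
# m ~ U(0.2, 1.8). Ground-truth interaction: dot(latent_i, latent_j) > 0.8;
# pairs in the ambiguous band (0.6, 0.8] are excluded from negative
# sampling, mirroring benchmark construction where sampled negatives are
# kept away from known positives.
LATENT_DOT_THRESHOLD <- 0.8
LATENT_DOT_MARGIN <- 0.6
gen_latents <- function(cfg) {
  with_seed(cfg$seed + 1L, {
    v0 <- abs(stats::rnorm(20)); v0 <- v0 / sqrt(sum(v0^2))
    m <- stats::runif(cfg$n_proteins, 0.2, 1.8)
    L <- t(vapply(seq_len(cfg$n_proteins), function(i) {
      d <- v0 + 0.25 * stats::rnorm(20)
      m[i] * d / sqrt(sum(d^2))
    }, numeric(20)))
    rownames(L) <- sprintf("P%04d", seq_len(cfg$n_proteins))
    L
  })
}

#' Generate a synthetic pseudo-profile for one protein
#'
#' The U x 20 profile is baseline Gaussian noise (sd 2, the magnitude of
#' real log-odds fluctuation) plus a rank-1 planted term: every position
#' row receives `3 * signal_strength * latent`, so the condensed
#' cross-product matrix carries the latent outer product. Entries are
#' rounded to integers and clamped to `[-10, 12]` to mimic PSI-BLAST
#' log-odds; the result is exactly reproducible from `(record, seed)`.
#'
#' @param id Protein identifier (used to derive a per-protein seed).
#' @param sequence Amino-acid sequence (its length sets U).
#' @param latent Numeric length-20 latent vector.
#' @param cfg A [synth_config()].
#' @return An integer-valued `ppi_profile` with `source = "synthetic"`.
#' @export
gen_profile <- function(id, sequence, latent, cfg) {
  stopifnot(inherits(cfg, "synth_config"), length(latent) == 20L)
  U <- nchar(sequence)
  sub_seed <- (cfg$seed * 10007L +
               sum(utf8ToInt(id)) * 31L) %% .Machine$integer.max
  with_seed(sub_seed, {
    noise <- matrix(stats::rnorm(U * 20L, 0, 2), U, 20L)
    planted <- matrix(rep(3 * cfg$signal_strength * latent, each = U),
                      U, 20L)
    vals <- pmin(pmax(round(noise + planted), -10), 12)
    new_profile(vals, source = "synthetic",
                residues = strsplit(toupper(sequence), "")[[1L]])
  })
}

#' Generate a complete labelled synthetic dataset
#'
#' Produces everything the pipeline needs offline: records, profiles and
#' a balanced labelled pair set. Positive pairs are sampled among the
#' latent-correlated pairs (`dot(latent_i, latent_j) > 0.8`, i < j);
#' negatives are drawn by [sample_negatives()] from the complement of
#' the interacting set plus an ambiguous margin band (dot in
#' (0.6, 0.8]), so no sampled negative is a true or borderline positive.
#'
#' @param cfg A [synth_config()].
#' @return List with `records` (named character), `profiles` (named
#'   list of `ppi_profile`), `pairs` (data.frame `idA`, `idB`, `label`)
#'   and `latents` (n x 20 matrix).
#' @export
gen_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  records <- gen_proteins(cfg)
  latents <- gen_latents(cfg)
  ids <- names(records)
  profiles <- lapply(ids, function(id)
    gen_profile(id, records[[id]], latents[id, ], cfg))
  names(profiles) <- ids
  if (cfg$signal_strength == 0) {
    # Null condition: labels must be independent of the features AND of
    # protein identity (a protein's fixed profile identifies it across
    # folds, so latent-derived labels would still be memorisable even
    # with pure-noise profiles). Pairs are drawn uniformly instead.
    all_pos <- with_seed(cfg$seed + 2L, {
      cmb <- utils::combn(ids, 2L)
      pick <- sample.int(ncol(cmb), cfg$n_pos)
      # random slot order, so listed order carries no label signal
      sw <- sample(c(TRUE, FALSE), cfg$n_pos, replace = TRUE)
      data.frame(idA = ifelse(sw, cmb[2L, pick], cmb[1L, pick]),
                 idB = ifelse(sw, cmb[1L, pick], cmb[2L, pick]),
                 label = 1L, stringsAsFactors = FALSE)
    })
    neg <- sample_negatives(ids, all_pos, cfg$n_neg, seed = cfg$seed + 3L)
    pairs <- rbind(all_pos, neg)
    rownames(pairs) <- NULL
    return(list(records = records, profiles = profiles, pairs = pairs,
                latents = latents))
  }
  G <- latents %*% t(latents)
  ut <- which(upper.tri(G) & G > LATENT_DOT_THRESHOLD, arr.ind = TRUE)
  n_int <- nrow(ut)
  if (n_int < cfg$n_pos)
    stop("only ", n_int, " interacting pairs available, need ", cfg$n_pos,
         "; increase n_proteins or signal correlation")
  interacting <- data.frame(idA = ids[ut[, 1L]], idB = ids[ut[, 2L]],
                            stringsAsFactors = FALSE)
  pos <- with_seed(cfg$seed + 2L, {
    pick <- sample.int(n_int, cfg$n_pos)
    sw <- sample(c(TRUE, FALSE), cfg$n_pos, replace = TRUE)
    data.frame(idA = ifelse(sw, interacting$idB[pick], interacting$idA[pick]),
               idB = ifelse(sw, interacting$idA[pick], interacting$idB[pick]),
               label = 1L, stringsAsFactors = FALSE)
  })
  # exclude interacting pairs AND the ambiguous margin band (both orders,
  # self-pairs included) so sampled negatives are confidently non-interacting
  ex <- which(G > LATENT_DOT_MARGIN, arr.ind = TRUE)
  both <- data.frame(idA = ids[ex[, 1L]], idB = ids[ex[, 2L]])
  neg <- sample_negatives(ids, both, cfg$n_neg, seed = cfg$seed + 3L)
  pairs <- rbind(pos, neg)
  rownames(pairs) <- NULL
  list(records = records, profiles = profiles, pairs = pairs,
       latents = latents)
}

#' Write a profile as a PSI-BLAST-style ASCII PSSM fixture
#'
#' Emits the `psiblast -out_ascii_pssm` text dialect (header lines, one
#' row per position with index, residue, 20 integer log-odds and 20
#' percentage columns, trailing statistics) such that
#' [parse_ascii_pssm()] recovers the integer matrix exactly.
#'
#' @param profile Integer-valued `ppi_profile` (error if non-integer;
#'   round first).
#' @param id Protein identifier for the header.
#' @param sequence Amino-acid sequence (residue column; length must
#'   match the profile rows).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
emit_ascii_pssm <- function(profile, id, sequence, path) {
  P <- unclass(as.matrix(profile))
  if (ncol(P) != 20L) stop("profile must have 20 columns")
  if (any(P != round(P)))
    stop("profile has non-integer entries; round before emitting")
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (length(res) != nrow(P))
    stop("sequence length ", length(res), " != profile rows ", nrow(P))
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write PSSM to ", path))
  on.exit(close(con))
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("           ",
           paste(sprintf("%3s", c(AA_ORDER, AA_ORDER)), collapse = ""))),
    con)
  for (t in seq_len(nrow(P))) {
    writeLines(paste0(sprintf("%5d %s  ", t, res[t]),
                      paste(sprintf("%3d", as.integer(P[t, ])), collapse = ""),
                      "  ",
                      paste(sprintf("%3d", integer(20L)), collapse = ""),
                      sprintf("  %4.2f %8.2f", 0, 0)),
               con)
  }
  writeLines(c("", "                      K         Lambda",
               sprintf("Standard Ungapped    %.4f     %.4f", 0.1347, 0.3179),
               sprintf("PSI Ungapped         %.4f     %.4f", 0.1347, 0.3179)),
             con)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Convenience wrapper used by the `simulate` CLI subcommand: writes the
#' FASTA file, the tab-separated pair list and one ASCII PSSM fixture per
#' protein into `dir`.
#'
#' @param dataset A [gen_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$records, file.path(dir, "proteins.fasta"))
  write_pair_list(dataset$pairs, file.path(dir, "pairs.tsv"))
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (id in names(dataset$profiles))
    emit_ascii_pssm(dataset$profiles[[id]], id, dataset$records[[id]],
                    file.path(pssm_dir, paste0(id, ".pssm")))
  invisible(dir)
}
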