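# Consensus intrinsically-disordered-region (IDR) calling from
# multi-predictor per-residue disorder tracks, IDR proportions by protein
# class, and amino-acid composition enrichment against a background set.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Call consensus IDRs from per-residue predictor tracks
#'
#' A residue is consensus-disordered when strictly more than
#' `consensus_frac` of the predictors call it disordered; maximal runs of
#' consensus residues strictly longer than `min_run` become IDR intervals.
#' Both inequalities are strict: with 4 predictors, 3 agreeing (exactly
#' 75\%) does not pass the default 0.75 cut, and a run of exactly 10
#' residues is not an IDR while 11 is.
#'
#' @param calls logical (or 0/1) matrix, residues x predictors
#' @param consensus_frac fraction of predictors that must strictly be
#'   exceeded (default 0.75)
#' @param min_run run length that must strictly be exceeded (default 10)
#' @return list with `intervals` (data.frame `start`, `end`, 1-based
#'   inclusive), `idr_proportion` (summed interval length over protein
#'   length) and `length`
#' @examples
#' calls <- matrix(TRUE, nrow = 100, ncol = 4)
#' call_idrs(calls)$intervals  # one interval spanning 1..100
#' @export
call_idrs <- function(calls, consensus_frac = 0.75, min_run = 10) {
  if (is.null(dim(calls))) calls <- cbind(calls)
  stopifnot(ncol(calls) >= 1L)
  storage.mode(calls) <- "logical"
  consensus <- rowMeans(calls) > consensus_frac
  r <- rle(as.vector(consensus))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_run
  intervals <- data.frame(start = starts[keep], end = ends[keep])
  list(intervals = intervals,
       idr_proportion = sum(intervals$end - intervals$start + 1L) /
         nrow(calls),
       length = nrow(calls))
}

#' Compare IDR proportions across protein stability classes
#'
#' Pairwise two-sample rank-sum (Wilcoxon) tests between the per-protein
#' IDR-proportion distributions of each class, with Holm adjustment over
#' the comparisons. Classes with fewer than 3 members are skipped and
#' flagged. (The groups are unpaired and of unequal size, so a
#' signed-rank test is not applicable; the rank-sum test is used.)
#'
#' @param proportions numeric vector of per-protein IDR proportions
#' @param classes factor/character of the same length (e.g. stabilized /
#'   destabilized / unaffected)
#' @return data.frame with one row per class pair: `class_a`, `class_b`,
#'   `n_a`, `n_b`, `p_value`, `p_adjusted`, `skipped`
#' @export
idr_proportion_by_class <- function(proportions, classes) {
  stopifnot(length(proportions) == length(classes))
  classes <- as.character(classes)
  lv <- unique(classes)
  if (length(lv) < 2L) {
    return(data.frame(class_a = character(), class_b = character(),
                      n_a = integer(), n_b = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      skipped = logical()))
  }
  pairs <- utils::combn(lv, 2L)
  res <- data.frame(class_a = pairs[1L, ], class_b = pairs[2L, ],
                    n_a = NA_integer_, n_b = NA_integer_,
                    p_value = NA_real_, p_adjusted = NA_real_,
                    skipped = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    xa <- proportions[classes == res$class_a[i]]
    xb <- proportions[classes == res$class_b[i]]
    res$n_a[i] <- length(xa)
    res$n_b[i] <- length(xb)
    if (length(xa) < 3L || length(xb) < 3L) {
      res$skipped[i] <- TRUE
      next
    }
    res$p_value[i] <- suppressWarnings(
      wilcox.test(xa, xb, exact = FALSE)$p.value)
  }
  done <- !res$skipped
  res$p_adjusted[done] <- p.adjust(res$p_value[done], method = "holm")
  res
}

# amino-acid frequency vector of one or more sequences (pooled)
aa_frequencies <- function(seqs) {
  counts <- colSums(aa_count_matrix(seqs))
  counts / max(sum(counts), 1)
}

# per-sequence counts of the 20 standard amino acids
aa_count_matrix <- function(seqs) {
  m <- t(vapply(seqs, function(s) {
    tab <- table(factor(strsplit(toupper(s), "")[[1]], levels = AA20))
    as.numeric(tab)
  }, numeric(length(AA20))))
  colnames(m) <- AA20
  m
}

#' Amino-acid composition enrichment of a sequence group vs a background
#'
#' For each standard amino acid, the enrichment score is the relative
#' frequency difference (f_group - f_background) / f_background on pooled
#' residue frequencies: 0 means background-like, +1 a doubling, -1
#' complete depletion. Dispersion is a bootstrap standard deviation over
#' proteins (both sets resampled); significance is an unpaired two-sample
#' t-test on per-protein frequencies, Bonferroni-adjusted across the 20
#' amino acids. Amino acids absent from the background have no defined
#' score (`NA`, flagged).
#'
#' @param group_seqs character vector of group sequences (e.g. IDRs of
#'   stabilized proteins)
#' @param background_seqs character vector of background sequences
#' @param n_boot bootstrap replicates for the dispersion (default 1000)
#' @param seed RNG seed for the bootstrap (default 1)
#' @return data.frame, one row per amino acid: `aa`, `f_group`,
#'   `f_background`, `score`, `boot_sd`, `p_value`, `p_adjusted`
#' @export
composition_enrichment <- function(group_seqs, background_seqs,
                                   n_boot = 1000, seed = 1) {
  if (!length(group_seqs) || !length(background_seqs)) {
    stop("both sequence sets must be non-empty")
  }
  group_seqs <- as.character(group_seqs)
  background_seqs <- as.character(background_seqs)
  fg <- aa_frequencies(group_seqs)
  fb <- aa_frequencies(background_seqs)
  score <- ifelse(fb > 0, (fg - fb) / fb, NA_real_)

  boot_sd <- rep(NA_real_, length(AA20))
  if (n_boot > 0) {
    boots <- with_stream(seed, "composition_boot", {
      replicate(n_boot, {
        g <- sample(group_seqs, replace = TRUE)
        b <- sample(background_seqs, replace = TRUE)
        fgi <- aa_frequencies(g)
        fbi <- aa_frequencies(b)
        ifelse(fbi > 0, (fgi - fbi) / fbi, NA_real_)
      })
    })
    boot_sd <- apply(boots, 1L, sd, na.rm = TRUE)
  }

  # per-protein frequencies for the t-test
  gm <- aa_count_matrix(group_seqs)
  bm <- aa_count_matrix(background_seqs)
  gf <- gm / pmax(rowSums(gm), 1)
  bf <- bm / pmax(rowSums(bm), 1)
  p <- vapply(seq_along(AA20), function(j) {
    if (is.na(score[j])) return(NA_real_)
    if (sd(gf[, j]) == 0 && sd(bf[, j]) == 0) {
      return(if (mean(gf[, j]) == mean(bf[, j])) 1 else 0)
    }
    tryCatch(t.test(gf[, j], bf[, j])$p.value, error = function(e) NA_real_)
  }, numeric(1))

  data.frame(aa = AA20, f_group = unname(fg), f_background = unname(fb),
             score = unname(score), boot_sd = boot_sd, p_value = p,
             p_adjusted = pmin(1, p * length(AA20)),
             stringsAsFactors = FALSE)
}

#' Count occurrences of one residue in a protein sequence
#'
#' @param sequence amino-acid string
#' @param residue single-letter residue code
#' @return list with `count`, `length` (total residues) and
#'   `nonstandard` (named counts of any letters outside the 20-letter
#'   alphabet)
#' @examples
#' count_residue("MMSQ", "M")  # count 2 of 4
#' @export
count_residue <- function(sequence, residue) {
  stopifnot(is.character(sequence), nchar(sequence) > 0,
            nchar(residue) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  nonstd <- table(chars[!chars %in% AA20])
  list(count = sum(chars == toupper(residue)),
       length = length(chars),
       nonstandard = as.list(nonstd))
}

#' Read per-residue disorder tracks from a long-format TSV
#'
#' Expected columns: `protein_id`, `residue_index`, `predictor_id`,
#' `call` (0/1 or logical).
#'
#' @param path TSV file path
#' @return named list of residue x predictor logical matrices
#' @export
read_disorder_tracks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "residue_index", "predictor_id", "call")
  if (!all(need %in% names(df))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$protein_id), function(d) {
    preds <- sort(unique(d$predictor_id))
    n <- max(d$residue_index)
    m <- matrix(FALSE, nrow = n, ncol = length(preds),
                dimnames = list(NULL, preds))
    m[cbind(d$residue_index, match(d$predictor_id, preds))] <-
      as.logical(d$call)
    m
  })
}

#' Write IDR intervals as a BED-like TSV
#'
#' Coordinates are 1-based inclusive (stated in the header comment),
#' unlike BED's 0-based half-open convention.
#'
#' @param idr_sets named list of [call_idrs()] results (names = protein
#'   ids)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_idr_intervals <- function(idr_sets, path) {
  rows <- do.call(rbind, lapply(names(idr_sets), function(id) {
    iv <- idr_sets[[id]]$intervals
    if (!nrow(iv)) return(NULL)
    data.frame(protein_id = id, start = iv$start, end = iv$end)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# IDR intervals; coordinates 1-based inclusive", con)
  if (is.null(rows)) {
    writeLines("protein_id\tstart\tend", con)
  } else {
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a plain
#' named character vector.
#'
#' @param path FASTA file path
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
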