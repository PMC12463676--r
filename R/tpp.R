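#' Per-temperature log2 fold changes of treatment versus control
#'
#' For each protein and temperature, the log2 ratio of the (normalized)
#' reporter intensity under treatment to the intensity under control.
#' Zero or missing intensities on either side leave the fold change
#' undefined at that temperature (a log ratio of zero intensity has no
#' meaning); the number of zero-censored cells is reported via a warning.
#'
#' @param matrix a [melt_curve_matrix()]
#' @param treatment treatment condition label
#' @param control control condition label; defaults to the matrix's control
#' @return a list with `log2fc` (protein x temperature matrix, `NA` where
#'   undefined), `n_points` (non-missing temperatures per protein),
#'   `temperatures`, `treatment` and `control`
#' @export
compute_fold_changes <- function(matrix, treatment,
                                 control = matrix$control) {
  stopifnot(inherits(matrix, "melt_curve_matrix"))
  if (!treatment %in% matrix$conditions) {
    stop(sprintf("unknown treatment condition '%s'", treatment))
  }
  if (!control %in% matrix$conditions) {
    stop(sprintf("unknown control condition '%s'", control))
  }
  if (identical(treatment, control)) {
    stop("treatment and control must differ")
  }
  it <- matrix$intensity[, , treatment, drop = FALSE][, , 1]
  ic <- matrix$intensity[, , control, drop = FALSE][, , 1]
  # single-protein edge: drop keeps matrix shape
  if (is.null(dim(it))) {
    it <- rbind(it); ic <- rbind(ic)
    rownames(it) <- rownames(ic) <- matrix$protein_ids
  }
  zero_censored <- sum((!is.na(it) & it == 0) | (!is.na(ic) & ic == 0))
  it[it == 0] <- NA
  ic[ic == 0] <- NA
  if (zero_censored > 0) {
    warning(sprintf("%d zero intensities treated as missing", zero_censored))
  }
  log2fc <- log2(it / ic)
  list(log2fc = log2fc,
       n_points = rowSums(!is.na(log2fc)),
       temperatures = matrix$temperatures,
       treatment = treatment,
       control = control)
}

#' Abundance score: mean log2 fold change at the two lowest temperatures
#'
#' At the lowest temperatures essentially no protein has melted, so the
#' fold change there reflects expression or solubility changes rather than
#' thermal stability. Undefined (`NA`) if either of the two lowest
#' temperatures is missing.
#'
#' @param log2fc protein x temperature matrix of log2 fold changes (columns
#'   ordered by increasing temperature), or a single row
#' @return numeric vector of abundance scores, one per protein
#' @export
abundance_score <- function(log2fc) {
  if (is.null(dim(log2fc))) log2fc <- rbind(log2fc)
  if (ncol(log2fc) < 2L) stop("need at least two temperatures")
  (log2fc[, 1L] + log2fc[, 2L]) / 2
}

#' Thermal stability score: summed abundance-corrected log2 fold changes
#'
#' The abundance score is subtracted from the fold change at every
#' temperature and the residuals are summed over the non-missing
#' temperatures. A positive score means the soluble fraction decays more
#' slowly under treatment (thermal stabilization). Proteins quantified at
#' fewer than `min_points` temperatures get `NA`: the sum is not
#' comparable across very different grid coverage.
#'
#' @param log2fc protein x temperature matrix of log2 fold changes
#' @param abundance abundance score per protein (see [abundance_score()])
#' @param min_points minimum non-missing temperatures required (default 10,
#'   i.e. the complete grid of the standard 10-temperature design)
#' @return numeric vector of stability scores
#' @export
stability_score <- function(log2fc, abundance, min_points = 10L) {
  if (is.null(dim(log2fc))) log2fc <- rbind(log2fc)
  stopifnot(length(abundance) == nrow(log2fc))
  n_points <- rowSums(!is.na(log2fc))
  s <- rowSums(log2fc - abundance, na.rm = TRUE)
  s[n_points < min_points | is.na(abundance)] <- NA_real_
  s
}

#' Standardize scores to z values
#'
#' Centers by the mean and scales by the sample standard deviation
#' (denominator n-1) over the non-missing entries; `NA` propagates.
#'
#' @param scores numeric vector, possibly with `NA`
#' @return z-scored vector of the same length
#' @export
z_transform <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 2L) stop("need at least two non-missing scores")
  s <- sd(scores[ok])
  if (s == 0) stop("zero standard deviation: degenerate score vector")
  (scores - mean(scores[ok])) / s
}

#' Significance of z scores under a robust weighted empirical null
#'
#' Models the bulk of the z distribution as the null. The null center and
#' scale are estimated robustly (median and MAD) so that a minority of true
#' effects does not inflate the null. Each observation carries a precision
#' weight proportional to the number of temperatures behind its score
#' (`weights`); a protein seen at fewer temperatures has a proportionally
#' larger null variance. Two-sided p-values come from the scaled normal
#' null; FDR is Benjamini-Hochberg by default, with a local-fdr variant
#' (empirical-Bayes two-groups model with a half-normal null) available.
#'
#' @param z numeric vector of z scores (`NA` allowed, propagates)
#' @param weights positive precision weights, typically `n_points`;
#'   recycled if length 1
#' @param fdr_method `"BH"` (tail-area, default) or `"local"`
#' @return data.frame with columns `p_value` and `fdr`
#' @export
moderated_significance <- function(z, weights = 1, fdr_method = c("BH", "local")) {
  fdr_method <- match.arg(fdr_method)
  weights <- rep_len(weights, length(z))
  if (any(weights < 1, na.rm = TRUE)) stop("weights must be >= 1")
  ok <- !is.na(z)
  if (sum(ok) < 10L) {
    stop("fewer than 10 observations: empirical null not estimable")
  }
  center <- median(z[ok])
  scale0 <- mad(z[ok], center = center)
  if (scale0 == 0) stop("zero MAD: degenerate z distribution")
  # null variance for protein i: pooled variance / relative precision
  wbar <- mean(weights[ok])
  u <- (z - center) / (scale0 / sqrt(weights / wbar))
  p <- 2 * pnorm(-abs(u))
  fdr <- rep(NA_real_, length(z))
  if (fdr_method == "BH") {
    fdr[ok] <- p.adjust(p[ok], method = "BH")
  } else {
    fdr[ok] <- local_fdr(u[ok])
  }
  data.frame(p_value = p, fdr = fdr)
}

# Local false discovery rate from standardized null-scaled statistics.
# Two-groups model: f(u) estimated by kernel density, null f0 = N(0, s0)
# with s0 refit by half-normal MLE on the central 90% of |u|, pi0 from the
# density ratio at the center (capped at 1).
local_fdr <- function(u) {
  core <- u[abs(u) <= quantile(abs(u), 0.9)]
  s0 <- sqrt(mean(core^2))
  d <- density(u, n = 2048, cut = 4)
  f <- approx(d$x, d$y, xout = u, rule = 2)$y
  pi0 <- min(1, approx(d$x, d$y, xout = 0, rule = 2)$y / dnorm(0, sd = s0))
  fdr <- pmin(1, pi0 * dnorm(u, sd = s0) / pmax(f, .Machine$double.eps))
  # enforce monotone non-increase away from the center on each side
  for (side in c(-1, 1)) {
    idx <- order(side * u)
    sel <- if (side < 0) u <= 0 else u >= 0
    ord <- idx[sel[idx]]
    fdr[ord] <- rev(cummin(rev(fdr[ord])))
  }
  fdr
}

#' Classify proteins by z score and FDR
#'
#' A protein is called stabilized when `z > z_cut` and `fdr < fdr_cut`,
#' destabilized when `z < -z_cut` and `fdr < fdr_cut`, otherwise
#' unaffected. `NA` in either input gives unaffected.
#'
#' @param z stability z scores
#' @param fdr false discovery rates
#' @param z_cut absolute z cutoff (default 1.5)
#' @param fdr_cut FDR cutoff (default 0.05)
#' @return factor with levels stabilized/destabilized/unaffected
#' @export
classify_stability <- function(z, fdr, z_cut = 1.5, fdr_cut = 0.05) {
  cls <- rep("unaffected", length(z))
  sig <- !is.na(z) & !is.na(fdr) & fdr < fdr_cut
  cls[sig & z > z_cut] <- "stabilized"
  cls[sig & z < -z_cut] <- "destabilized"
  factor(cls, levels = c("stabilized", "destabilized", "unaffected"))
}

#' Thermal proteome profiling stability analysis
#'
#' Runs the full TPP scoring pipeline for one treatment-versus-control
#' contrast: per-temperature log2 fold changes, abundance and thermal
#' stability scores, z-transformation (per contrast), robust weighted
#' empirical-null significance and FDR, and three-way classification.
#'
#' @param matrix a [melt_curve_matrix()]
#' @param treatment treatment condition label
#' @param control control label (defaults to the matrix's control)
#' @param min_points minimum temperatures for a stability score (default 10)
#' @param z_cut,fdr_cut classification cutoffs (defaults 1.5 and 0.05)
#' @param fdr_method `"BH"` or `"local"`, see [moderated_significance()]
#' @return object of class `tpp_stability`: a list with `table` (one row
#'   per protein: scores, z, p, fdr, class) and the call parameters
#' @examples
#' sim <- gen_tpp(n_proteins = 50, n_stabilized = 5, seed = 1)
#' fit <- tpp_stability(sim$curves, treatment = "treated")
#' head(fit$table)
#' @export
tpp_stability <- function(matrix, treatment, control = matrix$control,
                          min_points = 10L, z_cut = 1.5, fdr_cut = 0.05,
                          fdr_method = c("BH", "local")) {
  fdr_method <- match.arg(fdr_method)
  fc <- compute_fold_changes(matrix, treatment, control)
  abund <- abundance_score(fc$log2fc)
  stab <- stability_score(fc$log2fc, abund, min_points = min_points)
  abund_z <- z_transform(abund)
  stab_z <- z_transform(stab)
  sig <- moderated_significance(stab_z, weights = pmax(fc$n_points, 1),
                                fdr_method = fdr_method)
  cls <- classify_stability(stab_z, sig$fdr, z_cut = z_cut,
                            fdr_cut = fdr_cut)
  tab <- data.frame(
    protein_id = matrix$protein_ids,
    n_points = fc$n_points,
    abundance_score = abund,
    stability_score = stab,
    abundance_z = abund_z,
    stability_z = stab_z,
    p_value = sig$p_value,
    fdr = sig$fdr,
    class = cls,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, treatment = treatment, control = control,
         min_points = min_points, z_cut = z_cut, fdr_cut = fdr_cut,
         fdr_method = fdr_method),
    class = "tpp_stability"
  )
}

#' @export
print.tpp_stability <- function(x, ...) {
  cat(sprintf("TPP stability analysis: %s vs %s\n", x$treatment, x$control))
  cat(sprintf("  %d proteins, %d scored (min_points = %d)\n",
              nrow(x$table), sum(!is.na(x$table$stability_score)),
              x$min_points))
  n <- table(x$table$class)
  cat(sprintf("  stabilized: %d  destabilized: %d  unaffected: %d\n",
              n[["stabilized"]], n[["destabilized"]], n[["unaffected"]]))
  cat(sprintf("  cutoffs: |z| > %g, FDR < %g (%s)\n",
              x$z_cut, x$fdr_cut, x$fdr_method))
  invisible(x)
}

#' @export
summary.tpp_stability <- function(object, ...) {
  tab <- object$table
  hits <- tab[tab$class != "unaffected", ]
  hits <- hits[order(-abs(hits$stability_z)), ]
  out <- list(n_proteins = nrow(tab),
              n_scored = sum(!is.na(tab$stability_score)),
              class_counts = table(tab$class),
              top_hits = head(hits, 10L))
  class(out) <- "summary.tpp_stability"
  out
}

#' @export
print.summary.tpp_stability <- function(x, ...) {
  cat(sprintf("%d proteins (%d scored)\n", x$n_proteins, x$n_scored))
  print(x$class_counts)
  if (nrow(x$top_hits)) {
    cat("Top hits by |stability z|:\n")
    print(x$top_hits[, c("protein_id", "stability_z", "fdr", "class")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a TPP stability table to TSV
#' @param fit a `tpp_stability` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stability_table <- function(fit, path) {
  stopifnot(inherits(fit, "tpp_stability"))
  utils::write.table(fit$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
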