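# High-content screen scoring: per-plate control-referenced z-scores,
# Mahalanobis combination with shrinkage-regularized covariance, and
# linear time-drift normalization for in vitro plate reads.

#' Control-referenced z-scores for a screening plate
#'
#' For each feature, z = (x - mu) / sigma with mu and sigma the mean and
#' sample standard deviation of that plate's control wells only. Features
#' whose control values are constant (sigma = 0) are dropped with a
#' warning: they carry no usable scale.
#'
#' @param features numeric matrix, wells x features, with feature column
#'   names
#' @param role character vector per well, `"control"` or `"treatment"`
#' @return list with `z` (wells x retained features), `mu`, `sigma`
#'   (named control statistics) and `dropped` (names of constant features)
#' @export
control_zscores <- function(features, role) {
  stopifnot(is.matrix(features), nrow(features) == length(role))
  ctrl <- role == "control"
  if (sum(ctrl) < 2L) stop("need at least 2 control wells per plate")
  mu <- colMeans(features[ctrl, , drop = FALSE])
  sigma <- apply(features[ctrl, , drop = FALSE], 2L, sd)
  dropped <- colnames(features)[sigma == 0]
  if (length(dropped)) {
    warning("dropping constant control features: ",
            paste(dropped, collapse = ", "))
  }
  keep <- sigma > 0
  z <- sweep(sweep(features[, keep, drop = FALSE], 2L, mu[keep]),
             2L, sigma[keep], `/`)
  list(z = z, mu = mu[keep], sigma = sigma[keep], dropped = dropped)
}

# Ledoit-Wolf-style shrinkage of a covariance matrix toward its diagonal
# (Schafer-Strimmer estimator for the off-diagonal shrinkage intensity).
shrink_covariance <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  s <- cov(x)
  if (p == 1L) return(s)
  xc <- scale(x, center = TRUE, scale = FALSE)
  # var of each off-diagonal covariance estimate
  w <- array(0, dim = c(p, p))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      wij <- xc[, i] * xc[, j]
      w[i, j] <- w[j, i] <- n / ((n - 1)^3) * sum((wij - mean(wij))^2)
    }
  }
  off <- s; diag(off) <- 0
  denom <- sum(off^2)
  lambda <- if (denom > 0) min(1, max(0, sum(w) / denom)) else 1
  shrunk <- (1 - lambda) * s
  diag(shrunk) <- diag(s)
  attr(shrunk, "lambda") <- lambda
  shrunk
}

#' Mahalanobis distance of well z-vectors from the control distribution
#'
#' D = sqrt(z' S^-1 z) with S the covariance of the control wells'
#' z-vectors. With few controls relative to features the sample covariance
#' is unstable or singular, so by default S is shrunk toward its diagonal
#' (Ledoit-Wolf-style intensity estimated from the controls).
#'
#' @param z numeric matrix (wells x features) or a single z-vector
#' @param control_z numeric matrix of control-well z-vectors
#' @param shrinkage `"lw"` (default) or `"none"` (plain sample covariance;
#'   errors if singular)
#' @return numeric vector of distances, one per row of `z`
#' @export
mahalanobis_score <- function(z, control_z, shrinkage = c("lw", "none")) {
  shrinkage <- match.arg(shrinkage)
  if (is.null(dim(z))) z <- rbind(z)
  stopifnot(ncol(z) == ncol(control_z))
  s <- if (shrinkage == "lw") shrink_covariance(control_z)
       else cov(control_z)
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch)) {
    stop("control covariance is singular; use shrinkage = \"lw\"")
  }
  # D^2 = || L^-T z ||^2 via triangular solve
  y <- backsolve(ch, t(z), transpose = TRUE)
  sqrt(colSums(y^2))
}

#' Score a multi-plate screen and rank wells by Mahalanobis distance
#'
#' Per plate: control-referenced z-scores ([control_zscores()]) combined
#' into a Mahalanobis distance ([mahalanobis_score()]) against that
#' plate's own control covariance.
#'
#' @param wells data.frame with columns `plate_id`, `well_id`,
#'   `compound_id`, `role` plus one numeric column per feature
#' @param features character vector of feature column names; default all
#'   numeric columns not in the metadata set
#' @param shrinkage passed to [mahalanobis_score()]
#' @return the input data.frame plus a `mahalanobis` column, sorted by
#'   decreasing distance, with a `rank` column
#' @export
score_screen <- function(wells, features = NULL,
                         shrinkage = c("lw", "none")) {
  shrinkage <- match.arg(shrinkage)
  meta <- c("plate_id", "well_id", "compound_id", "role", "concentration")
  if (!all(c("plate_id", "well_id", "role") %in% names(wells))) {
    stop("`wells` needs plate_id, well_id and role columns")
  }
  if (is.null(features)) {
    features <- setdiff(names(wells)[vapply(wells, is.numeric, TRUE)], meta)
  }
  if (!length(features)) stop("no feature columns found")
  wells$mahalanobis <- NA_real_
  for (pl in unique(wells$plate_id)) {
    idx <- wells$plate_id == pl
    fm <- as.matrix(wells[idx, features, drop = FALSE])
    zs <- control_zscores(fm, wells$role[idx])
    ctrl_z <- zs$z[wells$role[idx] == "control", , drop = FALSE]
    wells$mahalanobis[idx] <- mahalanobis_score(zs$z, ctrl_z,
                                                shrinkage = shrinkage)
  }
  wells <- wells[order(-wells$mahalanobis), ]
  wells$rank <- seq_len(nrow(wells))
  rownames(wells) <- NULL
  wells
}

#' Correct a linear time drift using row-flanking controls
#'
#' Plate-read signals that drift over acquisition time (e.g. condensate
#' sedimentation) are referenced to control wells at the start and end of
#' each plate row, assuming linear change between them: each well's value
#' is divided (or, for additive drift, subtracted) by the control value
#' interpolated at its timestamp.
#'
#' @param values numeric vector of well measurements
#' @param times numeric acquisition timestamps, same length
#' @param t_start,t_end timestamps of the flanking control reads
#' @param c_start,c_end control values at those times
#' @param mode `"divide"` (default) or `"subtract"`
#' @return corrected values; in divide mode they are expressed relative to
#'   the local control level
#' @export
time_drift_normalize <- function(values, times, t_start, c_start,
                                 t_end, c_end,
                                 mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(length(values) == length(times))
  if (anyNA(c(t_start, c_start, t_end, c_end))) {
    stop("missing flanking control: row cannot be drift-corrected")
  }
  ref <- if (t_end == t_start) {
    rep((c_start + c_end) / 2, length(times))
  } else {
    c_start + (c_end - c_start) * (times - t_start) / (t_end - t_start)
  }
  if (mode == "divide") {
    if (any(ref == 0)) stop("interpolated control crosses zero")
    values / ref
  } else {
    values - ref + (c_start + c_end) / 2  # keep the row's mean level
  }
}

#' Monotone dose-dependence check
#'
#' Operationalizes "a clear monotonic dose-dependent response" as a
#' Spearman rank correlation between concentration and response whose
#' magnitude exceeds `rho_threshold` (in the expected direction when one
#' is given).
#'
#' @param concentrations positive concentrations
#' @param responses responses at those concentrations
#' @param rho_threshold minimum |Spearman rho| (default 0.8)
#' @param direction `"any"`, `"decreasing"` or `"increasing"`
#' @return logical; also carries the rho estimate as attribute `"rho"`
#' @export
monotone_dose_check <- function(concentrations, responses,
                                rho_threshold = 0.8,
                                direction = c("any", "decreasing",
                                              "increasing")) {
  direction <- match.arg(direction)
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 4L) stop("need at least 4 concentrations")
  if (sd(responses) == 0) {
    out <- FALSE
    attr(out, "rho") <- 0
    return(out)
  }
  rho <- suppressWarnings(
    cor(concentrations, responses, method = "spearman"))
  ok <- switch(direction,
               any = abs(rho) >= rho_threshold,
               decreasing = rho <= -rho_threshold,
               increasing = rho >= rho_threshold)
  attr(ok, "rho") <- rho
  ok
}
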