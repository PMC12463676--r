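# Seeded synthetic-data generators. Each generator is a pure function of
# its arguments plus a master seed; every generator draws from its own
# RNG stream derived from (seed, generator name), so adding or reordering
# generators never changes another generator's output. Each returns the
# simulated data in the exact shape the analysis functions consume, plus
# a ground-truth record for downstream checks.

#' Default 10-temperature gradient of the standard TPP design (degC)
#' @export
TPP_TEMPERATURES <- c(37.0, 40.4, 44.0, 46.9, 49.8, 52.9, 55.5, 58.6,
                      62.0, 66.3)

#' Soluble fraction of a melting protein at a given temperature
#'
#' The standard melt sigmoid: f(T) = (1 - plateau) /
#' (1 + exp((T - Tm)/slope)) + plateau. Exported so tests can evaluate
#' the planted model analytically.
#'
#' @param temp temperature (degC), vectorized
#' @param tm melting temperature (degC)
#' @param slope transition width (degC, > 0)
#' @param plateau non-denaturable floor in \[0, 1)
#' @return soluble fraction in (0, 1\]
#' @export
melt_fraction <- function(temp, tm, slope = 2, plateau = 0.05) {
  stopifnot(plateau >= 0, plateau < 1, slope > 0)
  (1 - plateau) / (1 + exp((temp - tm) / slope)) + plateau
}

#' Simulate a TPP melting-curve experiment
#'
#' Proteins melt as sigmoids with per-protein melting temperature drawn
#' uniformly from `tm_range`; a designated subset responds to treatment
#' with a melting-point shift `delta_tm` and/or an abundance shift
#' `delta_abundance` (log2 units). Intensities carry multiplicative
#' log-normal noise of coefficient of variation `noise_cv` (mean 1).
#'
#' @param n_proteins number of proteins (default 1000)
#' @param temperatures temperature grid (default [TPP_TEMPERATURES])
#' @param n_stabilized,n_destabilized numbers of proteins given `+delta_tm`
#'   / `-delta_tm` melting shifts under treatment (disjoint subsets)
#' @param delta_tm melting-point shift magnitude in degC (default 2)
#' @param n_abundance_shifted proteins given an abundance shift (disjoint
#'   from the stability subsets)
#' @param delta_abundance abundance shift in log2 units (default 1)
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.05)
#' @param tm_range melting-temperature range (default c(45, 55) degC,
#'   resembling published human meltome ranges)
#' @param slope,plateau melt-curve shape (defaults 2 degC and 0.05)
#' @param control,treatment condition labels
#' @param seed master seed
#' @return list with `curves` (a [melt_curve_matrix()] with the control
#'   and treatment conditions) and `truth` (data.frame: `protein_id`,
#'   `tm`, `delta_tm`, `delta_abundance`, `class`)
#' @examples
#' sim <- gen_tpp(n_proteins = 20, n_stabilized = 2, seed = 7)
#' sim$truth[sim$truth$class == "stabilized", ]
#' @export
gen_tpp <- function(n_proteins = 1000, temperatures = TPP_TEMPERATURES,
                    n_stabilized = 0, n_destabilized = 0, delta_tm = 2,
                    n_abundance_shifted = 0, delta_abundance = 1,
                    noise_cv = 0.05, tm_range = c(45, 55), slope = 2,
                    plateau = 0.05, control = "DMSO",
                    treatment = "treated", seed = 1) {
  stopifnot(n_stabilized + n_destabilized + n_abundance_shifted <=
              n_proteins, noise_cv >= 0)
  with_stream(seed, "tpp", {
    ids <- sprintf("P%04d", seq_len(n_proteins))
    tm <- runif(n_proteins, tm_range[1], tm_range[2])
    base_a <- 1e6 * rlnorm(n_proteins, 0, 0.5)
    dtm <- numeric(n_proteins)
    dab <- numeric(n_proteins)
    cls <- rep("null", n_proteins)
    idx <- sample.int(n_proteins,
                      n_stabilized + n_destabilized + n_abundance_shifted)
    if (n_stabilized > 0) {
      i <- idx[seq_len(n_stabilized)]
      dtm[i] <- delta_tm; cls[i] <- "stabilized"
    }
    if (n_destabilized > 0) {
      i <- idx[n_stabilized + seq_len(n_destabilized)]
      dtm[i] <- -delta_tm; cls[i] <- "destabilized"
    }
    if (n_abundance_shifted > 0) {
      i <- idx[n_stabilized + n_destabilized +
                 seq_len(n_abundance_shifted)]
      dab[i] <- delta_abundance; cls[i] <- "abundance_shifted"
    }
    nT <- length(temperatures)
    arr <- array(NA_real_, dim = c(n_proteins, nT, 2L),
                 dimnames = list(ids, as.character(temperatures),
                                 c(control, treatment)))
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- function() {
      if (noise_cv == 0) 1
      else rlnorm(n_proteins * nT, -sdlog^2 / 2, sdlog)
    }
    f_ctrl <- outer(tm, temperatures,
                    function(m, t) melt_fraction(t, m, slope, plateau))
    f_trt <- outer(tm + dtm, temperatures,
                   function(m, t) melt_fraction(t, m, slope, plateau))
    arr[, , control] <- base_a * f_ctrl * noise()
    arr[, , treatment] <- (base_a * 2^dab) * f_trt * noise()
    list(curves = melt_curve_matrix(arr, temperatures = temperatures,
                                    control = control),
         truth = data.frame(protein_id = ids, tm = tm, delta_tm = dtm,
                            delta_abundance = dab, class = cls,
                            stringsAsFactors = FALSE))
  })
}

# add a round 2-d Gaussian blob in place
add_blob <- function(img, cx, cy, sigma, amplitude) {
  n <- nrow(img); m <- ncol(img)
  r <- ceiling(4 * sigma)
  xs <- max(1, round(cx) - r):min(n, round(cx) + r)
  ys <- max(1, round(cy) - r):min(m, round(cy) + r)
  g <- outer(xs, ys, function(x, y) {
    amplitude * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
  })
  img[xs, ys] <- img[xs, ys] + g
  img
}

#' Simulate a multichannel field of view
#'
#' Places `n_nuclei` Gaussian-profile nuclei without overlap, plants
#' `round(n_nuclei * granules_per_cell)` bright cytoplasmic puncta away
#' from nuclei and `n_intranuclear` puncta at nucleus centers, and adds
#' optional Gaussian read noise. The DNA channel carries only nuclei; the
#' reporter channel carries a diffuse nuclear pool, a weak cytoplasmic
#' background and the puncta.
#'
#' @param n_nuclei nuclei count (>= 0)
#' @param granules_per_cell planted cytoplasmic puncta per nucleus
#' @param n_granules explicit cytoplasmic puncta count, overriding
#'   `granules_per_cell` (needed when `n_nuclei = 0`)
#' @param n_intranuclear puncta planted inside nuclei (default 0)
#' @param shape image dimensions in pixels (default 256 x 256, min 64)
#' @param nucleus_sigma,granule_sigma Gaussian radii in px (defaults 6, 2)
#' @param nucleus_intensity,granule_intensity,cyto_intensity amplitudes
#' @param noise_sd additive Gaussian noise sd (default 0 = noiseless)
#' @param max_tries placement retries before an infeasible-packing error
#' @param seed master seed
#' @return list with `channels` (list of matrices `dna`, `reporter`) and
#'   `truth` (planted counts and coordinates)
#' @export
gen_field_image <- function(n_nuclei = 10, granules_per_cell = 3,
                            n_granules = NULL, n_intranuclear = 0,
                            shape = c(256, 256), nucleus_sigma = 6,
                            granule_sigma = 2, nucleus_intensity = 0.6,
                            granule_intensity = 1, cyto_intensity = 0.05,
                            noise_sd = 0, max_tries = 5000, seed = 1) {
  stopifnot(all(shape >= 64), n_nuclei >= 0, n_intranuclear >= 0)
  if (is.null(n_granules)) n_granules <- round(n_nuclei * granules_per_cell)
  if (n_intranuclear > 0 && n_nuclei == 0) {
    stop("cannot place intranuclear puncta without nuclei")
  }
  with_stream(seed, "field_image", {
    margin <- 5 * nucleus_sigma
    place <- function(n, min_dist, avoid = NULL, avoid_dist = 0) {
      pts <- matrix(numeric(0), ncol = 2)
      tries <- 0
      while (nrow(pts) < n) {
        tries <- tries + 1
        if (tries > max_tries) {
          stop("infeasible packing: could not place objects")
        }
        p <- c(runif(1, margin, shape[1] - margin),
               runif(1, margin, shape[2] - margin))
        ok <- TRUE
        if (nrow(pts) > 0) {
          ok <- all(sqrt(rowSums(sweep(pts, 2, p)^2)) >= min_dist)
        }
        if (ok && !is.null(avoid) && nrow(avoid) > 0) {
          ok <- all(sqrt(rowSums(sweep(avoid, 2, p)^2)) >= avoid_dist)
        }
        if (ok) pts <- rbind(pts, p)
      }
      pts
    }
    nuc <- place(n_nuclei, min_dist = 6 * nucleus_sigma)
    gra <- place(n_granules, min_dist = 6 * granule_sigma, avoid = nuc,
                 avoid_dist = 5 * nucleus_sigma)
    dna <- matrix(0, shape[1], shape[2])
    rep_ch <- matrix(cyto_intensity, shape[1], shape[2])
    for (i in seq_len(n_nuclei)) {
      dna <- add_blob(dna, nuc[i, 1], nuc[i, 2], nucleus_sigma, 1)
      rep_ch <- add_blob(rep_ch, nuc[i, 1], nuc[i, 2], nucleus_sigma,
                         nucleus_intensity)
    }
    for (i in seq_len(n_granules)) {
      rep_ch <- add_blob(rep_ch, gra[i, 1], gra[i, 2], granule_sigma,
                         granule_intensity)
    }
    intra <- matrix(numeric(0), ncol = 2)
    if (n_intranuclear > 0) {
      which_nuc <- sample.int(n_nuclei, n_intranuclear, replace = TRUE)
      intra <- nuc[which_nuc, , drop = FALSE] +
        matrix(runif(2 * n_intranuclear, -1, 1), ncol = 2)
      for (i in seq_len(n_intranuclear)) {
        rep_ch <- add_blob(rep_ch, intra[i, 1], intra[i, 2],
                           granule_sigma, granule_intensity)
      }
    }
    if (noise_sd > 0) {
      dna <- dna + matrix(rnorm(length(dna), 0, noise_sd), nrow(dna))
      rep_ch <- rep_ch + matrix(rnorm(length(rep_ch), 0, noise_sd),
                                nrow(rep_ch))
      dna[dna < 0] <- 0
      rep_ch[rep_ch < 0] <- 0
    }
    list(channels = list(dna = dna, reporter = rep_ch),
         truth = list(n_nuclei = n_nuclei, n_granules = n_granules,
                      n_intranuclear = n_intranuclear,
                      nucleus_centers = nuc, granule_centers = gra,
                      intranuclear_centers = intra))
  })
}

#' Simulate a multi-plate screening feature table
#'
#' Control and untreated wells draw their feature vectors from a
#' multivariate normal with AR(1) correlation (`rho^|i-j|`); planted hits
#' are shifted by a stated per-feature multiple of the feature standard
#' deviation with random signs.
#'
#' @param n_plates number of plates (default 1)
#' @param wells_per_plate wells per plate (default 384)
#' @param n_controls control wells per plate (default 32)
#' @param n_features feature count (default 15)
#' @param n_hits planted hits across the whole screen (default 0)
#' @param hit_shift_range per-feature shift magnitude range in sd units
#'   (default c(2, 4))
#' @param rho AR(1) feature correlation (default 0.5)
#' @param seed master seed
#' @return list with `wells` (data.frame ready for [score_screen()]) and
#'   `truth` (data.frame of hit wells and their shift magnitudes)
#' @export
gen_plate <- function(n_plates = 1, wells_per_plate = 384,
                      n_controls = 32, n_features = 15, n_hits = 0,
                      hit_shift_range = c(2, 4), rho = 0.5, seed = 1) {
  stopifnot(n_controls >= 2, wells_per_plate > n_controls)
  with_stream(seed, "plate", {
    p <- n_features
    sigma <- rho^abs(outer(seq_len(p), seq_len(p), `-`))
    ch <- chol(sigma)
    n_total <- n_plates * wells_per_plate
    x <- matrix(rnorm(n_total * p), n_total, p) %*% ch
    colnames(x) <- sprintf("feature_%02d", seq_len(p))
    plate_id <- rep(sprintf("plate%02d", seq_len(n_plates)),
                    each = wells_per_plate)
    well_id <- sprintf("%s_w%03d", plate_id,
                       rep(seq_len(wells_per_plate), n_plates))
    role <- rep("treatment", n_total)
    for (pl in seq_len(n_plates)) {
      offs <- (pl - 1L) * wells_per_plate
      role[offs + sample.int(wells_per_plate, n_controls)] <- "control"
    }
    treat_idx <- which(role == "treatment")
    hits <- integer(0)
    shift_mag <- numeric(0)
    if (n_hits > 0) {
      hits <- sort(sample(treat_idx, n_hits))
      shift_mag <- runif(n_hits, hit_shift_range[1], hit_shift_range[2])
      for (k in seq_len(n_hits)) {
        signs <- sample(c(-1, 1), p, replace = TRUE)
        x[hits[k], ] <- x[hits[k], ] + shift_mag[k] * signs
      }
    }
    wells <- data.frame(plate_id = plate_id, well_id = well_id,
                        compound_id = ifelse(role == "control", "DMSO",
                                             well_id),
                        role = role, stringsAsFactors = FALSE)
    wells <- cbind(wells, as.data.frame(x))
    list(wells = wells,
         truth = data.frame(well_id = well_id[hits],
                            shift_sd = shift_mag,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate dose-response series from a four-parameter logistic model
#'
#' @param ec50 true EC50 (same units as `concentrations`)
#' @param slope true Hill slope (> 0: response falls with dose)
#' @param bottom,top asymptotes
#' @param concentrations concentration grid (default 12 half-log steps
#'   from 1 nM to 100 uM)
#' @param noise_cv multiplicative log-normal noise CV (default 0)
#' @param n_replicates independent replicate series (default 1)
#' @param seed master seed
#' @return list with `curves` (data.frame `replicate`, `concentration`,
#'   `response`) and `truth` (the model parameters)
#' @export
gen_dose_response <- function(ec50 = 2e-6, slope = 1.5, bottom = 0.1,
                              top = 3,
                              concentrations = 10^seq(-9, -4,
                                                      length.out = 12),
                              noise_cv = 0, n_replicates = 1, seed = 1) {
  stopifnot(ec50 > 0, all(concentrations > 0), noise_cv >= 0)
  with_stream(seed, "dose_response", {
    mu <- bottom + (top - bottom) / (1 + (concentrations / ec50)^slope)
    sdlog <- sqrt(log(1 + noise_cv^2))
    curves <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      noise <- if (noise_cv == 0) 1
               else rlnorm(length(mu), -sdlog^2 / 2, sdlog)
      data.frame(replicate = r, concentration = concentrations,
                 response = mu * noise)
    }))
    list(curves = curves,
         truth = list(ec50 = ec50, slope = slope, bottom = bottom,
                      top = top, noise_cv = noise_cv))
  })
}

# residue frequencies of an average globular proteome (approximate
# vertebrate background), used by the disorder generator
AA_BACKGROUND_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.036, G = 0.066,
  H = 0.026, I = 0.044, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
  W = 0.012, Y = 0.027)

#' Simulate multi-predictor disorder tracks with planted IDRs
#'
#' Each protein gets one planted IDR whose length depends on its class
#' (stabilized proteins get longer IDRs); inside the IDR each predictor
#' calls disorder with probability `agreement`, outside with probability
#' `false_call_rate`. Sequences are drawn from a background residue
#' distribution, except stabilized-class IDR residues, whose
#' arginine/tyrosine/phenylalanine frequencies are multiplied by
#' `enrich_factor` (renormalized).
#'
#' @param n_proteins number of proteins
#' @param class_probs named probabilities for classes stabilized /
#'   destabilized / unaffected (default c(0.012, 0.024, 0.964),
#'   resembling the 70/144/5811 split of a genome-scale TPP experiment)
#' @param n_predictors predictors per residue (default 8)
#' @param agreement within-IDR per-predictor call probability (default 1)
#' @param false_call_rate outside-IDR call probability (default 0.02)
#' @param length_range protein length range (default c(200, 500))
#' @param idr_length_range IDR length by class: a list with elements
#'   `stabilized`, `destabilized`, `unaffected` (defaults c(60, 120),
#'   c(15, 40), c(20, 60))
#' @param enrich_aa residues enriched in stabilized-class IDRs
#' @param enrich_factor enrichment multiplier (default 2)
#' @param seed master seed
#' @return list with `profiles` (named list of residue x predictor call
#'   matrices), `sequences` (named character), `truth` (data.frame:
#'   `protein_id`, `class`, `idr_start`, `idr_end`, `length`)
#' @export
gen_disorder <- function(n_proteins = 100,
                         class_probs = c(stabilized = 0.012,
                                         destabilized = 0.024,
                                         unaffected = 0.964),
                         n_predictors = 8, agreement = 1,
                         false_call_rate = 0.02,
                         length_range = c(200, 500),
                         idr_length_range = list(
                           stabilized = c(60, 120),
                           destabilized = c(15, 40),
                           unaffected = c(20, 60)),
                         enrich_aa = c("R", "Y", "F"),
                         enrich_factor = 2, seed = 1) {
  with_stream(seed, "disorder", {
    ids <- sprintf("D%04d", seq_len(n_proteins))
    cls <- sample(names(class_probs), n_proteins, replace = TRUE,
                  prob = class_probs)
    enriched_freq <- AA_BACKGROUND_FREQ
    enriched_freq[enrich_aa] <- enriched_freq[enrich_aa] * enrich_factor
    enriched_freq <- enriched_freq / sum(enriched_freq)
    profiles <- vector("list", n_proteins)
    seqs <- character(n_proteins)
    truth <- data.frame(protein_id = ids, class = cls,
                        idr_start = NA_integer_, idr_end = NA_integer_,
                        length = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_len(n_proteins)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      ir <- idr_length_range[[cls[i]]]
      ilen <- min(sample(ir[1]:ir[2], 1L), len - 2L)
      start <- sample.int(len - ilen + 1L, 1L)
      end <- start + ilen - 1L
      in_idr <- seq_len(len) >= start & seq_len(len) <= end
      pcall <- ifelse(in_idr, agreement, false_call_rate)
      calls <- matrix(runif(len * n_predictors) <
                        rep(pcall, n_predictors), len, n_predictors)
      freq_in <- if (cls[i] == "stabilized") enriched_freq
                 else AA_BACKGROUND_FREQ
      s <- character(len)
      s[!in_idr] <- sample(names(AA_BACKGROUND_FREQ), sum(!in_idr),
                           replace = TRUE, prob = AA_BACKGROUND_FREQ)
      s[in_idr] <- sample(names(freq_in), sum(in_idr), replace = TRUE,
                          prob = freq_in)
      profiles[[i]] <- calls
      seqs[i] <- paste(s, collapse = "")
      truth$idr_start[i] <- start
      truth$idr_end[i] <- end
      truth$length[i] <- len
    }
    names(profiles) <- ids
    names(seqs) <- ids
    list(profiles = profiles, sequences = seqs, truth = truth)
  })
}
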