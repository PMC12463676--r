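#' Melting-curve intensity container for thermal proteome profiling
#'
#' Holds soluble-protein reporter intensities on a protein x temperature x
#' condition grid, the raw material of TPP scoring. Every condition shares
#' the same strictly increasing temperature grid and one condition is
#' designated the vehicle control.
#'
#' @param intensity numeric 3-d array, dimensions protein x temperature x
#'   condition, with `dimnames` giving protein ids, temperatures and
#'   condition labels (temperature dimnames may be omitted if `temperatures`
#'   is supplied). Intensities are non-negative; `NA` marks a protein not
#'   quantified at that temperature/condition.
#' @param temperatures numeric vector of temperatures in degrees Celsius,
#'   strictly increasing, length `dim(intensity)[2]`.
#' @param control label of the control condition (e.g. `"DMSO"`); must be
#'   one of the condition labels.
#' @return an object of class `melt_curve_matrix`
#' @examples
#' arr <- array(100, dim = c(2, 3, 2),
#'              dimnames = list(c("P1", "P2"), NULL, c("DMSO", "drug")))
#' m <- melt_curve_matrix(arr, temperatures = c(37, 44, 52), control = "DMSO")
#' dim(m$intensity)
#' @export
melt_curve_matrix <- function(intensity, temperatures = NULL,
                              control = "DMSO") {
  if (!is.array(intensity) || length(dim(intensity)) != 3L) {
    stop("`intensity` must be a 3-d array (protein x temperature x condition)")
  }
  dn <- dimnames(intensity)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[3]])) {
    stop("`intensity` needs protein ids and condition labels as dimnames")
  }
  if (is.null(temperatures)) temperatures <- as.numeric(dn[[2]])
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) != dim(intensity)[2] || anyNA(temperatures)) {
    stop("`temperatures` must be numeric, one per temperature slice")
  }
  if (length(temperatures) < 2L || any(diff(temperatures) <= 0)) {
    stop("temperatures must be strictly increasing with length >= 2")
  }
  conditions <- dn[[3]]
  if (!control %in% conditions) {
    stop(sprintf("control condition '%s' not present in data", control))
  }
  if (any(intensity[!is.na(intensity)] < 0)) {
    stop("intensities must be non-negative")
  }
  dimnames(intensity)[[2]] <- as.character(temperatures)
  structure(
    list(intensity = intensity,
         protein_ids = dn[[1]],
         temperatures = temperatures,
         conditions = conditions,
         control = control),
    class = "melt_curve_matrix"
  )
}

#' @export
print.melt_curve_matrix <- function(x, ...) {
  cat(sprintf(
    "Melting-curve matrix: %d proteins x %d temperatures x %d conditions\n",
    length(x$protein_ids), length(x$temperatures), length(x$conditions)))
  cat(sprintf("  temperatures (degC): %s\n",
              paste(x$temperatures, collapse = ", ")))
  cat(sprintf("  conditions: %s (control: %s)\n",
              paste(x$conditions, collapse = ", "), x$control))
  na_frac <- mean(is.na(x$intensity))
  cat(sprintf("  missing values: %.1f%%\n", 100 * na_frac))
  invisible(x)
}

#' Read melting curves from a long- or wide-format table
#'
#' Long format has columns `protein_id, condition, temperature, intensity`;
#' wide format has a `protein_id` column plus one `<condition>_<temperature>`
#' column per cell of the design.
#'
#' @param path TSV/CSV file path; the delimiter is inferred from the
#'   extension (`.csv` = comma, otherwise tab)
#' @param control control condition label
#' @param format `"long"` or `"wide"`
#' @return a [melt_curve_matrix()]
#' @export
read_melt_curves <- function(path, control = "DMSO",
                             format = c("long", "wide")) {
  format <- match.arg(format)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv
            else read.delim
  df <- reader(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "long") {
    need <- c("protein_id", "condition", "temperature", "intensity")
    if (!all(need %in% names(df))) {
      stop("long format needs columns: ", paste(need, collapse = ", "))
    }
    prot <- sort(unique(df$protein_id))
    temps <- sort(unique(as.numeric(df$temperature)))
    conds <- unique(df$condition)
    arr <- array(NA_real_, dim = c(length(prot), length(temps), length(conds)),
                 dimnames = list(prot, as.character(temps), conds))
    idx <- cbind(match(df$protein_id, prot),
                 match(as.numeric(df$temperature), temps),
                 match(df$condition, conds))
    arr[idx] <- df$intensity
  } else {
    if (!"protein_id" %in% names(df)) stop("wide format needs `protein_id`")
    cols <- setdiff(names(df), "protein_id")
    m <- regmatches(cols, regexec("^(.*)_([0-9.]+)$", cols))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad)) stop("unparseable wide columns: ",
                       paste(cols[bad], collapse = ", "))
    conds <- unique(vapply(m, `[`, "", 2L))
    temps <- sort(unique(as.numeric(vapply(m, `[`, "", 3L))))
    arr <- array(NA_real_,
                 dim = c(nrow(df), length(temps), length(conds)),
                 dimnames = list(df$protein_id, as.character(temps), conds))
    for (j in seq_along(cols)) {
      arr[, match(as.numeric(m[[j]][3]), temps), m[[j]][2]] <- df[[cols[j]]]
    }
  }
  melt_curve_matrix(arr, control = control)
}

#' Write a melt-curve matrix as a long-format TSV
#' @param x a [melt_curve_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_melt_curves <- function(x, path) {
  stopifnot(inherits(x, "melt_curve_matrix"))
  g <- expand.grid(protein_id = x$protein_ids,
                   temperature = x$temperatures,
                   condition = x$conditions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$intensity <- as.vector(x$intensity)
  g <- g[!is.na(g$intensity), ]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
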