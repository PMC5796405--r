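## Per-residue input feature construction.
##
## Model M1: 7 physicochemical properties + 20 PSSM scores = 27 features
## per residue, sliding window of 13 -> 351 inputs.
## Model M2: 20 PSSM scores + 18 predicted structure properties = 38
## features per residue, sliding window of 7 -> 266 inputs.

PROPERTY_COLUMNS <- c("ss_H", "ss_E", "ss_C", "rsa",
                      "phi_sin", "phi_cos", "psi_sin", "psi_cos",
                      "theta_sin", "theta_cos", "tau_sin", "tau_cos",
                      "cn_ca", "cn_cb",
                      "hseb_up", "hseb_down", "hsea_up", "hsea_down")

aaPropEnv <- new.env(parent = emptyenv())

aaPropertiesTable <- function() {
  if (is.null(aaPropEnv$tab)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "torsionGrid")
    tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    rownames(tab) <- tab$aa
    aaPropEnv$tab <- as.matrix(tab[, -1L])
  }
  aaPropEnv$tab
}

#' Seven amino-acid properties
#'
#' Returns the seven representative physicochemical properties (steric
#' parameter, hydrophobicity, volume, polarizability, isoelectric point,
#' helix probability, sheet probability) from the table shipped in
#' \code{inst/extdata/aa_properties.tsv}. The unknown residue code
#' \code{"X"} maps to the column-wise mean of the 20 standard residues.
#'
#' @param residue character vector of 1-letter residue codes.
#' @return a matrix with one 7-value row per input code (a single row for
#'   a single code).
#' @export
aaProperties <- function(residue) {
  tab <- aaPropertiesTable()
  res <- toupper(residue)
  unknown <- setdiff(res, c(rownames(tab), "X"))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  xrow <- colMeans(tab)
  out <- matrix(NA_real_, length(res), ncol(tab),
                dimnames = list(residue, colnames(tab)))
  std <- res %in% rownames(tab)
  if (any(std)) out[std, ] <- tab[res[std], , drop = FALSE]
  if (any(!std)) out[!std, ] <- matrix(xrow, sum(!std), ncol(tab), byrow = TRUE)
  out
}

#' Transform raw PSSM log-odds scores
#'
#' The default squashes each score x through the logistic function
#' 1/(1 + exp(-x)), the common convention of sequence-based
#' structure-property predictors (integer log-odds saturate sigmoid
#' units); alternatives are the raw scores or a per-column z-score.
#'
#' @param pssm a \linkS4class{PssmProfile}.
#' @param method "logistic" (default), "raw" or "zscore".
#' @return a \linkS4class{PssmProfile} with transformed scores.
#' @export
transformPssm <- function(pssm, method = c("logistic", "raw", "zscore")) {
  stopifnot(is(pssm, "PssmProfile"))
  method <- match.arg(method)
  s <- pssm@scores
  s <- switch(method,
    logistic = 1 / (1 + exp(-s)),
    raw = s,
    zscore = {
      mu <- colMeans(s)
      sdv <- apply(s, 2L, sd)
      sdv[sdv == 0] <- 1
      sweep(sweep(s, 2L, mu, "-"), 2L, sdv, "/")
    })
  initialize(pssm, scores = s)
}

## Concatenate each residue's base feature block with its window context;
## positions beyond the chain termini contribute zeros.
slideWindow <- function(base, window) {
  if (window %% 2L != 1L) stop("'window' must be odd", call. = FALSE)
  n <- nrow(base); d <- ncol(base)
  half <- (window - 1L) %/% 2L
  out <- matrix(0, n, d * window)
  nms <- character(d * window)
  for (w in seq_len(window)) {
    off <- w - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    cols <- (w - 1L) * d + seq_len(d)
    out[ok, cols] <- base[src[ok], , drop = FALSE]
    nms[cols] <- sprintf("pos%+d.%s", off, colnames(base))
  }
  colnames(out) <- nms
  out
}

#' Build M1 feature vectors (properties + PSSM)
#'
#' Per residue: 7 amino-acid properties plus 20 transformed PSSM scores
#' (27 features), concatenated over a sliding window of 13 residues (6 on
#' each side, zero-padded past the termini) for 351 inputs per residue.
#'
#' @param pssm a \linkS4class{PssmProfile}.
#' @param window odd window size; default 13.
#' @param transform PSSM score transform passed to \code{transformPssm}.
#' @return numeric feature matrix (residues x 27*window) with named columns.
#' @export
buildM1 <- function(pssm, window = 13L, transform = "logistic") {
  stopifnot(is(pssm, "PssmProfile"))
  if (length(pssm@sequence) == 0L) stop("empty profile", call. = FALSE)
  props <- aaProperties(pssm@sequence)
  rownames(props) <- NULL
  scores <- transformPssm(pssm, transform)@scores
  colnames(scores) <- paste0("pssm.", colnames(pssm@scores))
  slideWindow(cbind(props, scores), as.integer(window))
}

#' Build M2 feature vectors (PSSM + structure properties)
#'
#' Per residue: 20 transformed PSSM scores plus the 18 structure-property
#' values (3 secondary-structure probabilities, RSA, sin/cos of the four
#' backbone angles, 2 contact numbers, 4 half-sphere exposures) for a base
#' block of 38, concatenated over a sliding window of 7 (3 on each side,
#' zero-padded) for 266 inputs per residue.
#'
#' @param pssm a \linkS4class{PssmProfile}.
#' @param props a structure-property data.frame with the 18 columns listed
#'   in \code{PROPERTY_COLUMNS} (see \code{propsFromAngles} and
#'   \code{readPropertyTable}).
#' @param window odd window size; default 7.
#' @param transform PSSM score transform passed to \code{transformPssm}.
#' @return numeric feature matrix (residues x 38*window) with named columns.
#' @export
buildM2 <- function(pssm, props, window = 7L, transform = "logistic") {
  stopifnot(is(pssm, "PssmProfile"))
  props <- validatePropertyTable(props)
  if (nrow(props) != length(pssm@sequence))
    stop("PSSM and structure-property table lengths differ", call. = FALSE)
  scores <- transformPssm(pssm, transform)@scores
  colnames(scores) <- paste0("pssm.", colnames(pssm@scores))
  slideWindow(cbind(scores, as.matrix(props)), as.integer(window))
}

validatePropertyTable <- function(props) {
  props <- as.data.frame(props)
  miss <- setdiff(PROPERTY_COLUMNS, names(props))
  if (length(miss))
    stop("structure-property table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  props <- props[, PROPERTY_COLUMNS]
  ss <- as.matrix(props[, c("ss_H", "ss_E", "ss_C")])
  if (any(ss < 0 | ss > 1))
    stop("secondary-structure probabilities must lie in [0, 1]",
         call. = FALSE)
  for (k in ANGLE_KINDS) {
    nrm <- props[[paste0(k, "_sin")]]^2 + props[[paste0(k, "_cos")]]^2
    if (any(nrm > 1 + 1e-6))
      stop(sprintf("%s sin/cos pair exceeds unit norm", k), call. = FALSE)
  }
  props
}

#' Assemble a structure-property table from angles and extras
#'
#' Encodes each backbone angle as (sin, cos) computed in radians, with
#' undefined angles contributing (0, 0), and binds the remaining ten
#' structure properties (secondary-structure probabilities, RSA, contact
#' numbers, half-sphere exposures).
#'
#' @param angles an \linkS4class{AngleTable}.
#' @param extras data.frame with columns ss_H, ss_E, ss_C, rsa, cn_ca,
#'   cn_cb, hseb_up, hseb_down, hsea_up, hsea_down and one row per residue.
#' @return data.frame with the 18 canonical structure-property columns.
#' @export
propsFromAngles <- function(angles, extras) {
  stopifnot(is(angles, "AngleTable"))
  extras <- as.data.frame(extras)
  need <- setdiff(PROPERTY_COLUMNS, c(paste0(rep(ANGLE_KINDS, each = 2L),
                                             c("_sin", "_cos"))))
  miss <- setdiff(need, names(extras))
  if (length(miss))
    stop("extras missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(extras) != nResidues(angles))
    stop("extras row count must match the angle table", call. = FALSE)
  out <- extras[, need, drop = FALSE]
  for (k in ANGLE_KINDS) {
    a <- angleValues(angles, k) * pi / 180
    def <- definedMask(angles, k)
    out[[paste0(k, "_sin")]] <- ifelse(def, sin(a), 0)
    out[[paste0(k, "_cos")]] <- ifelse(def, cos(a), 0)
  }
  out[, PROPERTY_COLUMNS]
}
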