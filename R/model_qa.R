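## Model quality assessment from predicted angle probabilities: the
## pseudo-energy PE-score = sum_i log(P_i / P0_i) over the bins occupied
## by a candidate model, evaluated against superposition-based quality
## (S-score, GDT-style score) via Pearson correlation.

#' Estimate background bin frequencies from an angle corpus
#'
#' The expected probability P0 of each bin is its pseudocounted relative
#' frequency over all defined angles of the corpus:
#' (count + pseudocount) / (N + pseudocount * K).
#'
#' @param angleTables a list of \linkS4class{AngleTable} objects (or one).
#' @param scheme a \linkS4class{BinScheme}.
#' @param pseudocount added to every bin; default 1.
#' @return a \linkS4class{BackgroundDistribution}.
#' @export
estimateBackground <- function(angleTables, scheme, pseudocount = 1) {
  if (is(angleTables, "AngleTable")) angleTables <- list(angleTables)
  if (!length(angleTables)) stop("empty angle corpus", call. = FALSE)
  stopifnot(is(scheme, "BinScheme"))
  freq <- list()
  for (k in ANGLE_KINDS) {
    K <- scheme@bins[[k]]
    counts <- numeric(K)
    N <- 0L
    for (tab in angleTables) {
      bins <- angleToBin(angleValues(tab, k)[definedMask(tab, k)], k, scheme)
      counts <- counts + tabulate(bins, nbins = K)
      N <- N + length(bins)
    }
    if (N == 0L)
      stop(sprintf("corpus has no defined %s angles", k), call. = FALSE)
    freq[[k]] <- (counts + pseudocount) / (N + pseudocount * K)
  }
  new("BackgroundDistribution", freq = freq, pseudocount = pseudocount,
      scheme = scheme)
}

#' Pseudo-energy score of a model structure
#'
#' For every residue whose angle is defined in the model, the log-ratio of
#' the predicted probability at the model's occupied bin to the background
#' probability of that bin is accumulated (natural log): PE =
#' sum_i log(P_i / P0_i). Higher is better. Predicted probabilities below
#' \code{eps} are floored, with the number of floored residues reported in
#' the \code{nFloored} attribute.
#'
#' @param profile a \linkS4class{ProbabilityProfile} for the target
#'   sequence.
#' @param modelAngles the \linkS4class{AngleTable} of the candidate model,
#'   aligned by residue with the profile.
#' @param background a \linkS4class{BackgroundDistribution}.
#' @param kind one of "phi", "psi", "theta", "tau".
#' @param eps probability floor; default 1e-8.
#' @param perResidue if TRUE, return the mean instead of the sum (model
#'   lengths vary; the sum is the canonical definition).
#' @return the PE-score, with attributes \code{n} (residues used) and
#'   \code{nFloored}.
#' @export
peScore <- function(profile, modelAngles, background, kind, eps = 1e-8,
                    perResidue = FALSE) {
  kind <- checkKind(kind)
  stopifnot(is(profile, "ProbabilityProfile"),
            is(modelAngles, "AngleTable"),
            is(background, "BackgroundDistribution"))
  if (nResidues(profile) != nResidues(modelAngles))
    stop("profile and model angle table are not aligned", call. = FALSE)
  if (!isTRUE(all.equal(profile@scheme@bins, background@scheme@bins)))
    stop("profile and background use different schemes", call. = FALSE)
  ok <- which(definedMask(modelAngles, kind))
  if (!length(ok)) {
    warning("model has no defined ", kind, " angles; PE-score undefined",
            call. = FALSE)
    return(NA_real_)
  }
  bins <- angleToBin(angleValues(modelAngles, kind)[ok], kind,
                     profile@scheme)
  block <- angleBlock(profile, kind)
  p <- block[cbind(ok, bins)]
  nFloored <- sum(p < eps)
  p <- pmax(p, eps)
  p0 <- background@freq[[kind]][bins]
  val <- sum(log(p / p0))
  if (perResidue) val <- val / length(ok)
  structure(val, n = length(ok), nFloored = nFloored)
}

#' Combined PE-score over the four angle kinds
#'
#' Sum of the four per-angle PE-scores (per-angle scores are the
#' canonical, separately reported quantities).
#'
#' @inheritParams peScore
#' @return named numeric vector with the four per-angle scores and
#'   \code{combined}.
#' @export
peScoreAll <- function(profile, modelAngles, background, eps = 1e-8) {
  vals <- vapply(ANGLE_KINDS, function(k)
    as.numeric(suppressWarnings(peScore(profile, modelAngles, background,
                                        k, eps))), numeric(1L))
  c(vals, combined = sum(vals, na.rm = TRUE))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of matched coordinate sets via SVD of the
#' covariance matrix, constrained to a proper rotation. Decoys share the
#' target's sequence, so residues are matched by position (no structural
#' alignment search).
#'
#' @param modelCa,nativeCa matched n x 3 coordinate matrices (n >= 3).
#' @return list with \code{rotation} (3 x 3), \code{translation} (length
#'   3; the superposed model is \code{modelCa \%*\% rotation + translation}),
#'   \code{d} (per-residue distances after superposition) and \code{rmsd}.
#' @export
kabschSuperpose <- function(modelCa, nativeCa) {
  P <- as.matrix(modelCa); Q <- as.matrix(nativeCa)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("coordinate sets must be matched n x 3 matrices", call. = FALSE)
  if (nrow(P) < 3L)
    stop("at least 3 matched residues are required", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
  fitted <- Pc %*% R
  d <- sqrt(rowSums((fitted - Qc)^2))
  list(rotation = R, translation = as.numeric(cq - cp %*% R),
       d = d, rmsd = sqrt(mean(d^2)))
}

#' Local quality S-score
#'
#' S = 1 / (1 + (d / d0)^2) with d0 = 3 Angstrom: 1 at zero deviation,
#' 0.5 at d = d0, strictly decreasing in d.
#'
#' @param d non-negative per-residue distance(s) in Angstrom.
#' @param d0 reference distance; default 3.
#' @return value(s) in (0, 1].
#' @export
sScore <- function(d, d0 = 3) {
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  1 / (1 + (d / d0)^2)
}

#' GDT-style global quality score
#'
#' Mean over the cutoffs {1, 2, 4, 8} Angstrom of the fraction of native
#' residues whose post-superposition deviation is at most the cutoff.
#' Residues absent from the model count against every cutoff because the
#' denominator is the native length.
#'
#' @param d per-residue distances from \code{kabschSuperpose}.
#' @param lNative native residue count; defaults to \code{length(d)}.
#' @param cutoffs distance cutoffs in Angstrom.
#' @return score in [0, 1].
#' @export
gdtLike <- function(d, lNative = length(d), cutoffs = c(1, 2, 4, 8)) {
  if (!length(d)) stop("empty distance vector", call. = FALSE)
  mean(vapply(cutoffs, function(ct) sum(d <= ct) / lNative, numeric(1L)))
}

#' Score one decoy against a profile and native structure
#'
#' Computes the per-angle and combined PE-scores from the decoy's own
#' backbone angles, and (when a native is given) the superposition-based
#' quality: per-residue S-scores and the GDT-style score.
#'
#' @param decoy a \linkS4class{BackboneChain} candidate model.
#' @param profile the target's \linkS4class{ProbabilityProfile}.
#' @param background a \linkS4class{BackgroundDistribution}.
#' @param native optional native \linkS4class{BackboneChain}.
#' @param id model identifier.
#' @param maxCaDist CA-CA break threshold passed to \code{computeAngles};
#'   decoys are continuous models of the full target sequence, so by
#'   default no distance-based chain break is applied (a heavily distorted
#'   model should be scored on its distorted angles, not silently skipped).
#' @return one-row data.frame: id, the four per-angle PE-scores,
#'   \code{pe} (combined), and with a native also \code{gdt} and
#'   \code{meanS}; per-residue S-scores are in attribute \code{sScores}.
#' @export
scoreDecoy <- function(decoy, profile, background, native = NULL,
                       id = "model", maxCaDist = Inf) {
  angles <- computeAngles(decoy, maxCaDist = maxCaDist)
  pe <- peScoreAll(profile, angles, background)
  out <- data.frame(id = id, t(pe))
  names(out) <- c("id", paste0("pe_", ANGLE_KINDS), "pe")
  if (!is.null(native)) {
    match <- intersect(residueIds(decoy), residueIds(native))
    sup <- kabschSuperpose(caCoords(decoy)[match(match, residueIds(decoy)), ],
                           caCoords(native)[match(match, residueIds(native)), ])
    out$gdt <- gdtLike(sup$d, lNative = nResidues(native))
    s <- sScore(sup$d)
    out$meanS <- mean(s)
    attr(out, "sScores") <- s
  }
  out
}

#' Rank decoy models by PE-score against their quality
#'
#' For each target, the Pearson correlation between PE-score and quality
#' over its decoys, plus the quality of the PE-top-1 model; summarised
#' across targets by mean and median PCC.
#'
#' @param decoys data.frame with columns \code{target}, \code{pe} and
#'   \code{quality} (one row per decoy model).
#' @return list with \code{perTarget} (target, pcc, top1Quality, n),
#'   \code{meanPCC}, \code{medianPCC}, \code{meanTop1}.
#' @export
rankModels <- function(decoys) {
  need <- c("target", "pe", "quality")
  if (!all(need %in% names(decoys)))
    stop("decoys must have columns target, pe, quality", call. = FALSE)
  per <- do.call(rbind, lapply(split(decoys, decoys$target), function(sub) {
    pcc <- if (nrow(sub) >= 2L && sd(sub$pe) > 0 && sd(sub$quality) > 0)
      cor(sub$pe, sub$quality) else {
        warning("zero variance for target '", sub$target[1L],
                "'; PCC undefined", call. = FALSE)
        NA_real_
      }
    data.frame(target = sub$target[1L], pcc = pcc,
               top1Quality = sub$quality[which.max(sub$pe)], n = nrow(sub))
  }))
  rownames(per) <- NULL
  list(perTarget = per,
       meanPCC = mean(per$pcc, na.rm = TRUE),
       medianPCC = median(per$pcc, na.rm = TRUE),
       meanTop1 = mean(per$top1Quality, na.rm = TRUE))
}
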