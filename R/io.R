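## Readers and writers for the package's file formats:
## PSI-BLAST ASCII PSSM, PDB ATOM records, tab-delimited structure-property
## tables, long-format probability profiles, disorder tracks, background
## distributions, residue label files and the model archive.

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard \code{-out_ascii_pssm} layout: the 20 log-odds
#' columns are kept, the 20 weighted-percentage columns are ignored, and
#' the sequence is taken from the second column. A missing footer is
#' tolerated; a garbled body row raises an error naming its line.
#'
#' @param path path to the PSSM file (or a character vector of its lines).
#' @return a \linkS4class{PssmProfile} of raw log-odds scores.
#' @export
readPssm <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  toks <- strsplit(trimws(lines), "\\s+")
  ## candidate body rows: residue index then a 1-letter code
  isBody <- vapply(toks, function(tk)
    length(tk) >= 2L && grepl("^[0-9]+$", tk[1L]) &&
      grepl("^[A-Zx*]$", tk[2L]), logical(1L))
  if (!any(isBody)) stop("no PSSM body rows found", call. = FALSE)
  ## the alphabet header is the last line before the body made of 1-letter codes
  first <- which(isBody)[1L]
  alpha <- NULL
  if (first > 1L) {
    hd <- toks[[first - 1L]]
    if (length(hd) >= 20L && all(grepl("^[A-Z]$", hd)))
      alpha <- hd[1:20]
  }
  if (is.null(alpha))
    alpha <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  allBody <- which(isBody)
  ## the body is the first contiguous run; trailing footer lines are
  ## tolerated, but a break with body rows continuing after it means a
  ## garbled row, not a footer
  body <- allBody[seq_len(which.max(c(diff(allBody) != 1L, TRUE)))]
  if (length(allBody) > length(body))
    stop(sprintf("garbled PSSM row at line %d: '%s'",
                 body[length(body)] + 1L, lines[body[length(body)] + 1L]),
         call. = FALSE)
  n <- length(body)
  seqs <- character(n)
  scores <- matrix(NA_real_, n, 20L, dimnames = list(NULL, alpha))
  for (i in seq_len(n)) {
    tk <- toks[[body[i]]]
    v <- if (length(tk) >= 22L)
      suppressWarnings(as.numeric(tk[3:22])) else NA_real_
    if (anyNA(v))
      stop(sprintf("garbled PSSM row at line %d: '%s'", body[i],
                   lines[body[i]]), call. = FALSE)
    seqs[i] <- toupper(tk[2L])
    scores[i, ] <- v
  }
  new("PssmProfile", sequence = seqs, scores = scores)
}

#' Write a PssmProfile in PSI-BLAST ASCII layout
#'
#' Writes a file that \code{readPssm} parses back identically; the
#' percentage columns are written as zeros.
#'
#' @param pssm a \linkS4class{PssmProfile}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePssm <- function(pssm, path) {
  stopifnot(is(pssm, "PssmProfile"))
  alpha <- colnames(pssm@scores)
  hdr <- c("",
           "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
           paste0("           ", paste(sprintf("%3s", c(alpha, alpha)),
                                       collapse = "")))
  rows <- vapply(seq_along(pssm@sequence), function(i)
    paste0(sprintf("%5d %s  ", i, pssm@sequence[i]),
           paste(sprintf("%3d", round(pssm@scores[i, ])), collapse = ""),
           paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
           sprintf("  %4.2f %8.2f", 0, 0)),
    character(1L))
  writeLines(c(hdr, rows, ""), path)
  invisible(path)
}

#' Write a BackboneChain as PDB ATOM records
#'
#' @param chain a \linkS4class{BackboneChain}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePdb <- function(chain, path) {
  stopifnot(is(chain, "BackboneChain"))
  fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  serial <- 0L
  out <- character(0)
  atoms <- list(c(" N", "coordsN", "N"), c(" CA", "coordsCA", "C"),
                c(" C", "coordsC", "C"))
  for (i in seq_len(nResidues(chain))) {
    for (a in atoms) {
      serial <- serial + 1L
      xyz <- slot(chain, a[[2L]])[i, ]
      out <- c(out, sprintf(fmt, serial, a[[1L]], chain@residueNames[i],
                            chain@chainId, chain@residueIds[i],
                            xyz[1L], xyz[2L], xyz[3L], 1, 0, a[[3L]]))
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read/write a tab-delimited structure-property table
#'
#' The file has a header row naming the 18 canonical columns (see
#' \code{propsFromAngles}) plus a leading residue index column.
#'
#' @param path file path.
#' @return data.frame with the 18 structure-property columns.
#' @export
readPropertyTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  validatePropertyTable(tab)
}

#' @rdname readPropertyTable
#' @param props data.frame with the 18 canonical columns.
#' @export
writePropertyTable <- function(props, path) {
  props <- validatePropertyTable(props)
  out <- cbind(residue = seq_len(nrow(props)), props)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a probability profile
#'
#' Long tab-delimited format with columns residue, kind, bin, prob; one
#' row per (residue, angle kind, bin).
#'
#' @param profile a \linkS4class{ProbabilityProfile}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "ProbabilityProfile"))
  blocks <- schemeBlocks(profile@scheme)
  n <- nResidues(profile)
  parts <- lapply(ANGLE_KINDS, function(k) {
    K <- profile@scheme@bins[[k]]
    data.frame(residue = rep(seq_len(n), each = K),
               kind = k, bin = rep(seq_len(K), n),
               prob = as.vector(t(profile@probs[, blocks[[k]], drop = FALSE])))
  })
  write.table(do.call(rbind, parts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("residue", "kind", "bin", "prob")
  if (!all(need %in% names(tab)))
    stop("profile file must have columns residue, kind, bin, prob",
         call. = FALSE)
  Kphi <- max(tab$bin[tab$kind == "phi"])
  scheme <- makeScheme(360 / Kphi)
  n <- max(tab$residue)
  probs <- matrix(0, n, scheme@total)
  blocks <- schemeBlocks(scheme)
  for (k in ANGLE_KINDS) {
    sub <- tab[tab$kind == k, ]
    probs[cbind(sub$residue, blocks[[k]][1L] - 1L + sub$bin)] <- sub$prob
  }
  new("ProbabilityProfile", probs = probs, scheme = scheme)
}

#' Serialize a background distribution
#'
#' Tab-delimited columns kind, bin, prob.
#'
#' @param background a \linkS4class{BackgroundDistribution}.
#' @param path output path.
#' @export
writeBackground <- function(background, path) {
  stopifnot(is(background, "BackgroundDistribution"))
  parts <- lapply(ANGLE_KINDS, function(k)
    data.frame(kind = k, bin = seq_along(background@freq[[k]]),
               prob = background@freq[[k]]))
  write.table(do.call(rbind, parts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeBackground
#' @export
readBackground <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  Kphi <- max(tab$bin[tab$kind == "phi"])
  scheme <- makeScheme(360 / Kphi)
  freq <- lapply(ANGLE_KINDS, function(k) {
    sub <- tab[tab$kind == k, ]
    sub$prob[order(sub$bin)]
  })
  names(freq) <- ANGLE_KINDS
  new("BackgroundDistribution", freq = freq, pseudocount = NA_real_,
      scheme = scheme)
}

#' Read a two-column residue label file
#'
#' Tab- or space-delimited rows of (residue index, 0/1 label), with 1
#' marking disordered residues.
#'
#' @param path file path.
#' @return integer 0/1 vector indexed by residue.
#' @export
readLabels <- function(path) {
  tab <- read.table(path, header = FALSE)
  labels <- integer(max(tab[[1L]]))
  labels[tab[[1L]]] <- as.integer(tab[[2L]])
  labels
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    return(setNames(as.character(x), names(x)))
  }
  ## minimal fallback
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- tapply(lines[!hdr], id[!hdr], paste, collapse = "")
  setNames(as.character(seqs), sub("^>\\s*", "", lines[hdr]))
}

#' Save or load a trained network model
#'
#' The model is persisted as a single binary archive that embeds its
#' configuration additionally as a JSON string, and round-trips exactly.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param path archive path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "NetworkModel"))
  cfg <- model@config
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE)
  obj <- list(weights = model@weights, biases = model@biases,
              inputDim = model@inputDim, width = model@scheme@width,
              config = cfgList, meta = model@meta,
              configJson = jsonlite::toJSON(cfgList, auto_unbox = TRUE))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(networkConfig, obj$config)
  new("NetworkModel", weights = obj$weights, biases = obj$biases,
      inputDim = obj$inputDim, scheme = makeScheme(obj$width),
      config = cfg, meta = obj$meta)
}

#' Write a disorder score track
#'
#' Tab-delimited columns: residue, raw entropy, normalized entropy,
#' window-averaged score.
#'
#' @param track a data.frame as returned by \code{disorderTrack}.
#' @param path output path.
#' @export
writeTrack <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
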