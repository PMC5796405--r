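## Backbone geometry: PDB parsing and the four backbone angles.
##
## phi_i  = dihedral(C_{i-1}, N_i,  CA_i,  C_i)     about the N-CA bond
## psi_i  = dihedral(N_i,     CA_i, C_i,   N_{i+1}) about the CA-C bond
## theta_i = planar angle CA_{i-1} - CA_i - CA_{i+1}
## tau_i  = dihedral(CA_{i-1}, CA_i, CA_{i+1}, CA_{i+2}) about CA_i-CA_{i+1}

## Map any angle in degrees to the half-open interval [-180, 180);
## +180 wraps to -180 so bin assignment is unambiguous.
wrapTo180 <- function(x) ((x + 180) %% 360) - 180

#' Dihedral angle of four points
#'
#' Torsion about the p2-p3 axis with the IUPAC sign convention (positive
#' for a clockwise rotation of p3-p4 relative to p2-p1 viewed from p2
#' toward p3), computed by projecting the outer bonds onto the plane
#' normal to the axis. The value lies in the half-open interval
#' [-180, 180); exactly 180 wraps to -180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees, or NA if the construction is degenerate
#'   (an outer bond collinear with the axis, or a zero-length bond).
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  nb1 <- sqrt(sum(b1^2))
  if (nb1 < 1e-10) return(NA_real_)
  b1 <- b1 / nb1
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  if (sum(v^2) < 1e-20 || sum(w^2) < 1e-20) return(NA_real_)
  x <- sum(v * w)
  y <- sum(crossProd3(b1, v) * w)
  wrapTo180(atan2(y, x) * 180 / pi)
}

crossProd3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Planar angle of three points
#'
#' The bond angle at p2, i.e. the angle between the arms p1-p2 and p3-p2,
#' in [0, 180] degrees.
#'
#' @param p1,p2,p3 numeric 3-vectors (Angstrom).
#' @return angle in degrees, or NA if either arm has zero length.
#' @export
planarAngle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-10 || nv < 1e-10) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Parse backbone coordinates from PDB text
#'
#' Reads the ATOM records of one chain (PDB v3.3 fixed-width columns) and
#' assembles the N/CA/C backbone. Only the first model of a multi-model
#' file is used; the first alternate location is kept; insertion-coded
#' residues are kept in file order. Residues missing any of N, CA or C are
#' dropped with a warning.
#'
#' @param pdb path to a PDB file, or a character scalar/vector of PDB text.
#' @param chain chain identifier; defaults to the first chain in the file.
#' @return a \linkS4class{BackboneChain}.
#' @export
parseBackbone <- function(pdb, chain = NULL) {
  lines <- readPdbLines(pdb)
  ## first model only
  mend <- grep("^ENDMDL", lines)
  if (length(mend)) lines <- lines[seq_len(mend[1L] - 1L)]
  isAtom <- startsWith(lines, "ATOM  ")
  if (!any(isAtom)) stop("no ATOM records found", call. = FALSE)
  atomIdx <- which(isAtom)
  al <- lines[atomIdx]
  bad <- which(nchar(al) < 54)
  if (length(bad))
    stop(sprintf("malformed ATOM record at line %d: '%s'",
                 atomIdx[bad[1L]], al[bad[1L]]), call. = FALSE)
  fld <- function(from, to) trimws(substring(al, from, to))
  elety <- fld(13, 16)
  alt <- fld(17, 17)
  chains <- substring(al, 22, 22)
  resno <- suppressWarnings(as.integer(fld(23, 26)))
  insert <- fld(27, 27)
  resna <- fld(18, 20)
  xyz <- suppressWarnings(cbind(as.numeric(fld(31, 38)),
                                as.numeric(fld(39, 46)),
                                as.numeric(fld(47, 54))))
  bad <- which(!stats::complete.cases(xyz) | is.na(resno))
  if (length(bad))
    stop(sprintf("malformed ATOM record at line %d: '%s'",
                 atomIdx[bad[1L]], al[bad[1L]]), call. = FALSE)
  if (is.null(chain)) chain <- chains[1L]
  keep <- chains == chain & elety %in% c("N", "CA", "C") & alt %in% c("", "A")
  if (!any(keep))
    stop(sprintf("no parsable backbone residues for chain '%s'", chain),
         call. = FALSE)
  elety <- elety[keep]; resno <- resno[keep]; insert <- insert[keep]
  resna <- resna[keep]; xyz <- xyz[keep, , drop = FALSE]
  key <- paste(resno, insert, sep = "|")
  ukey <- unique(key)
  ## order residues by residue number; insertion-coded residues keep
  ## file order among themselves (stable sort)
  ukey <- ukey[order(as.integer(sub("\\|.*$", "", ukey)))]
  n <- length(ukey)
  cn <- cca <- cc <- matrix(NA_real_, n, 3L)
  rnam <- character(n); rid <- integer(n)
  for (i in seq_len(n)) {
    sel <- which(key == ukey[i])
    rid[i] <- resno[sel[1L]]
    rnam[i] <- resna[sel[1L]]
    for (a in sel) {
      ## first altloc: keep the first occurrence of each atom name
      tgt <- switch(elety[a], "N" = "cn", "CA" = "cca", "C" = "cc")
      m <- get(tgt)
      if (is.na(m[i, 1L])) {
        m[i, ] <- xyz[a, ]
        assign(tgt, m)
      }
    }
  }
  complete <- stats::complete.cases(cn) & stats::complete.cases(cca) &
    stats::complete.cases(cc)
  if (!all(complete))
    warning(sprintf("dropped %d residue(s) missing backbone atoms: %s",
                    sum(!complete), paste(rid[!complete], collapse = ", ")),
            call. = FALSE)
  if (!any(complete))
    stop(sprintf("no parsable backbone residues for chain '%s'", chain),
         call. = FALSE)
  new("BackboneChain", chainId = chain, residueIds = rid[complete],
      residueNames = rnam[complete],
      coordsN = cn[complete, , drop = FALSE],
      coordsCA = cca[complete, , drop = FALSE],
      coordsC = cc[complete, , drop = FALSE])
}

readPdbLines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb))
    return(readLines(pdb, warn = FALSE))
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

#' Compute the four backbone angles of a chain
#'
#' Produces per-residue phi, psi, theta and tau with defined-ness masks.
#' Termini follow the angle definitions (phi undefined at the first
#' residue, psi at the last, theta at both termini, tau at the first and
#' the last two). A chain break (residue-number gap or consecutive CA-CA
#' distance above \code{maxCaDist}) invalidates every angle spanning it.
#'
#' @param chain a \linkS4class{BackboneChain}.
#' @param maxCaDist CA-CA distance (Angstrom) above which consecutive
#'   residues are treated as disconnected; default 4.5.
#' @return an \linkS4class{AngleTable}.
#' @export
computeAngles <- function(chain, maxCaDist = 4.5) {
  stopifnot(is(chain, "BackboneChain"))
  n <- nResidues(chain)
  ang <- matrix(NA_real_, n, 4L, dimnames = list(NULL, ANGLE_KINDS))
  N <- chain@coordsN; CA <- chain@coordsCA; C <- chain@coordsC
  ## linked[i]: residues i and i+1 form an unbroken peptide link
  linked <- logical(max(n - 1L, 0L))
  if (n > 1L) {
    d <- sqrt(rowSums((CA[-1L, , drop = FALSE] - CA[-n, , drop = FALSE])^2))
    linked <- diff(chain@residueIds) == 1L & d <= maxCaDist
  }
  lnk <- function(i) i >= 1L && i <= length(linked) && linked[i]
  for (i in seq_len(n)) {
    if (lnk(i - 1L))
      ang[i, "phi"] <- dihedralAngle(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    if (lnk(i))
      ang[i, "psi"] <- dihedralAngle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
    if (lnk(i - 1L) && lnk(i))
      ang[i, "theta"] <- planarAngle(CA[i - 1L, ], CA[i, ], CA[i + 1L, ])
    if (lnk(i - 1L) && lnk(i) && lnk(i + 1L))
      ang[i, "tau"] <- dihedralAngle(CA[i - 1L, ], CA[i, ], CA[i + 1L, ],
                                     CA[i + 2L, ])
  }
  new("AngleTable", angles = ang, defined = !is.na(ang))
}
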