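# OpenBabel glue + fingerprint computation.
#
# MACCS keys come from OpenBabel's SMARTS dictionary (via ChemmineOB); the
# on-bit column numbers equal the conventional 1-based MACCS key numbers
# (1..166). ECFP is computed in-package: a Morgan-style iterative atom-
# environment hash folded modulo nbits, so that every bit can be traced back
# to the atom environments (fragments) that activated it -- which the
# bit-degeneracy analysis requires.

# Parse a list of SMILES into OpenBabel molecule refs, one try() per entry so
# a malformed line never aborts the batch. Failures come back as NULL.
.obMols <- function(smiles) {
  lapply(smiles, function(s) {
    if (!nzchar(trimws(s))) return(NULL)
    m <- try(suppressWarnings(
      ChemmineOB::forEachMol("SMILES", s, identity)), silent = TRUE)
    if (inherits(m, "try-error") || length(m) == 0L) return(NULL)
    if (ChemmineOB:::OBMol_NumAtoms(m[[1L]]) == 0L) return(NULL)
    m[[1L]]
  })
}

.parseFailure <- function(smiles, context = "SMILES") {
  stop(sprintf("unparseable %s: '%s'", context, smiles), call. = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Round-trips each SMILES through OpenBabel's canonical writer. Used to
#' deduplicate molecules and reaction components.
#'
#' @param smiles character vector of SMILES.
#' @param onError `"stop"` (default) or `"na"`: what to do with strings that
#'   do not parse.
#' @return character vector of canonical SMILES (or `NA` where requested).
#' @examples
#' canonicalSmiles(c("OCC", "C1=CC=CC=C1"))
#' @export
canonicalSmiles <- function(smiles, onError = c("stop", "na")) {
  onError <- match.arg(onError)
  vapply(smiles, function(s) {
    out <- try(suppressWarnings(
      ChemmineOB::convertFormat("SMILES", "CAN", s)), silent = TRUE)
    if (inherits(out, "try-error") || !nzchar(trimws(out))) {
      if (onError == "stop") .parseFailure(s)
      return(NA_character_)
    }
    strsplit(trimws(out), "[\t ]")[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Compute MACCS key sets
#'
#' Returns, for each molecule, the on-bit MACCS key indices (1..166) under
#' the toolkit's SMARTS definitions. Deterministic for a given toolkit
#' version.
#'
#' @param smiles character vector of SMILES strings.
#' @return a [KeySetList] with backend `"MACCS"`.
#' @examples
#' computeMACCS(c("CCO", "c1ccccc1"))
#' @export
computeMACCS <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  mols <- .obMols(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) .parseFailure(smiles[which(bad)[1L]])
  fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (is.vector(fp)) fp <- matrix(fp, nrow = 1L)
  sets <- lapply(seq_len(nrow(fp)), function(i) {
    k <- which(fp[i, ] != 0)
    as.integer(k[k >= 1L & k <= 166L])
  })
  new("KeySetList", sets = sets, backend = "MACCS", ids = as.character(smiles))
}

# ---------------------------------------------------------------------------
# Molecular graph extraction (V2000 text from OpenBabel). ChemmineR's SDFset
# reader rejects single-heavy-atom molecules such as methane, so the counts
# line, atom symbols, bond block and M CHG lines are read directly.
.molGraph <- function(smiles) {
  txt <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMILES", "SDF", smiles)), silent = TRUE)
  if (inherits(txt, "try-error") || !nzchar(trimws(txt)))
    .parseFailure(smiles)
  ln <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  counts <- ln[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L) .parseFailure(smiles)
  atoms <- trimws(substr(ln[5L:(4L + na)], 32L, 34L))
  bonds <- if (nb > 0L) {
    bl <- ln[(5L + na):(4L + na + nb)]
    cbind(a1 = as.integer(substr(bl, 1L, 3L)),
          a2 = as.integer(substr(bl, 4L, 6L)),
          order = as.integer(substr(bl, 7L, 9L)))
  } else matrix(integer(), 0L, 3L, dimnames = list(NULL, c("a1", "a2", "order")))
  charges <- integer(na)
  for (cl in grep("^M  CHG", ln, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "[ ]+")[[1L]])
    n <- f[1L]
    for (j in seq_len(n)) charges[f[2L * j]] <- f[2L * j + 1L]
  }
  list(atoms = atoms, bonds = bonds, charges = charges, smiles = smiles)
}

# Adjacency: list per atom of (neighbor, bond order) pairs.
.adjacency <- function(graph) {
  adj <- rep(list(matrix(integer(), 0L, 2L)), length(graph$atoms))
  b <- graph$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b[i, 1L]]] <- rbind(adj[[b[i, 1L]]], c(b[i, 2L], b[i, 3L]))
    adj[[b[i, 2L]]] <- rbind(adj[[b[i, 2L]]], c(b[i, 1L], b[i, 3L]))
  }
  adj
}

# Morgan-style environment enumeration. Returns one row per distinct atom
# environment of radius 0..radius: the center atom, the radius, the
# environment hash (32-bit), and the member atom indices (for fragment
# extraction). Environments with identical hashes within one molecule are
# collapsed (they are the same substructure).
.morganEnvironments <- function(graph, radius) {
  na <- length(graph$atoms)
  adj <- .adjacency(graph)
  inv <- fnvHash(paste(graph$atoms, graph$charges,
                       vapply(adj, nrow, integer(1)),
                       vapply(adj, function(a) sum(a[, 2L]), integer(1)),
                       sep = "|"))
  members <- lapply(seq_len(na), function(i) i)
  out <- list(data.frame(center = seq_len(na), radius = 0L, hash = inv))
  outMembers <- members
  for (r in seq_len(radius)) {
    nxt <- character(na)
    newMembers <- vector("list", na)
    for (i in seq_len(na)) {
      nb <- adj[[i]]
      if (nrow(nb)) {
        o <- order(nb[, 2L], inv[nb[, 1L]])
        nxt[i] <- paste(r, inv[i],
                        paste(nb[o, 2L], inv[nb[o, 1L]], collapse = ","),
                        sep = ";")
        newMembers[[i]] <- sort(unique(c(members[[i]],
                                         unlist(members[nb[, 1L]]))))
      } else {
        nxt[i] <- paste(r, inv[i], sep = ";")
        newMembers[[i]] <- members[[i]]
      }
    }
    inv <- fnvHash(nxt)
    members <- newMembers
    out[[r + 1L]] <- data.frame(center = seq_len(na), radius = r, hash = inv)
    outMembers <- c(outMembers, newMembers)
  }
  env <- do.call(rbind, out)
  env$members <- outMembers
  env[!duplicated(env$hash), , drop = FALSE]
}

#' Compute folded circular (ECFP/Morgan) fingerprints
#'
#' Atom environments of radius 0 up to `radius` are enumerated with the
#' Morgan iteration (initial invariants: element, formal charge, heavy
#' degree, bond-order sum), hashed, and folded modulo `nbits`. The same
#' hashing underlies [analyzeBitDegeneracy()], so every on bit can be traced
#' to the fragments that set it.
#'
#' @param smiles character vector of SMILES.
#' @param radius environment radius (1 or 2 typical).
#' @param nbits folded length (1024 or 2048 typical).
#' @return a [KeySetList] with backend `"ECFP"`, 0-based bit indices.
#' @examples
#' computeECFP("CCO", radius = 1, nbits = 1024)
#' @export
computeECFP <- function(smiles, radius = 2L, nbits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) > 0L,
            radius >= 0L, nbits >= 2L)
  sets <- lapply(smiles, function(s) {
    env <- .morganEnvironments(.molGraph(s), radius)
    sort(unique(as.integer(env$hash %% nbits)))
  })
  new("KeySetList", sets = sets, backend = "ECFP",
      radius = as.integer(radius), nbits = as.integer(nbits),
      ids = as.character(smiles))
}

# Canonical SMILES of an induced subgraph (atom environment fragment).
.fragmentSmiles <- function(graph, atomIdx) {
  keep <- sort(atomIdx)
  remap <- match(seq_along(graph$atoms), keep)
  b <- graph$bonds
  inb <- b[, 1L] %in% keep & b[, 2L] %in% keep
  b <- b[inb, , drop = FALSE]
  hdr <- c("", " fragretro", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(keep), nrow(b)))
  atomLines <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       graph$atoms[keep])
  bondLines <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0",
                                    remap[b[, 1L]], remap[b[, 2L]], b[, 3L])
               else character()
  chg <- which(graph$charges[keep] != 0L)
  chgLines <- if (length(chg))
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, graph$charges[keep][chg]),
                  collapse = ""))
  else character()
  sdf <- paste(c(hdr, atomLines, bondLines, chgLines, "M  END", "$$$$"),
               collapse = "\n")
  out <- try(suppressWarnings(
    ChemmineOB::convertFormat("SDF", "CAN", sdf)), silent = TRUE)
  if (inherits(out, "try-error") || !nzchar(trimws(out)))
    return(NA_character_)
  strsplit(trimws(out), "[\t ]")[[1L]][1L]
}

#' Bit degeneracy of folded circular fingerprints
#'
#' For every bit set anywhere in the corpus, collects the distinct atom-
#' environment fragments (canonical sub-SMILES) that activated it. A high
#' fragments-per-bit count means one token stands for many substructures,
#' which blurs what a sequence model can learn from the bit pattern.
#'
#' @param smiles character vector (the corpus).
#' @param radius environment radius.
#' @param nbits folded length.
#' @return list with `bits` (named list: bit index -> character vector of
#'   fragment SMILES), `meanFragmentsPerBit`, `nBitsOn`.
#' @export
analyzeBitDegeneracy <- function(smiles, radius = 2L, nbits = 1024L) {
  stopifnot(length(smiles) > 0L)
  acc <- new.env(parent = emptyenv())
  for (s in smiles) {
    g <- .molGraph(s)
    env <- .morganEnvironments(g, radius)
    frag <- vapply(env$members, function(m) .fragmentSmiles(g, m),
                   character(1))
    bit <- as.integer(env$hash %% nbits)
    ok <- !is.na(frag)
    for (i in which(ok)) {
      kb <- as.character(bit[i])
      acc[[kb]] <- union(acc[[kb]], frag[i])
    }
  }
  bits <- as.list(acc)
  bits <- bits[order(as.integer(names(bits)))]
  counts <- vapply(bits, length, integer(1))
  list(bits = bits,
       meanFragmentsPerBit = if (length(counts)) mean(counts) else NA_real_,
       nBitsOn = length(bits))
}
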