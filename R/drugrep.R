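#' Parse a drug structure from SMILES or InChI
#'
#' SMILES is preferred; InChI is converted (OpenBabel) as a fallback. The
#' structure is canonicalized before graph extraction. The returned molecule
#' holds the atom list (element, charge, 2D coordinates), bond list (atom
#' indices, order) and the canonical SMILES.
#'
#' @param smiles SMILES string (may be empty).
#' @param inchi InChI string (may be empty).
#' @param drugId identifier used in error messages.
#' @return list of class \code{MoleculeStruct}: \code{drug_id},
#'   \code{canonical_smiles}, \code{atoms} (data.frame element, charge, x,
#'   y), \code{bonds} (data.frame from, to, order), \code{sdf} (ChemmineR
#'   SDF object).
#' @export
parseStructure <- function(smiles = "", inchi = "", drugId = "drug") {
  smiles <- if (is.na(smiles)) "" else smiles
  inchi <- if (is.na(inchi)) "" else inchi
  if (!nzchar(smiles) && !nzchar(inchi)) {
    stop("drug ", drugId, ": both SMILES and InChI are empty")
  }
  if (!nzchar(smiles)) {
    smiles <- tryCatch(
      sub("\\s+$", "", ChemmineOB::convertFormat("INCHI", "SMI", inchi)),
      error = function(e) "")
    if (!nzchar(smiles)) {
      stop("drug ", drugId, ": InChI could not be parsed")
    }
  }
  can <- tryCatch(
    sub("\\s+$", "", ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  if (!nzchar(can)) stop("drug ", drugId, ": SMILES could not be parsed")
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(can)),
                  error = function(e) NULL)
  if (is.null(sdf)) stop("drug ", drugId, ": structure conversion failed")
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  atoms <- data.frame(
    element = sub("_.*$", "", rownames(ab)),
    charge = if ("charge" %in% colnames(ab)) ab[, "charge"] else 0,
    x = ab[, 1], y = ab[, 2], row.names = NULL)
  bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]), row.names = NULL)
  } else data.frame(from = integer(), to = integer(), order = integer())
  structure(list(drug_id = drugId, canonical_smiles = can,
                 atoms = atoms, bonds = bonds, sdf = sdf),
            class = "MoleculeStruct")
}

#' @export
print.MoleculeStruct <- function(x, ...) {
  cat("MoleculeStruct", x$drug_id, ":", x$canonical_smiles, "-",
      nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

# antialiased segment drawing into a matrix (distance-to-segment shading)
drawSegment <- function(img, x0, y0, x1, y1, radius = 1.2, value = 1) {
  n <- nrow(img)
  xmin <- max(1, floor(min(x0, x1) - radius - 1))
  xmax <- min(n, ceiling(max(x0, x1) + radius + 1))
  ymin <- max(1, floor(min(y0, y1) - radius - 1))
  ymax <- min(n, ceiling(max(y0, y1) + radius + 1))
  if (xmin > xmax || ymin > ymax) return(img)
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / L2))
  d <- sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
  inten <- pmax(0, 1 - d / radius) * value
  idx <- cbind(px, py)
  img[idx] <- pmax(img[idx], inten)
  img
}

#' Render a standardized 2D depiction of a molecule
#'
#' Draws the OpenBabel 2D layout into an in-memory grayscale raster: bonds
#' as antialiased lines (double/triple bonds drawn heavier), atoms as small
#' discs with heteroatoms brighter than carbon. Values lie in [0, 1]; the
#' output is deterministic for a fixed canonical structure.
#'
#' @param mol a \code{MoleculeStruct}.
#' @param size raster side length (default 224).
#' @return size x size numeric matrix in [0, 1].
#' @export
renderDepiction <- function(mol, size = 224) {
  at <- mol$atoms
  img <- matrix(0, size, size)
  pad <- size * 0.12
  if (nrow(at) == 1) {
    cx <- size / 2
    return(drawSegment(img, cx, cx, cx, cx, radius = size * 0.02, value = 1))
  }
  rngx <- range(at$x); rngy <- range(at$y)
  span <- max(diff(rngx), diff(rngy), 1e-6)
  sx <- pad + (at$x - rngx[1]) / span * (size - 2 * pad)
  sy <- pad + (at$y - rngy[1]) / span * (size - 2 * pad)
  # center the shorter axis
  sx <- sx + (size - 2 * pad - diff(rngx) / span * (size - 2 * pad)) / 2
  sy <- sy + (size - 2 * pad - diff(rngy) / span * (size - 2 * pad)) / 2
  bd <- mol$bonds
  for (i in seq_len(nrow(bd))) {
    w <- 1 + 0.5 * (min(bd$order[i], 3) - 1)
    img <- drawSegment(img, sx[bd$from[i]], sy[bd$from[i]],
                       sx[bd$to[i]], sy[bd$to[i]],
                       radius = 1.2 * w, value = 0.7)
  }
  for (i in seq_len(nrow(at))) {
    v <- if (at$element[i] == "C") 0.75 else 1
    img <- drawSegment(img, sx[i], sy[i], sx[i], sy[i],
                       radius = 2.5, value = v)
  }
  pmin(img, 1)
}

bondInRing <- function(mol) {
  if (nrow(mol$bonds) == 0) return(logical(0))
  g <- igraph::graph_from_data_frame(mol$bonds[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(
                                       name = seq_len(nrow(mol$atoms))))
  vapply(seq_len(nrow(mol$bonds)), function(i) {
    g2 <- igraph::delete_edges(g, i)
    is.finite(igraph::distances(
      g2, v = as.character(mol$bonds$from[i]),
      to = as.character(mol$bonds$to[i]))[1, 1])
  }, TRUE)
}

#' Numeric drug descriptors with cell-line context
#'
#' Fixed-length vector of structural properties (heavy atoms, bonds, rings,
#' aromatic rings, molecular weight, topological polar surface area, logP,
#' H-bond donors/acceptors, rotatable bonds), a pass-through cytotoxicity
#' index annotation, and two context terms: \code{target_match} (fraction of
#' the drug's annotated targets that are altered, i.e. mutated, in the cell
#' line; 0 when the target list is empty) and \code{target_expression}
#' (mean expression of the annotated targets in the cell line; 0 when
#' unavailable).
#'
#' @param mol a \code{MoleculeStruct}.
#' @param targets character vector of drug-annotated target genes.
#' @param alteredGenes genes altered in the cell line context.
#' @param targetExpression named expression vector for the cell line (or
#'   NULL).
#' @param cytotoxicityIndex optional annotation passed through (default 0).
#' @return named numeric vector of length 13 (constant across drugs).
#' @export
drugDescriptors <- function(mol, targets = character(),
                            alteredGenes = character(),
                            targetExpression = NULL,
                            cytotoxicityIndex = 0) {
  rc <- tryCatch(ChemmineR::rings(mol$sdf[[1]], type = "count", arom = TRUE),
                 error = function(e) c(RINGS = 0, AROMATIC = 0))
  pr <- tryCatch(ChemmineR::propOB(mol$sdf),
                 error = function(e) NULL)
  getp <- function(nm) if (!is.null(pr) && nm %in% colnames(pr))
    as.numeric(pr[1, nm]) else 0
  inRing <- bondInRing(mol)
  deg <- tabulate(c(mol$bonds$from, mol$bonds$to), nbins = nrow(mol$atoms))
  rot <- sum(mol$bonds$order == 1 & !inRing &
             deg[mol$bonds$from] > 1 & deg[mol$bonds$to] > 1)
  tm <- if (length(targets) == 0) 0 else
    length(intersect(targets, alteredGenes)) / length(targets)
  te <- if (is.null(targetExpression) || length(targets) == 0) 0 else
    mean(targetExpression[intersect(targets, names(targetExpression))],
         na.rm = TRUE)
  if (!is.finite(te)) te <- 0
  c(heavy_atoms = nrow(mol$atoms), n_bonds = nrow(mol$bonds),
    n_rings = unname(rc["RINGS"]), n_aromatic_rings = unname(rc["AROMATIC"]),
    mw = getp("MW"), tpsa = getp("TPSA"), logp = getp("logP"),
    hbd = getp("HBD"), hba = getp("HBA1"), rotatable = rot,
    cytotoxicity_index = cytotoxicityIndex,
    target_match = tm, target_expression = te)
}
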