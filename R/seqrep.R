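#' @importFrom Biostrings DNAStringSet DNAString pairwiseAlignment
NULL

#' Sliding windows over a gene sequence
#'
#' Enumerates windows of length \code{Lw} at 1-based start positions
#' \code{p = 1 + m*Sw}, \code{m = 0,...,floor((L-Lw)/Sw)}. A sequence shorter
#' than \code{Lw} yields an empty window set with a warning.
#'
#' @param sequence character scalar over \{A,C,G,T\}.
#' @param Lw window length (>= 1).
#' @param Sw step size (>= 1).
#' @param geneId optional identifier carried through.
#' @return list with \code{gene_id}, \code{Lw}, \code{Sw} and \code{windows},
#'   a data.frame of (start, subsequence).
#' @export
makeWindows <- function(sequence, Lw, Sw, geneId = NA_character_) {
  stopifnot(Lw >= 1, Sw >= 1)
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  if (L < Lw) {
    warning("sequence shorter than window length; empty window set")
    return(list(gene_id = geneId, Lw = Lw, Sw = Sw,
                windows = data.frame(start = integer(),
                                     subsequence = character())))
  }
  m <- 0:((L - Lw) %/% Sw)
  starts <- 1L + m * Sw
  subs <- substring(sequence, starts, starts + Lw - 1L)
  list(gene_id = geneId, Lw = Lw, Sw = Sw,
       windows = data.frame(start = starts, subsequence = subs,
                            stringsAsFactors = FALSE))
}

revString <- function(s) {
  vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), "")
}

# longest substring of length >= kMin occurring >= 2 times in s (brute,
# windows are short); returns NULL or list(sub, start)
longestRepeat <- function(s, kMin) {
  n <- nchar(s)
  if (n %/% 2 < kMin) return(NULL)
  for (len in seq(n %/% 2, kMin, by = -1)) {
    subs <- substring(s, 1:(n - len + 1), len:(n))
    dup <- subs[duplicated(subs)]
    if (length(dup) > 0) {
      sub <- dup[1]
      return(list(sub = sub, start = regexpr(sub, s, fixed = TRUE)[1],
                  len = len))
    }
  }
  NULL
}

# longest substring equal to its own reverse, length >= kMin
longestPalindrome <- function(s, kMin) {
  n <- nchar(s)
  if (n < kMin) return(NULL)
  for (len in seq(n, kMin, by = -1)) {
    starts <- 1:(n - len + 1)
    subs <- substring(s, starts, starts + len - 1)
    hit <- which(subs == revString(subs))
    if (length(hit) > 0) {
      return(list(sub = subs[hit[1]], start = starts[hit[1]], len = len))
    }
  }
  NULL
}

#' Detect structural events in a window relative to a reference window
#'
#' Five event classes: \emph{duplication} (maximal substring of length >=
#' \code{kMin} occurring at least twice in the window); \emph{mirror}
#' (maximal substring equal to its own reverse); \emph{inversion} (a
#' reference substring whose reverse, length >= \code{kMin}, occurs in the
#' window while the forward form does not); \emph{insertion}/\emph{deletion}
#' (gap runs in the global edit alignment of window vs reference window).
#'
#' @param window character scalar (the observed window).
#' @param referenceWindow character scalar (the matched reference window).
#' @param kMin minimum motif length (default 4).
#' @return data.frame (segment, event, start, length); zero rows if no event.
#' @export
detectEvents <- function(window, referenceWindow, kMin = 4) {
  window <- as.character(window); referenceWindow <- as.character(referenceWindow)
  out <- data.frame(segment = character(), event = character(),
                    start = integer(), length = integer(),
                    stringsAsFactors = FALSE)
  addRow <- function(seg, ev, st, len) {
    rbind(out, data.frame(segment = seg, event = ev, start = st, length = len,
                          stringsAsFactors = FALSE))
  }
  rep_ <- longestRepeat(window, kMin)
  if (!is.null(rep_)) out <- addRow(rep_$sub, "duplication", rep_$start, rep_$len)
  pal <- longestPalindrome(window, kMin)
  if (!is.null(pal)) out <- addRow(pal$sub, "mirror", pal$start, pal$len)

  # inversion: reversed reference k-mers present in window, forward absent
  nr <- nchar(referenceWindow)
  if (nr >= kMin && nchar(window) >= kMin && window != referenceWindow) {
    found <- FALSE
    for (len in seq(min(nr, nchar(window)), kMin, by = -1)) {
      if (found) break
      starts <- 1:(nr - len + 1)
      subs <- substring(referenceWindow, starts, starts + len - 1)
      rsubs <- revString(subs)
      for (i in seq_along(subs)) {
        if (rsubs[i] != subs[i] &&
            grepl(rsubs[i], window, fixed = TRUE) &&
            !grepl(subs[i], window, fixed = TRUE)) {
          pos <- regexpr(rsubs[i], window, fixed = TRUE)[1]
          out <- addRow(rsubs[i], "inversion", pos, len)
          found <- TRUE
          break
        }
      }
    }
  }

  # insertion / deletion via global edit alignment
  if (window != referenceWindow && nchar(window) > 0 && nr > 0) {
    aln <- Biostrings::pairwiseAlignment(window, referenceWindow,
                                         type = "global",
                                         gapOpening = 4, gapExtension = 1)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    gapRuns <- function(isGap) {
      r <- rle(isGap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      data.frame(start = starts[r$values], len = r$lengths[r$values])
    }
    ins <- gapRuns(sbj == "-")  # in window, absent from reference
    if (nrow(ins) > 0) {
      for (i in seq_len(nrow(ins))) {
        seg <- paste(pat[ins$start[i]:(ins$start[i] + ins$len[i] - 1)],
                     collapse = "")
        wpos <- sum(pat[seq_len(ins$start[i])] != "-")  # position in window
        out <- addRow(seg, "insertion", wpos - ins$len[i] + 1L, ins$len[i])
      }
    }
    del <- gapRuns(pat == "-")  # in reference, absent from window
    if (nrow(del) > 0) {
      for (i in seq_len(nrow(del))) {
        seg <- paste(sbj[del$start[i]:(del$start[i] + del$len[i] - 1)],
                     collapse = "")
        wpos <- sum(pat[seq_len(del$start[i])] != "-")
        out <- addRow(seg, "deletion", max(wpos, 1L), del$len[i])
      }
    }
  }
  out
}

#' Detect events across a whole gene sequence
#'
#' Windows the variant sequence, pairs windows positionally with the
#' reference, and pools per-window detections; duplicate detections of the
#' same (event, segment) from overlapping windows are collapsed.
#'
#' @param variant,reference character scalars (full gene sequences).
#' @param Lw,Sw windowing parameters.
#' @param kMin minimum motif length.
#' @return data.frame (segment, event, start, length) with window-offset
#'   starts mapped to gene coordinates.
#' @export
detectGeneEvents <- function(variant, reference, Lw = 40, Sw = 20, kMin = 4) {
  ws <- suppressWarnings(makeWindows(variant, Lw, Sw))
  out <- NULL
  # indels shift downstream coordinates; align each variant window against a
  # reference slice re-centred by the running offset
  offset <- 0L
  refLen <- nchar(reference)
  for (i in seq_len(nrow(ws$windows))) {
    st <- ws$windows$start[i]
    rs <- max(1L, st - offset)
    refWin <- substring(reference, rs, min(refLen, rs + Lw - 1L))
    ev <- detectEvents(ws$windows$subsequence[i], refWin, kMin)
    if (nrow(ev) > 0) {
      ev$start <- ev$start + st - 1L
      out <- rbind(out, ev)
      sh <- ev[ev$event %in% c("insertion", "deletion"), , drop = FALSE]
      if (nrow(sh) > 0) {
        offset <- offset + sum(ifelse(sh$event == "insertion", sh$length,
                                      -sh$length))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(segment = character(), event = character(),
                      start = integer(), length = integer()))
  }
  out[!duplicated(out[, c("segment", "event")]), , drop = FALSE]
}

#' Numeric descriptor of a detected segment
#'
#' Fixed 12-value vector: length, GC fraction, base composition (A,C,G,T),
#' one-hot event label (insertion, deletion, inversion, mirror, duplication),
#' and the Shannon entropy (bits) of the 2-mer distribution.
#'
#' @param segment character scalar.
#' @param event one of the five event labels.
#' @return named numeric vector of length 12.
#' @export
segmentDescriptor <- function(segment, event) {
  events <- c("insertion", "deletion", "inversion", "mirror", "duplication")
  event <- match.arg(event, events)
  stopifnot(nchar(segment) > 0)
  chars <- strsplit(toupper(segment), "")[[1]]
  n <- length(chars)
  comp <- vapply(c("A", "C", "G", "T"), function(b) mean(chars == b), 0)
  gc <- comp["C"] + comp["G"]
  if (n >= 2) {
    kmers <- paste0(chars[-n], chars[-1])
    p <- table(kmers) / length(kmers)
    ent <- -sum(p * log2(p))
  } else ent <- 0
  onehot <- as.numeric(events == event)
  v <- c(n, gc, comp, onehot, ent)
  names(v) <- c("length", "gc", "A", "C", "G", "T", events, "entropy2")
  v
}

#' Descriptor matrix for a segment set
#'
#' @param segments data.frame with columns \code{segment}, \code{event}.
#' @return matrix (segments x 12 descriptor values).
#' @export
segmentDescriptors <- function(segments) {
  t(mapply(segmentDescriptor, segments$segment, segments$event))
}

#' Neighbor-joining segment tree
#'
#' Agglomerates segments by classical neighbor joining on the Euclidean
#' descriptor dissimilarity (or a supplied distance matrix), using the
#' standard Q-criterion. Row sums of the distance matrix are maintained
#' incrementally across merges (the caching acceleration); merge semantics
#' and branch lengths are classical NJ, with ties broken by the lowest
#' (i, j) index pair and negative branch lengths clamped to zero. The
#' result is an unrooted \code{"phylo"} tree (root trifurcation for >= 3
#' leaves).
#'
#' @param x descriptor matrix (rows = segments) or a square distance matrix /
#'   \code{dist} object.
#' @param labels optional leaf labels.
#' @return an \code{ape} \code{"phylo"} object with branch lengths.
#' @export
mnjaBuildTree <- function(x, labels = NULL) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else {
    x <- as.matrix(x)
    if (nrow(x) == ncol(x) && isTRUE(all.equal(unname(x), unname(t(x)))) &&
        all(diag(x) == 0)) {
      D <- x
    } else {
      D <- as.matrix(stats::dist(x))
    }
  }
  n <- nrow(D)
  if (n < 2) stop("need at least 2 segments to build a tree")
  if (is.null(labels)) {
    labels <- rownames(D)
    if (is.null(labels)) labels <- paste0("seg", seq_len(n))
  }
  dimnames(D) <- NULL

  # node bookkeeping: tips 1..n, internals n+1 ...
  active <- seq_len(n)          # node id of each active cluster
  idx <- seq_len(n)             # row index into D of each active cluster
  edges <- matrix(0L, 0, 2)
  elen <- numeric(0)
  nextNode <- n + 1L
  rowSums_ <- rowSums(D)        # cached; updated incrementally per merge

  while (length(active) > 3) {
    m <- length(active)
    Q <- (m - 2) * D - outer(rowSums_, rowSums_, "+")
    diag(Q) <- Inf
    # lowest (i,j) tie break: which.min scans column-major; enforce i<j order
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    }
    dij <- D[bi, bj]
    li <- dij / 2 + (rowSums_[bi] - rowSums_[bj]) / (2 * (m - 2))
    lj <- dij - li
    li <- max(li, 0); lj <- max(lj, 0)
    edges <- rbind(edges, c(nextNode, active[bi]), c(nextNode, active[bj]))
    elen <- c(elen, li, lj)
    newd <- (D[bi, ] + D[bj, ] - dij) / 2
    newd <- newd[-c(bi, bj)]
    # incremental row-sum cache: r_k <- r_k - d_ik - d_jk + d_uk
    dik <- D[bi, -c(bi, bj)]; djk <- D[bj, -c(bi, bj)]
    rowSums_ <- c(rowSums_[-c(bi, bj)] - dik - djk + newd, sum(newd))
    D <- D[-c(bi, bj), -c(bi, bj), drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    active <- c(active[-c(bi, bj)], nextNode)
    nextNode <- nextNode + 1L
  }

  if (length(active) == 3) {
    d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
    l1 <- max((d12 + d13 - d23) / 2, 0)
    l2 <- max((d12 + d23 - d13) / 2, 0)
    l3 <- max((d13 + d23 - d12) / 2, 0)
    edges <- rbind(edges, c(nextNode, active[1]), c(nextNode, active[2]),
                   c(nextNode, active[3]))
    elen <- c(elen, l1, l2, l3)
    root <- nextNode; nextNode <- nextNode + 1L
  } else {
    edges <- rbind(edges, c(nextNode, active[1]), c(nextNode, active[2]))
    elen <- c(elen, D[1, 2] / 2, D[1, 2] / 2)
    root <- nextNode; nextNode <- nextNode + 1L
  }

  nInternal <- nextNode - n - 1L
  # renumber internals so the root is n+1 (ape convention)
  remap <- integer(nextNode - 1L)
  remap[seq_len(n)] <- seq_len(n)
  internals <- (n + 1L):(nextNode - 1L)
  ord <- c(root, setdiff(internals, root))
  remap[ord] <- n + seq_along(ord)
  edges2 <- matrix(remap[edges], ncol = 2)
  tr <- list(edge = edges2, edge.length = elen, tip.label = labels,
             Nnode = nInternal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Patristic-distance map of a segment tree
#'
#' Leaves are ordered by a deterministic depth-first traversal; the map cell
#' (i, j) is the path-length (patristic) distance between leaves i and j,
#' min-max normalized to [0, 1] and zero-padded to \code{size} x \code{size}.
#'
#' @param tree a \code{"phylo"} tree.
#' @param size output side length (default 224).
#' @return a \code{size} x \code{size} numeric matrix, symmetric in its
#'   leading block with zero diagonal.
#' @export
treeToMap <- function(tree, size = 224) {
  nt <- length(tree$tip.label)
  if (nt > size) {
    stop("tree has more leaves (", nt, ") than map size ", size,
         "; raise size or merge segments")
  }
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  # deterministic DFS leaf order from the root (node nt+1)
  dfs <- igraph::dfs(g, root = as.character(nt + 1))
  ord <- as.integer(igraph::V(g)$name[dfs$order])
  leaves <- ord[ord <= nt]
  dm <- igraph::distances(g, v = as.character(leaves),
                          to = as.character(leaves))
  dm <- unname(dm)
  if (max(dm) > 0) dm <- (dm - min(dm)) / (max(dm) - min(dm))
  out <- matrix(0, size, size)
  out[seq_len(nt), seq_len(nt)] <- dm
  attr(out, "leafOrder") <- tree$tip.label[leaves]
  out
}
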