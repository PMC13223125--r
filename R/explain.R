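#' @importFrom stats phyper p.adjust
NULL

shapleyKernelWeight <- function(k, s) {
  (k - 1) / (choose(k, s) * s * (k - s))
}

evalCoalitions <- function(f, Z, x, background, chunk = 4000L) {
  # v(S) for each coalition row of Z: average model output with coalition
  # features from x and the rest from each background row; chunked so the
  # model never sees more than ~chunk rows at once
  B <- nrow(background); k <- ncol(background)
  out <- numeric(nrow(Z))
  per <- max(1L, chunk %/% B)
  i <- 1L
  while (i <= nrow(Z)) {
    j <- min(nrow(Z), i + per - 1L)
    nz <- j - i + 1L
    Xc <- background[rep(seq_len(B), times = nz), , drop = FALSE]
    Zc <- Z[rep(i:j, each = B), , drop = FALSE]
    Xrep <- matrix(rep(x, each = nz * B), nz * B, k)
    Xc[Zc == 1] <- Xrep[Zc == 1]
    v <- f(Xc)
    out[i:j] <- colMeans(matrix(v, B, nz))
    i <- j + 1L
  }
  out
}

#' Kernel SHAP attribution
#'
#' For at most \code{exactMax} features all \code{2^k} coalitions are
#' enumerated, giving exact Shapley values under the background
#' distribution (so local accuracy holds exactly); otherwise coalitions are
#' sampled with Shapley-kernel weights under a fixed seed and the values
#' solve the constrained weighted least squares. The background must come
#' from training folds; explaining a sample that is itself present in the
#' background is rejected as leakage unless \code{allowOverlap}.
#'
#' @param f model function: matrix of samples -> numeric output (e.g.
#'   probability of sensitivity).
#' @param samples matrix of rows to explain.
#' @param background background reference matrix (training rows; default
#'   size in the pipeline is 200).
#' @param nsamples sampled coalitions when k > exactMax (default 2000).
#' @param exactMax full-enumeration threshold (default 12).
#' @param seed integer seed for coalition sampling.
#' @param allowOverlap permit explained rows identical to background rows.
#' @return list of class \code{Attribution}: \code{phi} (samples x
#'   features), \code{base} (mean background output), \code{backgroundSize}.
#' @export
kernelShap <- function(f, samples, background, nsamples = 2000,
                       exactMax = 12, seed = 1, allowOverlap = FALSE) {
  samples <- as.matrix(samples); background <- as.matrix(background)
  k <- ncol(samples)
  stopifnot(ncol(background) == k)
  if (!allowOverlap) {
    bkey <- apply(background, 1, paste, collapse = "\r")
    skey <- apply(samples, 1, paste, collapse = "\r")
    if (any(skey %in% bkey)) {
      stop("background overlaps explained samples: leakage")
    }
  }
  base <- mean(f(background))
  phi <- matrix(0, nrow(samples), k,
                dimnames = list(rownames(samples), colnames(samples)))
  if (k <= exactMax) {
    Z <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
    colnames(Z) <- NULL
    sizes <- rowSums(Z)
    for (si in seq_len(nrow(samples))) {
      v <- evalCoalitions(f, Z, samples[si, ], background)
      for (j in seq_len(k)) {
        withJ <- Z[, j] == 1
        # match each S (without j) to S union {j}
        Zno <- Z[!withJ, , drop = FALSE]
        vno <- v[!withJ]
        key <- Z; key[, j] <- 1
        keyStr <- apply(key[!withJ, , drop = FALSE], 1, paste, collapse = "")
        allStr <- apply(Z, 1, paste, collapse = "")
        vyes <- v[match(keyStr, allStr)]
        s <- rowSums(Zno)
        w <- factorial(s) * factorial(k - s - 1) / factorial(k)
        phi[si, j] <- sum(w * (vyes - vno))
      }
    }
  } else {
    set.seed(seed)
    sizes <- 1:(k - 1)
    pw <- vapply(sizes, function(s) shapleyKernelWeight(k, s) * choose(k, s),
                 0)
    pw <- pw / sum(pw)
    M2 <- ceiling(nsamples / 2)
    szDraw <- sample(sizes, M2, replace = TRUE, prob = pw)
    Zh <- t(vapply(szDraw, function(s) {
      z <- numeric(k); z[sample.int(k, s)] <- 1; z
    }, numeric(k)))
    Z <- rbind(Zh, 1 - Zh)  # paired (antithetic) coalitions
    M <- nrow(Z)
    wts <- rep(1, M)  # size already sampled with kernel probability
    for (si in seq_len(nrow(samples))) {
      fx <- as.numeric(f(samples[si, , drop = FALSE]))
      v <- evalCoalitions(f, Z, samples[si, ], background)
      # eliminate the efficiency constraint: phi_k = (fx-base) - sum(others)
      Zr <- Z[, -k, drop = FALSE] - Z[, k]
      yr <- v - base - Z[, k] * (fx - base)
      W <- diag(wts)
      A <- crossprod(Zr, Zr * wts) + 1e-8 * diag(k - 1)
      bvec <- crossprod(Zr, yr * wts)
      ph <- solve(A, bvec)
      phi[si, ] <- c(ph, (fx - base) - sum(ph))
    }
  }
  structure(list(phi = phi, base = base,
                 backgroundSize = nrow(background)),
            class = "Attribution")
}

#' Rank features by mean absolute SHAP value
#'
#' @param attribution an \code{Attribution} (or a phi matrix).
#' @return data.frame (feature, mean_abs_shap) in descending order, ties
#'   broken lexicographically by feature name.
#' @export
rankFeatures <- function(attribution) {
  phi <- if (inherits(attribution, "Attribution")) attribution$phi else
    as.matrix(attribution)
  stopifnot(nrow(phi) >= 1)
  nm <- colnames(phi)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(phi)))
  mAbs <- colMeans(abs(phi))
  o <- order(-mAbs, nm)
  data.frame(feature = nm[o], mean_abs_shap = unname(mAbs[o]),
             stringsAsFactors = FALSE)
}

#' Top-K genes from a feature ranking
#'
#' Maps ranked feature columns to gene symbols (non-gene columns are
#' skipped), de-duplicates in rank order, and returns the first K genes.
#'
#' @param ranked data.frame from \code{\link{rankFeatures}}.
#' @param featureGeneMap named character vector feature -> gene (NA or
#'   missing entries are skipped).
#' @param K number of genes (default 50).
#' @return character vector (length <= K; shorter with a warning if fewer
#'   mappable genes exist).
#' @export
topKGenes <- function(ranked, featureGeneMap, K = 50) {
  genes <- featureGeneMap[ranked$feature]
  genes <- genes[!is.na(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) < K) {
    warning("fewer than K mappable genes; returning all ", length(genes))
    return(unname(genes))
  }
  unname(genes[seq_len(K)])
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set's overlap with the gene
#' list against the universe, with Benjamini-Hochberg adjustment across all
#' tested sets; significant at FDR < 0.05. Sets are intersected with the
#' universe first.
#'
#' @param geneList character vector (must be contained in the universe).
#' @param geneSets named list of character vectors (e.g.
#'   \code{\link{readGMT}} output).
#' @param universe character vector of all candidate genes.
#' @return data.frame of class \code{EnrichmentResult}: set, overlap,
#'   set_size, universe_size, p, fdr, significant; ordered by p.
#' @export
hypergeomEnrich <- function(geneList, geneSets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  geneList <- intersect(unique(geneList), universe)
  N <- length(universe); n <- length(geneList)
  res <- do.call(rbind, lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    K <- length(set)
    ov <- length(intersect(geneList, set))
    p <- if (K == 0) 1 else phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = K, universe_size = N,
               p = p, stringsAsFactors = FALSE)
  }))
  res$fdr <- p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < 0.05
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}
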