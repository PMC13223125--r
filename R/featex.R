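#' Decimal-scaling normalization
#'
#' Divides by \code{10^j} where j is the smallest non-negative integer such
#' that \code{max(abs(x)) / 10^j < 1} (j = 0 when already below 1). Applied
#' to convolutional responses before activation so feature magnitudes from
#' fused channels stay on a comparable scale. The exponent is attached as
#' attribute \code{"j"}; \code{x * 10^j} reconstructs the input exactly.
#'
#' @param x numeric array (finite).
#' @return scaled array with attribute \code{j}.
#' @export
dsScale <- function(x) {
  if (!all(is.finite(x))) stop("non-finite input to decimal scaling")
  mx <- max(abs(x))
  j <- 0L
  while (mx / 10^j >= 1) j <- j + 1L
  out <- x / 10^j
  attr(out, "j") <- j
  out
}

#' Fuse the three representation channels into one tensor
#'
#' Channel order is fixed: 1 = tree patristic-distance map, 2 = binary
#' event-indicator map, 3 = drug depiction. No mixing happens at fusion.
#'
#' @param treeMap,eventMap,depiction equally sized square matrices.
#' @return size x size x 3 array.
#' @export
fuseTensor <- function(treeMap, eventMap, depiction) {
  d <- dim(treeMap)
  if (!identical(d, dim(eventMap)) || !identical(d, dim(depiction))) {
    stop("channel shape mismatch: ",
         paste(d, collapse = "x"), " vs ",
         paste(dim(eventMap), collapse = "x"), " vs ",
         paste(dim(depiction), collapse = "x"))
  }
  array(c(treeMap, eventMap, depiction), dim = c(d, 3))
}

#' Binary event-indicator channel
#'
#' Marks the tree-map leaf rows by event type banding: for leaf i carrying
#' event type k (of the five-event vocabulary), the cells in row i within
#' the k-th vertical band are set to 1.
#'
#' @param events character vector of event labels, one per leaf (in leaf
#'   order).
#' @param size map side length.
#' @return size x size binary matrix.
#' @export
makeEventMap <- function(events, size = 224) {
  vocab <- c("insertion", "deletion", "inversion", "mirror", "duplication")
  m <- matrix(0, size, size)
  if (length(events) == 0) return(m)
  if (length(events) > size) stop("more leaves than map size")
  bw <- size %/% 5
  for (i in seq_along(events)) {
    k <- match(events[i], vocab)
    if (is.na(k)) next
    cols <- ((k - 1) * bw + 1):(k * bw)
    m[i, cols] <- 1
  }
  m
}

# ---- mini inception-style deep feature extractor ---------------------------

pad2d <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

# im2col convolution, 'same' padding; W: (k*k*C) x F
conv2d <- function(x, W, k) {
  d <- dim(x)
  p <- (k - 1) %/% 2
  xp <- pad2d(x, p)
  H <- d[1]; Wd <- d[2]; C <- d[3]
  cols <- matrix(0, H * Wd, k * k * C)
  col <- 1
  for (cc in seq_len(C)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    cols[, col] <- as.vector(xp[(1 + di):(H + di), (1 + dj):(Wd + dj), cc])
    col <- col + 1
  }
  out <- cols %*% W
  array(out, dim = c(H, Wd, ncol(W)))
}

avgPool2 <- function(x) {
  d <- dim(x)
  h <- d[1] %/% 2; w <- d[2] %/% 2
  x <- x[seq_len(2 * h), seq_len(2 * w), , drop = FALSE]
  (x[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
   x[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
   x[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE] +
   x[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE]) / 4
}

maxPool3same <- function(x) {
  d <- dim(x)
  xp <- pad2d(x, 1)
  out <- x
  for (cc in seq_len(d[3])) {
    m <- xp[, , cc]
    acc <- matrix(-Inf, d[1], d[2])
    for (di in 0:2) for (dj in 0:2) {
      acc <- pmax(acc, m[(1 + di):(d[1] + di), (1 + dj):(d[2] + dj)])
    }
    out[, , cc] <- acc
  }
  out
}

#' Deep feature extractor configuration
#'
#' \code{miniMode} (default) uses a 56 x 56 input with two inception blocks
#' and penultimate width 64, sized so a forward pass runs in well under a
#' second on one CPU; full mode uses 224 x 224 with four blocks.
#'
#' @param miniMode logical.
#' @param seed integer seed for the convolutional filter initialization.
#' @return a \code{DSCNNConfig} list.
#' @export
dscnnConfig <- function(miniMode = TRUE, seed = 1) {
  if (miniMode) {
    list(inputSize = 56,
         blocks = list(c(f1 = 4, f3 = 8, f5 = 4, fp = 4),
                       c(f1 = 8, f3 = 16, f5 = 8, fp = 8)),
         penultimate = 64, seed = as.integer(seed), miniMode = TRUE)
  } else {
    list(inputSize = 224,
         blocks = list(c(f1 = 16, f3 = 32, f5 = 16, fp = 16),
                       c(f1 = 32, f3 = 48, f5 = 32, fp = 16),
                       c(f1 = 48, f3 = 64, f5 = 48, fp = 32),
                       c(f1 = 64, f3 = 96, f5 = 64, fp = 32)),
         penultimate = 1024, seed = as.integer(seed), miniMode = FALSE)
  }
}

heInit <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Initialize deep extractor parameters
#'
#' Convolutional filters, pooling maps and the fully connected layer are
#' drawn from a seeded He-scaled Gaussian; with a fixed seed the parameter
#' set (and hence every extracted feature) is reproducible.
#'
#' @param config a \code{\link{dscnnConfig}}.
#' @param channels input channel count (3 for the fused tensor).
#' @return parameter list.
#' @export
dscnnInit <- function(config, channels = 3) {
  set.seed(config$seed)
  params <- list(blocks = list(), config = config)
  cin <- channels
  for (b in seq_along(config$blocks)) {
    w <- config$blocks[[b]]
    blk <- list(
      W1 = heInit(1 * 1 * cin, w["f1"]),
      W3 = heInit(3 * 3 * cin, w["f3"]),
      W5 = heInit(5 * 5 * cin, w["f5"]),
      Wp = heInit(1 * 1 * cin, w["fp"]))
    cout <- sum(w)
    blk$Wd <- heInit(cout, cout) / sqrt(cout)  # learnable pooling map
    params$blocks[[b]] <- blk
    cin <- cout
  }
  params$Wfc <- heInit(cin, config$penultimate)
  params$bfc <- rep(0, config$penultimate)
  params
}

#' Deep features from a fused tensor
#'
#' Forward pass of the inception-style extractor: each convolutional
#' response is decimal-scaled, then ReLU-activated; each block is followed
#' by 2 x 2 average pooling and a learnable channel map; global average
#' pooling and a fully connected layer give the penultimate feature vector.
#' Per-layer maxima of the decimal-scaled pre-activations are attached as
#' attribute \code{"ds_max"} (all strictly below 1 by construction).
#'
#' @param tensor input array (inputSize x inputSize x 3); larger inputs are
#'   average-pooled down to the configured size.
#' @param params from \code{\link{dscnnInit}}.
#' @return numeric penultimate feature vector.
#' @export
dscnnFeatures <- function(tensor, params) {
  cfg <- params$config
  while (dim(tensor)[1] > cfg$inputSize) tensor <- avgPool2(tensor)
  stopifnot(dim(tensor)[1] == cfg$inputSize)
  dsmax <- c()
  act <- function(z) {
    zs <- dsScale(z)
    dsmax <<- c(dsmax, max(abs(zs)))
    pmax(zs, 0)
  }
  x <- tensor
  for (blk in params$blocks) {
    b1 <- act(conv2d(x, blk$W1, 1))
    b3 <- act(conv2d(x, blk$W3, 3))
    b5 <- act(conv2d(x, blk$W5, 5))
    bp <- act(conv2d(maxPool3same(x), blk$Wp, 1))
    x <- array(c(b1, b3, b5, bp),
               dim = c(dim(b1)[1], dim(b1)[2],
                       dim(b1)[3] + dim(b3)[3] + dim(b5)[3] + dim(bp)[3]))
    x <- avgPool2(x)
    d <- dim(x)
    x <- array(matrix(x, d[1] * d[2], d[3]) %*% blk$Wd, dim = d)
  }
  gap <- apply(x, 3, mean)
  pen <- act(as.numeric(gap %*% params$Wfc + params$bfc))
  attr(pen, "ds_max") <- dsmax
  pen
}

#' Fit the softmax pretraining head
#'
#' Multinomial/binomial logistic head on penultimate features of the
#' training rows only; its softmax output is the pretraining objective, and
#' the penultimate representation is what downstream stages consume.
#'
#' @param features rows = samples (training fold only).
#' @param labels binary labels (factor or 0/1).
#' @return object with \code{predictProb} returning class probabilities
#'   summing to 1.
#' @export
dscnnTrainHead <- function(features, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  fit <- glmnet::glmnet(as.matrix(features), y, family = "binomial",
                        lambda = 0.01)
  structure(list(fit = fit,
                 predictProb = function(newx) {
                   p1 <- as.numeric(predict(fit, as.matrix(newx),
                                            type = "response"))
                   cbind(p0 = 1 - p1, p1 = p1)
                 }), class = "DscnnHead")
}

# ---- handcrafted texture descriptors ---------------------------------------

quantizeGray <- function(img, nGray) {
  r <- range(img)
  if (diff(r) < 1e-12) return(matrix(1L, nrow(img), ncol(img)))
  q <- floor((img - r[1]) / diff(r) * nGray) + 1L
  q[q > nGray] <- nGray
  matrix(as.integer(q), nrow(img), ncol(img))
}

#' Gray-level co-occurrence (Haralick) features
#'
#' Quantizes to \code{nGray} levels and accumulates symmetric co-occurrence
#' at four offsets (0,1), (1,0), (1,1), (1,-1); reports contrast,
#' correlation, energy and homogeneity per offset (16 values).
#'
#' @param img 2D numeric matrix.
#' @param nGray gray-level count (default 8).
#' @return named numeric vector of length 16.
#' @export
glcmFeatures <- function(img, nGray = 8) {
  if (length(dim(img)) != 2) stop("glcmFeatures expects a 2D image")
  q <- quantizeGray(img, nGray)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  out <- c()
  n <- nrow(q); m <- ncol(q)
  for (o in offs) {
    di <- o[1]; dj <- o[2]
    i0 <- max(1, 1 - di):min(n, n - di)
    j0 <- max(1, 1 - dj):min(m, m - dj)
    a <- q[i0, j0, drop = FALSE]
    b <- q[i0 + di, j0 + dj, drop = FALSE]
    P <- matrix(0, nGray, nGray)
    for (k in seq_along(a)) {
      P[a[k], b[k]] <- P[a[k], b[k]] + 1
      P[b[k], a[k]] <- P[b[k], a[k]] + 1
    }
    P <- P / sum(P)
    i <- row(P); j <- col(P)
    mu_i <- sum(i * P); mu_j <- sum(j * P)
    sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
    corr <- if (sd_i < 1e-12 || sd_j < 1e-12) 0 else
      sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
    out <- c(out,
             contrast = sum((i - j)^2 * P),
             correlation = corr,
             energy = sum(P^2),
             homogeneity = sum(P / (1 + (i - j)^2)))
  }
  names(out) <- paste0(rep(c("contrast", "correlation", "energy",
                             "homogeneity"), 4),
                       rep(c("_0_1", "_1_0", "_1_1", "_1_m1"), each = 4))
  out
}

# uniform LBP lookup for P=8: patterns with <=2 circular transitions map to
# 58 bins, the rest to bin 59
.lbpUniformMap <- local({
  m <- integer(256)
  bin <- 1L
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    trans <- sum(bits != c(bits[-1], bits[1]))
    if (trans <= 2) {
      m[code + 1] <- bin
      bin <- bin + 1L
    } else m[code + 1] <- 0L
  }
  m[m == 0] <- max(m) + 1L
  m
})

lbpCodes <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n < 3 || m < 3) stop("image too small for LBP")
  ci <- 2:(n - 1); cj <- 2:(m - 1)
  ctr <- img[ci, cj]
  # neighbors in circular order
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, length(ci), length(cj))
  for (b in seq_along(offs)) {
    nb <- img[ci + offs[[b]][1], cj + offs[[b]][2]]
    code <- code + as.integer(nb >= ctr) * 2L^(b - 1L)
  }
  code
}

#' Uniform local binary pattern histogram (P = 8, R = 1)
#'
#' @param img 2D numeric matrix (>= 3 x 3).
#' @return normalized 59-bin histogram (58 uniform patterns + 1 catch-all).
#' @export
lbpFeatures <- function(img) {
  if (length(dim(img)) != 2) stop("lbpFeatures expects a 2D image")
  code <- lbpCodes(img)
  bins <- .lbpUniformMap[code + 1L]
  h <- tabulate(bins, nbins = 59)
  h / sum(h)
}

#' Local tetra pattern features
#'
#' First-order horizontal/vertical derivatives give each pixel a direction
#' code in \{1,2,3,4\}; for each center, the 8-neighborhood tetra pattern is
#' split into three binary patterns (one per non-center direction, in cyclic
#' order) each summarized as a uniform LBP histogram, plus a magnitude
#' pattern histogram and the 4-bin direction histogram (240 values).
#'
#' @param img 2D numeric matrix (>= 4 x 4).
#' @return numeric vector of length 240.
#' @export
ltrpFeatures <- function(img) {
  if (length(dim(img)) != 2) stop("ltrpFeatures expects a 2D image")
  n <- nrow(img); m <- ncol(img)
  gh <- cbind(img[, -1] - img[, -m], 0)
  gv <- rbind(img[-1, ] - img[-n, ], 0)
  dir <- matrix(1L, n, m)
  dir[gh < 0 & gv >= 0] <- 2L
  dir[gh < 0 & gv < 0] <- 3L
  dir[gh >= 0 & gv < 0] <- 4L
  mag <- sqrt(gh^2 + gv^2)

  dirHist <- tabulate(dir, nbins = 4) / length(dir)

  ci <- 2:(n - 1); cj <- 2:(m - 1)
  ctr <- dir[ci, cj]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  hists <- matrix(0, 3, 59)
  for (comp in 1:3) {
    # comp-th direction after the center's, cyclically
    target <- (ctr + comp - 1L) %% 4L + 1L
    code <- matrix(0L, length(ci), length(cj))
    for (b in seq_along(offs)) {
      nb <- dir[ci + offs[[b]][1], cj + offs[[b]][2]]
      code <- code + as.integer(nb == target) * 2L^(b - 1L)
    }
    bins <- .lbpUniformMap[code + 1L]
    h <- tabulate(bins, nbins = 59)
    hists[comp, ] <- h / sum(h)
  }
  magH <- lbpFeatures(mag)
  c(dirHist, as.vector(t(hists)), magH)
}

#' Assemble the full feature matrix
#'
#' Concatenates the deep, handcrafted and attribute blocks (rows aligned on
#' cell line-drug pair keys) with provenance-tagged column names, and
#' standardizes continuous columns using training-row statistics only.
#'
#' @param deep,handcrafted,attributes numeric matrices with identical
#'   rownames (pair keys); any may have zero columns.
#' @param trainIdx row indices (or logical) of the training fold; defaults
#'   to all rows.
#' @param standardize logical.
#' @return list: \code{X} (the assembled matrix), \code{provenance}
#'   (character per column), \code{center}, \code{scale}.
#' @export
assembleFeatures <- function(deep, handcrafted, attributes,
                             trainIdx = NULL, standardize = TRUE) {
  blocks <- list(deep = deep, handcrafted = handcrafted,
                 attributes = attributes)
  blocks <- Filter(function(b) !is.null(b) && ncol(b) > 0, blocks)
  keys <- rownames(blocks[[1]])
  for (nm in names(blocks)) {
    if (!identical(rownames(blocks[[nm]]), keys)) {
      bad <- setdiff(union(rownames(blocks[[nm]]), keys),
                     intersect(rownames(blocks[[nm]]), keys))
      stop("row misalignment across feature blocks; offending keys: ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  prov <- unlist(lapply(names(blocks), function(nm)
    rep(nm, ncol(blocks[[nm]]))))
  X <- do.call(cbind, blocks)
  colnames(X) <- make.unique(unlist(lapply(names(blocks), function(nm) {
    cn <- colnames(blocks[[nm]])
    if (is.null(cn)) cn <- paste0(nm, ".", seq_len(ncol(blocks[[nm]])))
    cn
  })))
  if (anyNA(X)) stop("missing values after assembly")
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    if (is.null(trainIdx)) trainIdx <- seq_len(nrow(X))
    Xt <- X[trainIdx, , drop = FALSE]
    ctr <- colMeans(Xt)
    scl <- apply(Xt, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  list(X = X, provenance = prov, center = ctr, scale = scl)
}
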