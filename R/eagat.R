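#' Aranda activation
#'
#' The asymmetric Aranda-Ordaz transformation
#' \code{phi(z) = 1 - (1 + lambda * exp(z))^(-1/lambda)}, strictly
#' increasing from 0 to 1; at \code{lambda = 1} it reduces exactly to the
#' logistic function. Used as the non-linearity after neighborhood
#' aggregation in the graph attention classifier.
#'
#' @param z numeric.
#' @param lambda shape (> 0), default 2.
#' @return values in (0, 1).
#' @export
arandaLog1p <- function(z, lambda) {
  lz <- log1p(lambda * exp(pmin(z, 30)))
  big <- z > 30
  if (any(big)) lz[big] <- log(lambda) + z[big]
  lz
}

arandaActivation <- function(z, lambda = 2) {
  if (lambda <= 0) stop("lambda must be positive")
  out <- 1 - exp(-arandaLog1p(z, lambda) / lambda)
  attributes(out) <- attributes(z)
  out
}

arandaGrad <- function(z, lambda = 2) {
  exp(z - (1 / lambda + 1) * arandaLog1p(z, lambda))
}

leaky <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
leakyGrad <- function(x, slope = 0.2) slope + (1 - slope) * (x > 0)

#' Feature graph over selected columns
#'
#' Nodes are feature columns. For at most \code{fullyConnectedMax} features
#' the graph is fully connected; otherwise each node is linked to its k
#' nearest neighbors by absolute Pearson correlation computed on training
#' rows only. The adjacency is symmetrized and self-loops are always
#' included, so every node has at least one neighbor.
#'
#' @param Xtrain training-row feature matrix.
#' @param k neighbors (default 10).
#' @param fullyConnectedMax threshold for the dense option (default 64).
#' @return list: \code{edges} (data.frame u, v), \code{p} (node count),
#'   \code{groups} (edge indices grouped by u).
#' @export
buildFeatureGraph <- function(Xtrain, k = 10, fullyConnectedMax = 64) {
  p <- ncol(Xtrain)
  if (p <= fullyConnectedMax) {
    eu <- rep(seq_len(p), each = p)
    ev <- rep(seq_len(p), times = p)
  } else {
    C <- abs(suppressWarnings(stats::cor(Xtrain)))
    C[is.na(C)] <- 0
    diag(C) <- -Inf
    kk <- min(k, p - 1)
    adj <- matrix(FALSE, p, p)
    for (u in seq_len(p)) {
      nb <- order(C[u, ], decreasing = TRUE)[seq_len(kk)]
      adj[u, nb] <- TRUE
    }
    adj <- adj | t(adj)
    diag(adj) <- TRUE
    idx <- which(adj, arr.ind = TRUE)
    eu <- idx[, 1]; ev <- idx[, 2]
  }
  o <- order(eu, ev)
  eu <- eu[o]; ev <- ev[o]
  list(edges = data.frame(u = eu, v = ev), p = p,
       groups = split(seq_along(eu), eu))
}

#' Initialize EA-GAT parameters
#'
#' @param p number of feature nodes.
#' @param hidden embedding width (default 16).
#' @param lambda Aranda shape (> 0).
#' @param activation "aranda" or "relu" (ablation).
#' @param seed integer seed.
#' @return parameter list (embed weight/bias, attention vectors, output
#'   layer, shape, activation tag).
#' @export
eagatInit <- function(p, hidden = 16, lambda = 2,
                      activation = c("aranda", "relu"), seed = 1) {
  activation <- match.arg(activation)
  if (lambda <= 0) stop("lambda must be positive")
  set.seed(seed)
  sc <- sqrt(1 / hidden)
  # gamma/delta: the learnable per-node (diagonal) part of the linear
  # embedding; w/b: the shared embedding direction
  list(gamma = rep(1, p), delta = rep(0, p),
       w = rnorm(hidden, sd = sc), b = rnorm(hidden, sd = sc),
       aAlpha = rnorm(hidden, sd = sc), aBeta = rnorm(hidden, sd = sc),
       Wo = matrix(rnorm(2 * hidden, sd = sc), 2, hidden),
       bo = c(0, 0), lambda = lambda, activation = activation,
       hidden = hidden, p = p)
}

actFn <- function(params) {
  if (params$activation == "aranda") {
    list(f = function(z) arandaActivation(z, params$lambda),
         g = function(z) arandaGrad(z, params$lambda))
  } else {
    list(f = function(z) pmax(z, 0), g = function(z) as.numeric(z > 0))
  }
}

# shared forward core; X: n x p, returns cache for backprop. Node states are
# H0_u = (gamma_u x_u + delta_u) w + b, i.e. a per-node affine transform
# followed by the shared embedding direction.
eagatForwardCore <- function(params, X, graph) {
  eu <- graph$edges$u; ev <- graph$edges$v
  n <- nrow(X); p <- graph$p; h <- params$hidden
  if (ncol(X) != p) stop("feature count does not match graph")
  S <- sweep(X, 2, params$gamma, "*")
  S <- sweep(S, 2, params$delta, "+")
  A1 <- sum(params$aAlpha * params$w)
  A2 <- sum(params$aBeta * params$w)
  A0 <- sum((params$aAlpha + params$aBeta) * params$b)
  S1 <- S[, eu, drop = FALSE] * A1 + S[, ev, drop = FALSE] * A2 + A0
  E <- leaky(S1)
  # per-neighborhood softmax; blocks assembled once to avoid large copies
  alphaBlocks <- vector("list", p)
  mCols <- vector("list", p)
  for (u in seq_len(p)) {
    g <- graph$groups[[u]]
    Eg <- E[, g, drop = FALSE]
    mx <- Eg[, 1]
    if (length(g) > 1) for (j in 2:length(g)) mx <- pmax(mx, Eg[, j])
    W <- exp(Eg - mx)
    ab <- W / rowSums(W)
    alphaBlocks[[u]] <- ab
    mCols[[u]] <- rowSums(ab * S[, ev[g], drop = FALSE])
  }
  alpha <- do.call(cbind, alphaBlocks)
  m <- do.call(cbind, mCols)
  af <- actFn(params)
  r <- matrix(0, n, h)
  Pre <- vector("list", h)
  for (k in seq_len(h)) {
    Pre[[k]] <- m * params$w[k] + params$b[k]
    r[, k] <- rowMeans(af$f(Pre[[k]]))
  }
  z <- r %*% t(params$Wo)
  z <- sweep(z, 2, params$bo, "+")
  zmax <- pmax(z[, 1], z[, 2])
  ez <- exp(z - zmax)
  probs <- ez / rowSums(ez)
  list(probs = probs, S = S, S1 = S1, alpha = alpha, m = m, Pre = Pre,
       r = r, eu = eu, ev = ev, af = af)
}

#' Attention coefficients for one sample
#'
#' Computes the normalized attention weights alpha_uv = softmax over the
#' neighborhood of u of the leaky-rectified attention logits; each row sums
#' to one over its neighborhood.
#'
#' @param params EA-GAT parameters.
#' @param x a single sample's feature vector.
#' @param graph a \code{\link{buildFeatureGraph}} result.
#' @return p x p matrix, zero off-neighborhood, rows summing to 1.
#' @export
attentionCoefficients <- function(params, x, graph) {
  fw <- eagatForwardCore(params, matrix(x, 1), graph)
  A <- matrix(0, graph$p, graph$p)
  A[cbind(fw$eu, fw$ev)] <- fw$alpha[1, ]
  A
}

#' EA-GAT forward pass
#'
#' Node scalar values are the sample's selected features; node states are
#' linearly embedded, aggregated with attention, passed through the Aranda
#' activation, mean-read-out over nodes and mapped to class probabilities
#' by a softmax output layer (resistant = 0, sensitive = 1).
#'
#' @param params EA-GAT parameters.
#' @param X samples x features matrix (features must match the graph).
#' @param graph feature graph.
#' @return n x 2 matrix of class probabilities (rows sum to 1).
#' @export
eagatForward <- function(params, X, graph) {
  eagatForwardCore(params, as.matrix(X), graph)$probs
}

eagatGradients <- function(params, X, Y, graph) {
  fw <- eagatForwardCore(params, X, graph)
  n <- nrow(X); p <- graph$p; h <- params$hidden
  dz <- (fw$probs - Y) / n
  loss <- -mean(rowSums(Y * log(pmax(fw$probs, 1e-12))))
  dWo <- t(dz) %*% fw$r
  dbo <- colSums(dz)
  dr <- dz %*% params$Wo
  dw <- numeric(h); db <- numeric(h)
  dm <- matrix(0, n, p)
  for (k in seq_len(h)) {
    gk <- fw$af$g(fw$Pre[[k]])
    dPre <- (dr[, k] / p) * gk
    dw[k] <- sum(dPre * fw$m)
    db[k] <- sum(dPre)
    dm <- dm + dPre * params$w[k]
  }
  S <- fw$S
  deBlocks <- vector("list", p)
  for (u in seq_len(p)) {
    g <- graph$groups[[u]]
    ag <- fw$alpha[, g, drop = FALSE]
    dg <- dm[, u] * S[, fw$ev[g], drop = FALSE]
    deBlocks[[u]] <- ag * (dg - rowSums(ag * dg))
  }
  dE <- do.call(cbind, deBlocks)
  dS1 <- dE * leakyGrad(fw$S1)
  A1 <- sum(params$aAlpha * params$w)
  A2 <- sum(params$aBeta * params$w)
  dA1 <- sum(dS1 * S[, fw$eu, drop = FALSE])
  dA2 <- sum(dS1 * S[, fw$ev, drop = FALSE])
  dA0 <- sum(dS1)
  daAlpha <- dA1 * params$w + dA0 * params$b
  daBeta <- dA2 * params$w + dA0 * params$b
  dw <- dw + dA1 * params$aAlpha + dA2 * params$aBeta
  db <- db + dA0 * (params$aAlpha + params$aBeta)
  # dS: (a) aggregation m_u = sum alpha_uv S_v, (b,c) attention logits
  vgroups <- split(seq_along(fw$ev), fw$ev)
  alphaDm <- fw$alpha * dm[, fw$eu, drop = FALSE]
  aggPart <- vapply(seq_len(p), function(v)
    rowSums(alphaDm[, vgroups[[v]], drop = FALSE]), numeric(n))
  attU <- vapply(seq_len(p), function(u)
    rowSums(dS1[, graph$groups[[u]], drop = FALSE]), numeric(n)) * A1
  attV <- vapply(seq_len(p), function(v)
    rowSums(dS1[, vgroups[[v]], drop = FALSE]), numeric(n)) * A2
  dS <- aggPart + attU + attV
  dgamma <- colSums(dS * X)
  ddelta <- colSums(dS)
  list(loss = loss,
       grads = list(gamma = dgamma, delta = ddelta, w = dw, b = db,
                    aAlpha = daAlpha, aBeta = daBeta, Wo = dWo, bo = dbo))
}

#' Train the EA-GAT classifier
#'
#' Full-batch Adam minimization of the cross-entropy with early stopping on
#' an inner validation split; seed-reproducible. All fitted quantities use
#' the supplied (training) rows only.
#'
#' @param X training features (rows = samples).
#' @param y binary labels (0 = resistant, 1 = sensitive).
#' @param graph feature graph from \code{\link{buildFeatureGraph}}.
#' @param hidden,lambda,activation architecture knobs (see
#'   \code{\link{eagatInit}}).
#' @param epochs,lr,patience optimization knobs.
#' @param weightDecay L2 penalty on weights (not biases); discourages the
#'   per-node gates from memorizing uninformative features.
#' @param valFrac inner validation fraction for early stopping.
#' @param maxRestarts some initializations stall at chance-level loss
#'   (~log 2) and are stopped early; up to this many re-initializations
#'   with derived seeds are tried, keeping the best validation loss.
#' @param seed integer seed.
#' @return fitted parameter list with attributes \code{trainLoss} (loss at
#'   accepted checkpoints, essentially non-increasing) and \code{valLoss}.
#' @export
eagatTrain <- function(X, y, graph, hidden = 16, lambda = 2,
                       activation = c("aranda", "relu"), epochs = 300,
                       lr = 0.05, patience = 30, weightDecay = 1e-3,
                       valFrac = 0.15, maxRestarts = 3, seed = 1) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("single-class training input")
  split <- innerStratifiedSplit(y, valFrac, seed)
  Xt <- X[split$train, , drop = FALSE]; yt <- y[split$train]
  Xv <- X[split$val, , drop = FALSE]; yv <- y[split$val]
  Yt <- cbind(1 - yt, yt); Yv <- cbind(1 - yv, yv)
  decayed <- c("gamma", "w", "aAlpha", "aBeta", "Wo")
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  trainOnce <- function(initSeed) {
    params <- eagatInit(graph$p, hidden, lambda, activation, initSeed)
    mAdam <- vAdam <- lapply(params[c("gamma", "delta", "w", "b", "aAlpha",
                                      "aBeta", "Wo", "bo")],
                             function(x) x * 0)
    best <- params; bestVal <- Inf; wait <- 0
    trainLoss <- c(); valLoss <- c()
    for (ep in seq_len(epochs)) {
      gr <- eagatGradients(params, Xt, Yt, graph)
      for (nm in names(mAdam)) {
        g <- gr$grads[[nm]]
        if (nm %in% decayed) g <- g + weightDecay * params[[nm]]
        mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g
        vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g^2
        mh <- mAdam[[nm]] / (1 - beta1^ep)
        vh <- vAdam[[nm]] / (1 - beta2^ep)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
      pv <- eagatForward(params, Xv, graph)
      vl <- -mean(rowSums(Yv * log(pmax(pv, 1e-12))))
      if (vl < bestVal - 1e-6) {
        bestVal <- vl; best <- params; wait <- 0
        trainLoss <- c(trainLoss, gr$loss); valLoss <- c(valLoss, vl)
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
    attr(best, "trainLoss") <- trainLoss
    attr(best, "valLoss") <- valLoss
    list(params = best, bestVal = bestVal)
  }

  stallLevel <- 0.95 * log(2)
  overallBest <- NULL; overallVal <- Inf
  for (attempt in seq_len(max(1, maxRestarts))) {
    res <- trainOnce(seed + (attempt - 1L) * 1000L)
    if (res$bestVal < overallVal) {
      overallVal <- res$bestVal; overallBest <- res$params
    }
    if (overallVal < stallLevel) break
  }
  overallBest
}

#' Predicted probability of sensitivity
#'
#' @param params trained EA-GAT parameters.
#' @param X feature matrix.
#' @param graph feature graph used at training time.
#' @return numeric vector of P(sensitive).
#' @export
eagatPredict <- function(params, X, graph) {
  eagatForward(params, X, graph)[, 2]
}

#' Plain multilayer perceptron baseline (non-graph ablation head)
#'
#' One hidden layer with the same activation options, trained with the same
#' Adam/early-stopping loop; used by the non-graph-classifier ablation.
#'
#' @inheritParams eagatTrain
#' @return list with fitted weights and a \code{predictProb} function.
#' @export
mlpTrain <- function(X, y, hidden = 16, epochs = 300, lr = 0.05,
                     patience = 30, valFrac = 0.15, seed = 1) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("single-class training input")
  split <- innerStratifiedSplit(y, valFrac, seed)
  Xt <- X[split$train, , drop = FALSE]; yt <- y[split$train]
  Xv <- X[split$val, , drop = FALSE]; yv <- y[split$val]
  Yt <- cbind(1 - yt, yt); Yv <- cbind(1 - yv, yv)
  p <- ncol(X)
  set.seed(seed)
  th <- list(W1 = matrix(rnorm(p * hidden, sd = sqrt(1 / p)), p, hidden),
             b1 = rep(0, hidden),
             W2 = matrix(rnorm(hidden * 2, sd = sqrt(1 / hidden)), hidden, 2),
             b2 = c(0, 0))
  fwd <- function(th, X) {
    H <- pmax(sweep(X %*% th$W1, 2, th$b1, "+"), 0)
    z <- sweep(H %*% th$W2, 2, th$b2, "+")
    ez <- exp(z - apply(z, 1, max))
    list(H = H, probs = ez / rowSums(ez))
  }
  mA <- vA <- lapply(th, function(x) x * 0)
  best <- th; bestVal <- Inf; wait <- 0
  for (ep in seq_len(epochs)) {
    f <- fwd(th, Xt)
    dz <- (f$probs - Yt) / nrow(Xt)
    gr <- list(W2 = t(f$H) %*% dz, b2 = colSums(dz))
    dH <- (dz %*% t(th$W2)) * (f$H > 0)
    gr$W1 <- t(Xt) %*% dH; gr$b1 <- colSums(dH)
    for (nm in names(th)) {
      mA[[nm]] <- 0.9 * mA[[nm]] + 0.1 * gr[[nm]]
      vA[[nm]] <- 0.999 * vA[[nm]] + 0.001 * gr[[nm]]^2
      th[[nm]] <- th[[nm]] - lr * (mA[[nm]] / (1 - 0.9^ep)) /
        (sqrt(vA[[nm]] / (1 - 0.999^ep)) + 1e-8)
    }
    pv <- fwd(th, Xv)$probs
    vl <- -mean(rowSums(Yv * log(pmax(pv, 1e-12))))
    if (vl < bestVal - 1e-6) { bestVal <- vl; best <- th; wait <- 0 }
    else { wait <- wait + 1; if (wait >= patience) break }
  }
  list(weights = best,
       predictProb = function(newX) fwd(best, as.matrix(newX))$probs[, 2])
}
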