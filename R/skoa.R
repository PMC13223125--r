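#' Initialize a kookaburra population
#'
#' Each coordinate is drawn i.i.d. uniform on its bounds:
#' position = (ub - lb) * alpha + lb with alpha ~ U(0, 1).
#'
#' @param a population size (>= 2).
#' @param k number of decision variables (>= 1).
#' @param lb,ub scalar or per-dimension bounds, lb < ub.
#' @param seed integer seed.
#' @return a \code{SKOAState} list: \code{E} (a x k positions), bounds,
#'   iteration counter, best position/fitness placeholders.
#' @export
skoaInitialize <- function(a = 30, k, lb = 0, ub = 1, seed) {
  stopifnot(a >= 2, k >= 1)
  lb <- rep_len(lb, k); ub <- rep_len(ub, k)
  if (any(lb >= ub)) stop("lb must be < ub in every dimension")
  set.seed(seed)
  alpha <- matrix(runif(a * k), a, k)
  E <- sweep(sweep(alpha, 2, ub - lb, "*"), 2, lb, "+")
  list(E = E, lb = lb, ub = ub, t = 0L, Tmax = NA_integer_,
       fitness = rep(NA_real_, a), best = NULL, bestFitness = -Inf)
}

#' Binarize a continuous position into a feature mask
#'
#' A coordinate is selected iff its value is strictly greater than 0.5; an
#' all-zero result is guarded by forcing inclusion of the single maximum
#' coordinate.
#'
#' @param position numeric vector in [0, 1].
#' @return logical mask of the same length.
#' @export
binarizeMask <- function(position) {
  mask <- position > 0.5
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

# closed-form ridge linear probe; returns inner-validation accuracy
ridgeProbeAccuracy <- function(X, y, trainIdx, valIdx, lambda = 1) {
  Xt <- X[trainIdx, , drop = FALSE]
  yt <- ifelse(y[trainIdx] == 1, 1, -1)
  ctr <- colMeans(Xt)
  Xt <- sweep(Xt, 2, ctr)
  A <- crossprod(Xt) + lambda * diag(ncol(Xt))
  beta <- solve(A, crossprod(Xt, yt))
  b0 <- mean(yt)
  Xv <- sweep(X[valIdx, , drop = FALSE], 2, ctr)
  pred <- as.numeric(Xv %*% beta + b0) > 0
  mean(pred == (y[valIdx] == 1))
}

#' Wrapper fitness of a feature mask
#'
#' Inner-validation accuracy of a fast ridge-regularized linear surrogate
#' trained on the masked columns; the inner stratified split touches
#' training-fold rows only. Invariant to column order within the mask.
#'
#' @param mask logical feature mask (non-empty).
#' @param X training feature matrix.
#' @param y binary labels (0/1).
#' @param innerFrac inner validation fraction (default 0.3).
#' @param seed seed for the inner split (fixed per run so all candidate
#'   masks are scored on the same split).
#' @return accuracy in [0, 1].
#' @export
skoaFitness <- function(mask, X, y, innerFrac = 0.3, seed = 1) {
  stopifnot(any(mask))
  split <- innerStratifiedSplit(y, innerFrac, seed)
  if (length(unique(y[split$val])) < 2 ||
      length(unique(y[split$train])) < 2) {
    stop("single-class inner split")
  }
  ridgeProbeAccuracy(X[, mask, drop = FALSE], y, split$train, split$val)
}

innerStratifiedSplit <- function(y, frac, seed) {
  if (!exists(".Random.seed", envir = .GlobalEnv)) set.seed(NULL)
  rs <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", rs, envir = .GlobalEnv))
  set.seed(seed)
  val <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    val <- c(val, sample(idx, max(1, round(frac * length(idx)))))
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Smoluchowski prey selection
#'
#' Samples the prey from the population with probability proportional to a
#' diffusion-weighted fitness kernel:
#' \code{w_i = Fit(x_i) * exp(-||x_i - x*||^2 / (2 sigma_t^2))}, where the
#' diffusion scale decays as \code{sigma_t^2 = sigma0^2 / t} (an
#' Einstein-Smoluchowski schedule): early iterations sample broadly, late
#' iterations concentrate near the incumbent best. All-zero weights fall
#' back to uniform sampling.
#'
#' @param state a \code{SKOAState} with fitness evaluated.
#' @param sigma0 base diffusion scale (default 1).
#' @return the selected prey position (numeric vector).
#' @export
smoluchowskiSelectPrey <- function(state, sigma0 = 1) {
  E <- state$E
  fit <- state$fitness
  if (nrow(E) == 1) return(E[1, ])
  t <- max(state$t, 1L)
  sigma2 <- sigma0^2 / t
  best <- if (is.null(state$best)) E[which.max(fit), ] else state$best
  d2 <- rowSums(sweep(E, 2, best)^2)
  w <- fit * exp(-d2 / (2 * sigma2))
  if (!any(w > 0) || !all(is.finite(w))) w <- rep(1, nrow(E))
  i <- sample.int(nrow(E), 1, prob = w)
  E[i, ]
}

#' One SKOA iteration
#'
#' Each member first explores toward the prey (x + C1 (P - x), C1 ~ U(0,2)
#' redrawn per member) and then exploits around it (p + C2 (x - p), with
#' C2 = 2 (1 - t / Tmax)); each move is accepted only if the candidate mask
#' improves fitness (greedy), positions are clipped to bounds, and the
#' elitist best is tracked.
#'
#' @param state a \code{SKOAState}.
#' @param X,y training features and labels.
#' @param fitnessFn fitness function (mask, X, y) -> accuracy.
#' @param preyFn prey-selection function (state) -> position; default the
#'   Smoluchowski kernel, the plain-KOA baseline passes the incumbent best.
#' @return updated state.
#' @export
skoaStep <- function(state, X, y, fitnessFn = skoaFitness,
                     preyFn = smoluchowskiSelectPrey) {
  a <- nrow(state$E)
  state$t <- state$t + 1L
  C2 <- 2 * (1 - state$t / state$Tmax)
  prey <- preyFn(state)
  clip <- function(x) pmin(pmax(x, state$lb), state$ub)
  for (i in seq_len(a)) {
    xi <- state$E[i, ]
    C1 <- runif(1, 0, 2)
    cand <- clip(xi + C1 * (prey - xi))
    f <- fitnessFn(binarizeMask(cand), X, y)
    if (f > state$fitness[i]) { state$E[i, ] <- cand; state$fitness[i] <- f }
    xi <- state$E[i, ]
    cand <- clip(prey + C2 * (xi - prey))
    f <- fitnessFn(binarizeMask(cand), X, y)
    if (f > state$fitness[i]) { state$E[i, ] <- cand; state$fitness[i] <- f }
    if (state$fitness[i] > state$bestFitness) {
      state$bestFitness <- state$fitness[i]
      state$best <- state$E[i, ]
    }
  }
  state
}

#' Run SKOA wrapper feature selection
#'
#' @param X training feature matrix.
#' @param y binary labels (0/1).
#' @param a population size.
#' @param Tmax iteration budget (>= 1).
#' @param seed integer seed (required).
#' @param plainKOA if TRUE, uses the plain kookaburra baseline: the prey is
#'   the incumbent global best (no Smoluchowski diffusion kernel).
#' @param fitnessFn fitness function.
#' @return list: \code{mask} (logical), \code{bestFitness}, \code{trace}
#'   (per-iteration best fitness, monotone non-decreasing), \code{selected}
#'   (column indices).
#' @export
skoaRun <- function(X, y, a = 30, Tmax = 50, seed, plainKOA = FALSE,
                    fitnessFn = skoaFitness) {
  stopifnot(Tmax >= 1)
  if (missing(seed)) stop("seed is required")
  state <- skoaInitialize(a = a, k = ncol(X), seed = seed)
  state$Tmax <- as.integer(Tmax)
  for (i in seq_len(a)) {
    state$fitness[i] <- fitnessFn(binarizeMask(state$E[i, ]), X, y)
  }
  ib <- which.max(state$fitness)
  state$best <- state$E[ib, ]; state$bestFitness <- state$fitness[ib]
  trace <- numeric(Tmax)
  preyFn <- if (plainKOA) function(s) s$best else smoluchowskiSelectPrey
  for (t in seq_len(Tmax)) {
    state <- skoaStep(state, X, y, fitnessFn = fitnessFn, preyFn = preyFn)
    trace[t] <- state$bestFitness
  }
  mask <- binarizeMask(state$best)
  list(mask = mask, bestFitness = state$bestFitness, trace = trace,
       selected = which(mask))
}

#' Mean pairwise Jaccard stability of fold masks
#'
#' @param masks list of equal-length logical masks (>= 2).
#' @return mean over unordered pairs of |intersection| / |union|; a pair of
#'   two empty masks counts as 1.
#' @export
jaccardStability <- function(masks) {
  stopifnot(length(masks) >= 2)
  n <- length(masks)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    u <- sum(masks[[i]] | masks[[j]])
    v <- if (u == 0) 1 else sum(masks[[i]] & masks[[j]]) / u
    vals <- c(vals, v)
  }
  mean(vals)
}

#' Feature-space retention rate
#'
#' @param meanSelected mean number of retained features per fold.
#' @param totalFeatures full feature-space width.
#' @return percentage retained (two decimals, half-up).
#' @export
retentionRate <- function(meanSelected, totalFeatures) {
  roundHalfUp(100 * meanSelected / totalFeatures, 2)
}
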