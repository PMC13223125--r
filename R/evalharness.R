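#' Stratified k-fold plan
#'
#' Shuffles each class under the seed and deals samples round-robin, so
#' per-fold class counts differ from proportional allocation by at most one.
#'
#' @param labels binary label vector.
#' @param n number of folds (default 10).
#' @param seed integer seed.
#' @return integer fold assignment (1..n) per sample.
#' @export
makeFolds <- function(labels, n = 10, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < n) {
      stop("class '", cls, "' has fewer samples (", length(idx),
           ") than folds (", n, ")")
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(n), length(idx))
  }
  fold
}

#' Area under the ROC curve (rank formula)
#' @param scores continuous scores.
#' @param y binary labels (0/1).
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Area under the precision-recall curve (step interpolation)
#' @inheritParams aurocScore
#' @return AUPRC in [0, 1].
#' @export
auprcScore <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  y <- y[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  prec <- tp / (tp + fp); rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

classifierMetrics <- function(scores, y, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  cm <- confusionMetrics(tp, fp, tn, fn)
  prec <- cm$ppv; rec <- cm$sensitivity
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  c(accuracy = cm$accuracy, precision = prec, recall = rec, f1 = f1,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    ppv = cm$ppv, npv = cm$npv,
    auroc = aurocScore(scores, y), auprc = auprcScore(scores, y))
}

#' Per-cell-line structural event summaries
#'
#' Runs the window/event detectors on each cell line's variant sequences
#' against the gene references and summarizes counts per event type plus
#' the total segment count (the tree-stage summary features). Results are
#' computed once per cohort and can be reused across folds and ablation
#' variants (the detectors have no fitted state).
#'
#' @param cohort a \linkS4class{CdrCohort} with sequences.
#' @param Lw,Sw,kMin detector parameters.
#' @return matrix (cell lines x 6) of event counts.
#' @export
cellLineEventSummaries <- function(cohort, Lw = 40, Sw = 20, kMin = 4) {
  vocab <- c("insertion", "deletion", "inversion", "mirror", "duplication")
  lines <- cellLineIds(cohort)
  out <- matrix(0, length(lines), 6,
                dimnames = list(lines, c(vocab, "n_segments")))
  refs <- as.character(cohort@refSequences)
  for (ln in lines) {
    vs <- cohort@variantSequences[[ln]]
    if (is.null(vs) || length(vs) == 0) next
    for (g in names(vs)) {
      if (!g %in% names(refs)) next
      ev <- detectGeneEvents(as.character(vs[[g]]), refs[[g]],
                             Lw = Lw, Sw = Sw, kMin = kMin)
      if (nrow(ev) > 0) {
        tab <- table(factor(ev$event, levels = vocab))
        out[ln, vocab] <- out[ln, vocab] + as.numeric(tab)
        out[ln, "n_segments"] <- out[ln, "n_segments"] + nrow(ev)
      }
    }
  }
  out
}

#' Assemble per-pair attribute features
#'
#' For every response pair: the cell line's expression profile, its binary
#' mutation calls, drug structural descriptors with cell-line context
#' (target-match fraction and mean target expression), and optionally the
#' per-line structural event summaries.
#'
#' @param cohort a labeled \linkS4class{CdrCohort}.
#' @param withDrugStructure include drug descriptor columns.
#' @param eventSummaries optional matrix from
#'   \code{\link{cellLineEventSummaries}} (NULL to omit the block).
#' @return list: \code{X} (raw, unstandardized), \code{y} (0/1),
#'   \code{pairKeys}, \code{featureGeneMap} (feature -> gene for SHAP
#'   aggregation), \code{provenance}.
#' @export
buildPairFeatures <- function(cohort, withDrugStructure = TRUE,
                              eventSummaries = NULL) {
  rt <- as.data.frame(cohort@responseTable)
  expr <- omicsBlock(cohort, "expression")
  mut <- omicsBlock(cohort, "mutation")
  genes <- rownames(expr)
  dt <- as.data.frame(cohort@drugTable)

  Xe <- t(expr[, rt$cell_line_id, drop = FALSE])
  colnames(Xe) <- paste0("expr.", genes)
  Xm <- t(mut[, rt$cell_line_id, drop = FALSE])
  colnames(Xm) <- paste0("mut.", genes)
  X <- cbind(Xe, Xm)

  if (withDrugStructure) {
    mols <- list(); desc0 <- list()
    for (i in seq_len(nrow(dt))) {
      mols[[dt$id[i]]] <- parseStructure(dt$smiles[i], dt$inchi[i], dt$id[i])
    }
    tgl <- strsplit(dt$targets, ";", fixed = TRUE)
    names(tgl) <- dt$id
    dd <- matrix(0, nrow(rt), 13)
    for (r in seq_len(nrow(rt))) {
      ln <- rt$cell_line_id[r]; dr <- rt$drug_id[r]
      altered <- genes[mut[, ln] == 1]
      ev <- drugDescriptors(mols[[dr]], targets = tgl[[dr]],
                            alteredGenes = altered,
                            targetExpression = expr[, ln],
                            cytotoxicityIndex = 0)
      dd[r, ] <- ev
      if (r == 1) colnames(dd) <- paste0("drug.", names(ev))
    }
    X <- cbind(X, dd)
  }
  if (!is.null(eventSummaries)) {
    es <- eventSummaries[rt$cell_line_id, , drop = FALSE]
    colnames(es) <- paste0("mnja.", colnames(es))
    X <- cbind(X, es)
  }
  pairKeys <- paste(rt$cell_line_id, rt$drug_id, sep = "::")
  rownames(X) <- pairKeys
  fmap <- rep(NA_character_, ncol(X))
  names(fmap) <- colnames(X)
  fmap[paste0("expr.", genes)] <- genes
  fmap[paste0("mut.", genes)] <- genes
  list(X = X, y = as.integer(rt$label == "sensitive"), pairKeys = pairKeys,
       featureGeneMap = fmap,
       provenance = ifelse(grepl("^drug\\.", colnames(X)), "drug-descriptor",
                    ifelse(grepl("^mnja\\.", colnames(X)), "mnja",
                           "attribute")))
}

#' Per-pair fused-tensor deep and handcrafted feature blocks
#'
#' For each cell line, detected segments are organised into a
#' neighbor-joining segment tree whose patristic map plus the event
#' indicator channel form the cellular channels; each drug contributes its
#' rasterised depiction. Per pair the three channels are fused and passed
#' through the deep extractor; handcrafted texture descriptors (GLCM + LBP
#' on the tree map, GLCM + LBP + local tetra patterns on the depiction) are
#' computed per entity and joined per pair. Cell lines without detected
#' segments get zero maps.
#'
#' @param cohort a labeled \linkS4class{CdrCohort} with sequences.
#' @param cnnParams from \code{\link{dscnnInit}} (fixes seed and size).
#' @param Lw,Sw,kMin detector parameters.
#' @return list with matrices \code{deep} and \code{handcrafted} (rows =
#'   pair keys, aligned with \code{\link{buildPairFeatures}}).
#' @export
buildTensorFeatures <- function(cohort, cnnParams, Lw = 40, Sw = 20,
                                kMin = 4) {
  size <- cnnParams$config$inputSize
  rt <- as.data.frame(cohort@responseTable)
  refs <- as.character(cohort@refSequences)
  lines <- cellLineIds(cohort)
  dt <- as.data.frame(cohort@drugTable)

  lineMaps <- list(); lineHand <- list()
  for (ln in lines) {
    vs <- cohort@variantSequences[[ln]]
    segs <- NULL
    if (!is.null(vs) && length(vs) > 0) {
      for (g in intersect(names(vs), names(refs))) {
        ev <- detectGeneEvents(as.character(vs[[g]]), refs[[g]],
                               Lw = Lw, Sw = Sw, kMin = kMin)
        if (nrow(ev) > 0) segs <- rbind(segs, ev)
      }
    }
    if (!is.null(segs) && nrow(segs) >= 2) {
      if (nrow(segs) > size) segs <- segs[seq_len(size), , drop = FALSE]
      desc <- segmentDescriptors(segs)
      tree <- mnjaBuildTree(desc, labels = paste0("s", seq_len(nrow(segs))))
      tmap <- treeToMap(tree, size = size)
      ord <- as.integer(sub("^s", "", attr(tmap, "leafOrder")))
      emap <- makeEventMap(segs$event[ord], size = size)
    } else {
      tmap <- matrix(0, size, size)
      emap <- matrix(0, size, size)
    }
    lineMaps[[ln]] <- list(tree = tmap, event = emap)
    lineHand[[ln]] <- c(glcmFeatures(tmap), lbpFeatures(tmap))
  }
  drugMaps <- list(); drugHand <- list()
  for (i in seq_len(nrow(dt))) {
    mol <- parseStructure(dt$smiles[i], dt$inchi[i], dt$id[i])
    dep <- renderDepiction(mol, size = size)
    drugMaps[[dt$id[i]]] <- dep
    drugHand[[dt$id[i]]] <- c(glcmFeatures(dep), lbpFeatures(dep),
                              ltrpFeatures(dep))
  }
  pairKeys <- paste(rt$cell_line_id, rt$drug_id, sep = "::")
  deep <- matrix(0, nrow(rt), cnnParams$config$penultimate,
                 dimnames = list(pairKeys,
                                 paste0("deep", seq_len(
                                   cnnParams$config$penultimate))))
  nh <- length(lineHand[[1]]) + length(drugHand[[1]])
  hand <- matrix(0, nrow(rt), nh, dimnames = list(pairKeys, NULL))
  for (r in seq_len(nrow(rt))) {
    lm <- lineMaps[[rt$cell_line_id[r]]]
    tensor <- fuseTensor(lm$tree, lm$event, drugMaps[[rt$drug_id[r]]])
    deep[r, ] <- as.numeric(dscnnFeatures(tensor, cnnParams))
    hand[r, ] <- c(lineHand[[rt$cell_line_id[r]]],
                   drugHand[[rt$drug_id[r]]])
  }
  colnames(hand) <- paste0("hand", seq_len(nh))
  list(deep = deep, handcrafted = hand)
}

#' Default pipeline configuration
#'
#' @param variant one of \code{"full"}, \code{"no_skoa"}, \code{"no_mnja"},
#'   \code{"no_drug_structure"}, \code{"non_graph_classifier"},
#'   \code{"no_aranda"}.
#' @param skoaA,skoaTmax SKOA population and iteration budget.
#' @param hidden,lambda EA-GAT width and Aranda shape.
#' @param epochs training epochs.
#' @param graphK correlation k-NN degree.
#' @param seed integer seed.
#' @return config list.
#' @export
pipelineConfig <- function(variant = "full", skoaA = 14, skoaTmax = 12,
                           hidden = 16, lambda = 2, epochs = 250,
                           graphK = 10, seed = 1) {
  variants <- c("full", "no_skoa", "no_mnja", "no_drug_structure",
                "non_graph_classifier", "no_aranda")
  if (!variant %in% variants) {
    stop("unknown variant '", variant, "'; valid: ",
         paste(variants, collapse = ", "))
  }
  list(variant = variant, skoaA = skoaA, skoaTmax = skoaTmax,
       hidden = hidden, lambda = lambda, epochs = epochs, graphK = graphK,
       seed = as.integer(seed))
}

#' Run one cross-validation fold of the pipeline
#'
#' Standardization, feature selection, graph construction and classifier
#' training are all fitted on training rows only, then applied to the held
#' out fold. With \code{sentinel = TRUE} the fit is repeated with poisoned
#' test rows (raw features scaled by 1e6) and every fitted statistic is
#' compared; any difference trips a hard failure.
#'
#' @param feats output of \code{\link{buildPairFeatures}} (raw features).
#' @param fold integer fold assignment from \code{\link{makeFolds}}.
#' @param testFold which fold is held out.
#' @param config from \code{\link{pipelineConfig}}.
#' @param sentinel run the leakage sentinel check.
#' @return list: per-fold \code{metrics}, test \code{scores}, \code{mask},
#'   fitted artifacts, \code{sentinelPass}.
#' @export
runFold <- function(feats, fold, testFold, config = pipelineConfig(),
                    sentinel = FALSE) {
  fitOnce <- function(Xraw) {
    testIdx <- which(fold == testFold)
    trainIdx <- which(fold != testFold)
    X <- Xraw
    if (config$variant == "no_drug_structure") {
      X <- X[, !grepl("^drug\\.", colnames(X)), drop = FALSE]
    }
    if (config$variant == "no_mnja") {
      X <- X[, !grepl("^mnja\\.", colnames(X)), drop = FALSE]
    }
    asm <- assembleFeatures(deep = NULL, handcrafted = NULL, attributes = X,
                            trainIdx = trainIdx)
    Xs <- asm$X
    y <- feats$y
    if (config$variant == "no_skoa") {
      mask <- rep(TRUE, ncol(Xs))
      sel <- list(mask = mask, trace = numeric(0))
    } else {
      sel <- skoaRun(Xs[trainIdx, , drop = FALSE], y[trainIdx],
                     a = config$skoaA, Tmax = config$skoaTmax,
                     seed = config$seed + testFold)
      mask <- sel$mask
    }
    Xsel <- Xs[, mask, drop = FALSE]
    if (config$variant == "non_graph_classifier") {
      model <- mlpTrain(Xsel[trainIdx, , drop = FALSE], y[trainIdx],
                        hidden = config$hidden, epochs = config$epochs,
                        seed = config$seed + testFold)
      graph <- NULL
      scores <- model$predictProb(Xsel[testIdx, , drop = FALSE])
      fitted <- list(center = asm$center, scale = asm$scale, mask = mask,
                     params = model$weights)
    } else {
      act <- if (config$variant == "no_aranda") "relu" else "aranda"
      graph <- buildFeatureGraph(Xsel[trainIdx, , drop = FALSE],
                                 k = config$graphK)
      model <- eagatTrain(Xsel[trainIdx, , drop = FALSE], y[trainIdx],
                          graph, hidden = config$hidden,
                          lambda = config$lambda, activation = act,
                          epochs = config$epochs,
                          seed = config$seed + testFold)
      scores <- eagatPredict(model, Xsel[testIdx, , drop = FALSE], graph)
      fitted <- list(center = asm$center, scale = asm$scale, mask = mask,
                     params = model[c("gamma", "delta", "w", "b", "aAlpha",
                                      "aBeta", "Wo", "bo")])
    }
    list(scores = scores, y = y[testIdx], mask = mask, fitted = fitted,
         graph = graph, model = model, Xsel = Xsel, trainIdx = trainIdx,
         testIdx = testIdx, trace = sel$trace)
  }
  res <- fitOnce(feats$X)
  sentinelPass <- NA
  if (sentinel) {
    Xp <- feats$X
    Xp[fold == testFold, ] <- Xp[fold == testFold, , drop = FALSE] * 1e6
    res2 <- fitOnce(Xp)
    sentinelPass <- isTRUE(all.equal(res$fitted, res2$fitted,
                                     tolerance = 0)) ||
      identical(res$fitted, res2$fitted)
    if (!sentinelPass) stop("leakage sentinel tripped: fitted statistics ",
                            "changed when test rows were poisoned")
  }
  list(metrics = classifierMetrics(res$scores, res$y),
       scores = res$scores, yTest = res$y, mask = res$mask,
       fitted = res$fitted, graph = res$graph, model = res$model,
       Xsel = res$Xsel, trainIdx = res$trainIdx, testIdx = res$testIdx,
       trace = res$trace, sentinelPass = sentinelPass)
}

#' Cross-validated pipeline evaluation
#'
#' @param feats from \code{\link{buildPairFeatures}}.
#' @param config from \code{\link{pipelineConfig}}.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed (fold plan + per-fold fits).
#' @param folds optional precomputed fold assignment (shared across
#'   ablation variants).
#' @return list of class \code{MetricsReport}: per-fold metric matrix,
#'   mean/sd rows, pooled AUROC/AUPRC, selection stability, variant tag.
#' @export
runCrossValidation <- function(feats, config = pipelineConfig(),
                               nFolds = 10, seed = 1, folds = NULL) {
  if (is.null(folds)) folds <- makeFolds(feats$y, n = nFolds, seed = seed)
  ids <- sort(unique(folds))
  perFold <- NULL
  masks <- list()
  pooledScores <- numeric(0); pooledY <- integer(0)
  for (f in ids) {
    r <- runFold(feats, folds, f, config)
    perFold <- rbind(perFold, r$metrics)
    masks[[f]] <- r$mask
    pooledScores <- c(pooledScores, r$scores)
    pooledY <- c(pooledY, r$yTest)
  }
  rownames(perFold) <- paste0("fold", ids)
  structure(list(
    variant = config$variant,
    perFold = perFold,
    mean = colMeans(perFold, na.rm = TRUE),
    sd = apply(perFold, 2, stats::sd, na.rm = TRUE),
    pooled = c(auroc = aurocScore(pooledScores, pooledY),
               auprc = auprcScore(pooledScores, pooledY)),
    stability = if (length(masks) >= 2) jaccardStability(masks) else NA,
    meanSelected = mean(vapply(masks, sum, 0)),
    folds = folds), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport [", x$variant, "] over", nrow(x$perFold), "folds\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  }
  cat(sprintf("  pooled AUROC %.4f, AUPRC %.4f; selection stability %.3f; mean selected %.1f\n",
              x$pooled["auroc"], x$pooled["auprc"], x$stability,
              x$meanSelected))
  invisible(x)
}

#' Run ablation variants on a shared fold plan
#'
#' @param feats from \code{\link{buildPairFeatures}} (with all blocks; each
#'   variant drops what it ablates).
#' @param variants character vector of variant names.
#' @param nFolds,seed as in \code{\link{runCrossValidation}}.
#' @param config base config (variant field is overridden).
#' @return named list of \code{MetricsReport}s, all sharing one fold plan.
#' @export
runAblation <- function(feats, variants = c("full", "no_skoa", "no_mnja",
                                            "no_drug_structure",
                                            "non_graph_classifier",
                                            "no_aranda"),
                        nFolds = 5, seed = 1, config = pipelineConfig()) {
  folds <- makeFolds(feats$y, n = nFolds, seed = seed)
  out <- list()
  for (v in variants) {
    cfg <- config
    cfg$variant <- pipelineConfig(variant = v)$variant
    out[[v]] <- runCrossValidation(feats, cfg, nFolds = nFolds, seed = seed,
                                   folds = folds)
  }
  out
}
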