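#' @importFrom stats cor coef predict aggregate
#' @importFrom utils combn
NULL

#' Four-parameter logistic viability curve
#'
#' \code{v(c) = B + (T - B) / (1 + (c / IC50)^(-h))} with the top asymptote
#' fixed at \code{T = 100}. The Hill slope \code{h} follows the
#' decreasing-curve sign convention (negative for viability that falls with
#' concentration), so \code{c -> 0} gives \code{v -> 100} and \code{v(IC50)
#' = (100 + B) / 2}.
#'
#' @param conc concentrations (uM, > 0).
#' @param ic50 half-maximal concentration (uM).
#' @param hill Hill slope (negative for a decreasing curve).
#' @param bottom bottom asymptote in [0, 100].
#' @param top top asymptote (fixed default 100).
#' @return viability percentages.
#' @export
fourPL <- function(conc, ic50, hill, bottom = 0, top = 100) {
  bottom + (top - bottom) / (1 + (conc / ic50)^(-hill))
}

#' Fit a 4PL dose-response curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with the top fixed at 100
#' and the bottom constrained to [0, 100]; multi-start over log-spaced IC50
#' initial values. Viability should be normalized to vehicle = 100.
#'
#' @param concentrations_uM >= 4 distinct positive concentrations.
#' @param viability_pct viability percentages (same length).
#' @return list of class \code{DoseResponseFit}: \code{ic50_uM},
#'   \code{hill}, \code{bottom}, \code{top}, \code{r_squared},
#'   \code{normalized_auc}, \code{converged}, \code{degenerate}.
#' @export
fit4PL <- function(concentrations_uM, viability_pct) {
  stopifnot(length(concentrations_uM) == length(viability_pct))
  if (length(unique(concentrations_uM)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  df <- data.frame(c = concentrations_uM, v = viability_pct)
  sstot <- sum((df$v - mean(df$v))^2)
  degenerate <- sstot < 1e-8

  best <- NULL; bestRss <- Inf
  if (!degenerate) {
    starts <- 10^seq(log10(min(df$c)), log10(max(df$c)), length.out = 7)
    for (s0 in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          v ~ B + (100 - B) / (1 + (c / ic50)^(-h)),
          data = df,
          start = list(B = max(min(df$v), 0), ic50 = s0, h = -1),
          lower = c(B = 0, ic50 = min(df$c) / 100, h = -10),
          upper = c(B = 100, ic50 = max(df$c) * 100, h = -0.01),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (rss < bestRss) { best <- fit; bestRss <- rss }
      }
    }
  }
  auc <- normalizedAUC(concentrations_uM, viability_pct)
  if (is.null(best)) {
    return(structure(list(ic50_uM = NA_real_, hill = NA_real_,
                          bottom = NA_real_, top = 100,
                          r_squared = NA_real_, normalized_auc = auc,
                          converged = FALSE, degenerate = degenerate),
                     class = "DoseResponseFit"))
  }
  cf <- coef(best)
  structure(list(ic50_uM = unname(cf["ic50"]), hill = unname(cf["h"]),
                 bottom = unname(cf["B"]), top = 100,
                 r_squared = 1 - bestRss / sstot,
                 normalized_auc = auc,
                 converged = TRUE, degenerate = FALSE),
            class = "DoseResponseFit")
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("4PL fit: IC50 = %.3g uM, hill = %.3g, bottom = %.3g, R2 = %.4f, AUC = %.3f\n",
                x$ic50_uM, x$hill, x$bottom, x$r_squared, x$normalized_auc))
  } else {
    cat(sprintf("4PL fit failed%s; normalized AUC = %.3f\n",
                if (x$degenerate) " (degenerate flat curve)" else "",
                x$normalized_auc))
  }
  invisible(x)
}

#' Normalized area under the viability curve
#'
#' Trapezoidal integral of viability/100 over log10-concentration, divided
#' by the log-concentration span. 1 = complete resistance, 0 = full
#' sensitivity. Replicate measurements at the same concentration are
#' averaged first.
#'
#' @param concentrations_uM positive concentrations (>= 2 distinct).
#' @param viability_pct matching viability percentages.
#' @return scalar in [0, 1] for curves within [0, 100].
#' @export
normalizedAUC <- function(concentrations_uM, viability_pct) {
  agg <- aggregate(list(v = viability_pct),
                   by = list(c = concentrations_uM), FUN = mean)
  agg <- agg[order(agg$c), ]
  if (nrow(agg) < 2) stop("need at least two distinct concentrations")
  x <- log10(agg$c); y <- agg$v / 100
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  area / (max(x) - min(x))
}

#' Exact Mann-Whitney U test
#'
#' \code{U = min(U1, U2)}; for group sizes <= 10 the two-sided p-value is
#' computed by full enumeration of group assignments, otherwise the normal
#' approximation is used.
#'
#' @param x,y numeric samples.
#' @return list(U, U1, U2, p_value, exact).
#' @export
mannWhitneyU <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  if (n1 <= 10 && n2 <= 10) {
    idx <- combn(n1 + n2, n1)
    v <- c(x, y)
    rk <- rank(v)
    Us <- apply(idx, 2, function(ii) {
      u1 <- sum(rk[ii]) - n1 * (n1 + 1) / 2
      min(u1, n1 * n2 - u1)
    })
    p <- mean(Us <= U + 1e-12)
    list(U = U, U1 = U1, U2 = U2, p_value = p, exact = TRUE)
  } else {
    mu <- n1 * n2 / 2
    sd_ <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    z <- (U - mu) / sd_
    list(U = U, U1 = U1, U2 = U2,
         p_value = min(1, 2 * stats::pnorm(z)), exact = FALSE)
  }
}

#' Spearman rank correlation with exact permutation p for small n
#'
#' Average ranks for ties; exact two-sided permutation p-value for n <= 8,
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors.
#' @return list(rho, p_value, exact).
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (n <= 8) {
    perms <- permuteAll(n)
    rx <- rank(x)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, exact = TRUE)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    list(rho = rho, p_value = p, exact = FALSE)
  }
}

permuteAll <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permuteAll(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(sub + (sub >= i), i))
  }
  out
}

#' Confusion-table metrics
#'
#' @param tp,fp,tn,fn 2x2 confusion counts (positive = sensitive).
#' @return list of accuracy, sensitivity, specificity, ppv, npv, mcc
#'   (NA where undefined).
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(accuracy = sdiv(tp + tn, tp + fp + tn + fn),
       sensitivity = sdiv(tp, tp + fn),
       specificity = sdiv(tn, tn + fp),
       ppv = sdiv(tp, tp + fp),
       npv = sdiv(tn, tn + fn),
       mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / den)
}

#' Agreement between model sensitivity scores and measured response
#'
#' Binarizes continuous model scores at \code{score_threshold} (predicted
#' sensitive above it) and IC50s at \code{ic50_threshold_uM} (experimentally
#' sensitive strictly below it), then reports confusion metrics, Spearman
#' rank correlations of score vs IC50 and vs normalized AUC, the
#' Mann-Whitney U test of IC50 between predicted groups, and group mean
#' IC50s.
#'
#' @param scores continuous sensitivity scores in [0, 1].
#' @param ic50s measured IC50s (uM).
#' @param aucs optional normalized AUCs.
#' @param score_threshold predicted-sensitive cut (default 0.5).
#' @param ic50_threshold_uM label cut (default 1 uM).
#' @return list of class \code{AgreementReport}.
#' @export
agreementReport <- function(scores, ic50s, aucs = NULL,
                            score_threshold = 0.5, ic50_threshold_uM = 1.0) {
  stopifnot(length(scores) == length(ic50s), length(scores) >= 3)
  predSens <- scores > score_threshold
  actSens <- ic50s < ic50_threshold_uM
  tp <- sum(predSens & actSens); fp <- sum(predSens & !actSens)
  tn <- sum(!predSens & !actSens); fn <- sum(!predSens & actSens)
  cm <- confusionMetrics(tp, fp, tn, fn)
  sp_ic <- spearmanRho(scores, ic50s)
  sp_auc <- if (!is.null(aucs)) spearmanRho(scores, aucs) else NULL
  mw <- if (any(predSens) && any(!predSens)) {
    mannWhitneyU(ic50s[predSens], ic50s[!predSens])
  } else NULL
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    metrics = cm,
    spearman_ic50 = sp_ic,
    spearman_auc = sp_auc,
    mann_whitney = mw,
    mean_ic50_predicted_sensitive = mean(ic50s[predSens]),
    mean_ic50_predicted_resistant = mean(ic50s[!predSens]),
    n = length(scores)), class = "AgreementReport")
}

#' @export
print.AgreementReport <- function(x, ...) {
  cm <- x$metrics
  cat(sprintf("Agreement over %d pairs: accuracy %.1f%% (TP=%d FP=%d TN=%d FN=%d)\n",
              x$n, 100 * cm$accuracy, x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%, MCC %.3f\n",
              100 * cm$sensitivity, 100 * cm$specificity, 100 * cm$ppv,
              100 * cm$npv, cm$mcc))
  cat(sprintf("  Spearman rho(score, IC50) = %.3f (p = %.3g)\n",
              x$spearman_ic50$rho, x$spearman_ic50$p_value))
  if (!is.null(x$mann_whitney)) {
    cat(sprintf("  Mann-Whitney U = %g (p = %.3g); group mean IC50: sens %.3g, res %.3g uM\n",
                x$mann_whitney$U, x$mann_whitney$p_value,
                x$mean_ic50_predicted_sensitive,
                x$mean_ic50_predicted_resistant))
  }
  invisible(x)
}
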