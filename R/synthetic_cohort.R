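#' @importFrom stats rnorm runif rbinom quantile setNames
NULL

# ~20 small valid organic SMILES used as the embedded synthetic drug set
.syntheticSmiles <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "c1ccccc1O", "CC(=O)Nc1ccc(O)cc1",
  "CCN(CC)CC", "C1CCCCC1", "c1ccncc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "CN1CCC[C@H]1c1cccnc1", "Cc1ccccc1N", "OCC(O)CO", "CC(=O)OC1CCCCC1",
  "Nc1ncnc2[nH]cnc12", "OC(=O)c1ccccc1O", "CCOC(=O)c1ccccc1",
  "CSCC(N)C(=O)O", "NCCc1ccc(O)c(O)c1", "CC(N)Cc1ccccc1", "OCCN1CCOCC1")

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic benchmark: cohort size,
#' signal architecture and noise. Defaults give a 100-line x 10-drug cohort
#' (1,000 pairs) with 10 planted causal genes, a strong effect and moderate
#' noise, the conditions under which planted signal is recoverable by the
#' downstream pipeline.
#'
#' @param nCellLines,nGenes,nDrugs cohort dimensions (all >= 1).
#' @param prevalence target sensitive fraction in (0, 1).
#' @param effectSize positive scaling of the pathway-activity x drug-target
#'   interaction on log10(IC50).
#' @param noiseSd Gaussian noise sd on log10(IC50).
#' @param plantedCausalGenes number of causal genes.
#' @param seed integer seed (required).
#' @param nSeqGenes how many genes get generated sequences.
#' @param seqLength reference sequence length (bp).
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(nCellLines = 100, nGenes = 100, nDrugs = 10,
                      prevalence = 0.5, effectSize = 2, noiseSd = 0.3,
                      plantedCausalGenes = 10, seed,
                      nSeqGenes = 12, seqLength = 300) {
  stopifnot(nCellLines >= 1, nGenes >= 1, nDrugs >= 1,
            prevalence > 0, prevalence < 1, effectSize >= 0, noiseSd >= 0,
            plantedCausalGenes >= 1, plantedCausalGenes <= nGenes)
  if (missing(seed)) stop("seed is required")
  structure(list(nCellLines = nCellLines, nGenes = nGenes, nDrugs = nDrugs,
                 prevalence = prevalence, effectSize = effectSize,
                 noiseSd = noiseSd, plantedCausalGenes = plantedCausalGenes,
                 seed = as.integer(seed), nSeqGenes = nSeqGenes,
                 seqLength = seqLength),
            class = "SimConfig")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic cohort with planted, recoverable signal
#'
#' Causal genes carry independent expression whose standardized mean is the
#' latent per-line pathway activity (so each causal gene contributes
#' non-redundant signal); log10(IC50) for pair (i, j) is
#' \code{mu0 - effectSize * activity_i * match_j + noise}, where
#' \code{match_j} in [0.4, 1] is the fraction of drug j's annotated targets
#' that are causal genes (every synthetic drug annotates at least one causal
#' target so that all pairs carry graded signal), and \code{mu0} is set so
#' that thresholding IC50 at 1 uM reproduces the configured prevalence.
#' Sequences are generated for \code{nSeqGenes} genes; cell lines with a
#' mutation call in a sequenced gene receive planted structural events.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{cohort} (a labeled, curated
#'   \linkS4class{CdrCohort}) and \code{truth} (causal gene ids, per-drug
#'   match scores, latent activities, planted events, coefficients).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nc <- config$nCellLines; ng <- config$nGenes; nd <- config$nDrugs
  genes <- sprintf("G%03d", seq_len(ng))
  lines <- sprintf("CL%03d", seq_len(nc))
  causal <- genes[seq_len(config$plantedCausalGenes)]

  # causal genes co-express through a shared pathway factor (rho) but each
  # also carries an independent component; the latent activity is the
  # standardized mean of the member genes, so the genes are realistically
  # correlated yet none is redundant
  rho <- 0.6
  expr <- matrix(rnorm(ng * nc), ng, nc, dimnames = list(genes, lines))
  z0 <- rnorm(nc)
  nCau <- length(causal)
  expr[causal, ] <- rho * matrix(z0, nCau, nc, byrow = TRUE) +
    sqrt(1 - rho^2) * matrix(rnorm(nCau * nc), nCau, nc)
  actRaw <- colMeans(expr[causal, , drop = FALSE])
  activity <- actRaw / sqrt(rho^2 + (1 - rho^2) / nCau)
  mut <- matrix(rbinom(ng * nc, 1, 0.15), ng, nc,
                dimnames = list(genes, lines))
  cnv <- matrix(rnorm(ng * nc, sd = 0.5), ng, nc,
                dimnames = list(genes, lines))

  # drugs: every drug targets >=1 causal gene; match = causal fraction
  smiles <- rep_len(.syntheticSmiles, nd)
  drugIds <- sprintf("D%02d", seq_len(nd))
  targets <- character(nd); matchScore <- numeric(nd)
  for (j in seq_len(nd)) {
    ntar <- sample(2:5, 1)
    ncau <- max(1L, round(runif(1, 0.4, 1) * ntar))
    ncau <- min(ncau, length(causal))
    tg <- c(sample(causal, ncau),
            if (ntar - ncau > 0) sample(setdiff(genes, causal), ntar - ncau))
    targets[j] <- paste(tg, collapse = ";")
    matchScore[j] <- ncau / ntar
  }
  drugs <- data.frame(id = drugIds, name = paste0("synth-", drugIds),
                      targets = targets, smiles = smiles,
                      inchi = "", stringsAsFactors = FALSE)

  pairs <- expand.grid(cell_line_id = lines, drug_id = drugIds,
                       stringsAsFactors = FALSE)
  a <- activity[match(pairs$cell_line_id, lines)]
  m <- matchScore[match(pairs$drug_id, drugIds)]
  s <- -config$effectSize * a * m + rnorm(nrow(pairs), sd = config$noiseSd)
  mu0 <- -unname(quantile(s, config$prevalence))
  log10ic <- mu0 + s
  pairs$ic50_uM <- 10^log10ic
  lab <- pairs$ic50_uM < 1
  if (all(lab) || !any(lab)) stop("degenerate config: single-class labels")

  # sequences + planted events for mutated sequenced genes
  nsg <- min(config$nSeqGenes, ng)
  seqGenes <- genes[seq_len(nsg)]  # includes causal genes first
  refs <- Biostrings::DNAStringSet(setNames(
    vapply(seqGenes, function(g) randomDna(config$seqLength), ""), seqGenes))
  eventTypes <- c("insertion", "deletion", "inversion", "mirror",
                  "duplication")
  variants <- list(); planted <- NULL
  for (i in seq_len(nc)) {
    vgenes <- seqGenes[mut[seqGenes, i] == 1]
    if (length(vgenes) == 0) next
    plan <- NULL
    for (g in vgenes) {
      ev <- sample(eventTypes, 1)
      len <- sample(8:12, 1)
      pos <- sample(seq(20, config$seqLength - 40), 1)
      plan <- rbind(plan, data.frame(gene = g, event = ev, pos = pos,
                                     len = len, stringsAsFactors = FALSE))
    }
    vs <- mutateSequences(refs[vgenes], plan)
    variants[[lines[i]]] <- vs
    plan$cell_line <- lines[i]
    planted <- rbind(planted, plan)
  }

  raw <- CdrCohort(
    profiles = SummarizedExperiment::SummarizedExperiment(
      assays = list(mutation = mut, cnv = cnv, expression = expr),
      colData = S4Vectors::DataFrame(
        lineage = sample(c("breast", "lung", "skin", "colon"), nc, TRUE),
        row.names = lines)),
    drugs = drugs, responses = pairs,
    refSequences = refs, variantSequences = variants)
  cohort <- assignLabels(curateCohort(raw))
  truth <- list(causal_gene_ids = causal,
                logistic_coefficients = setNames(
                  rep(config$effectSize, length(causal)), causal),
                drug_match = setNames(matchScore, drugIds),
                activity = setNames(activity, lines),
                planted_events = planted,
                mu0 = mu0)
  list(cohort = cohort, truth = truth)
}

#' Plant structural events into reference sequences
#'
#' Event plan rows are (gene, event, pos, len). Events within one gene must
#' not overlap (keeps the ground truth unambiguous). Events are applied
#' right-to-left so earlier coordinates stay valid. Construction: insertion
#' inserts a random subsequence at pos; deletion removes [pos, pos+len-1];
#' inversion reverses that range; mirror rewrites it as a palindrome
#' (first half mirrored); duplication repeats the range in place.
#'
#' @param references DNAStringSet keyed by gene.
#' @param plan data.frame with columns gene, event, pos, len.
#' @return DNAStringSet of mutated sequences (same names).
#' @export
mutateSequences <- function(references, plan) {
  seqs <- setNames(as.character(references), names(references))
  if (nrow(plan) == 0) return(Biostrings::DNAStringSet(seqs))
  stopifnot(all(plan$gene %in% names(seqs)))
  for (g in unique(plan$gene)) {
    pg <- plan[plan$gene == g, , drop = FALSE]
    pg <- pg[order(pg$pos, decreasing = TRUE), , drop = FALSE]
    iv <- cbind(pg$pos, pg$pos + pg$len - 1)
    if (nrow(iv) > 1) {
      o <- order(iv[, 1])
      if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)])) {
        stop("overlapping planted events in gene ", g)
      }
    }
    s <- seqs[[g]]
    for (r in seq_len(nrow(pg))) {
      pos <- pg$pos[r]; len <- pg$len[r]
      if (pos + len - 1 > nchar(s) && pg$event[r] != "insertion") {
        stop("event out of bounds in gene ", g)
      }
      pre <- substring(s, 1, pos - 1)
      mid <- substring(s, pos, pos + len - 1)
      post <- substring(s, pos + len, nchar(s))
      s <- switch(pg$event[r],
        insertion = paste0(pre, randomDna(len), mid, post),
        deletion = paste0(pre, post),
        inversion = paste0(pre, revString(mid), post),
        mirror = {
          h <- substring(mid, 1, ceiling(len / 2))
          pal <- paste0(h, revString(substring(h, 1, floor(len / 2))))
          paste0(pre, pal, post)
        },
        duplication = paste0(pre, mid, mid, post),
        stop("unknown event: ", pg$event[r]))
    }
    seqs[[g]] <- s
  }
  Biostrings::DNAStringSet(seqs)
}

#' Generate a synthetic dose-response plate
#'
#' Viabilities are four-parameter logistic evaluations (top fixed at 100)
#' plus Gaussian noise; noiseless at \code{noiseSd = 0}.
#'
#' @param ic50_uM true IC50 (uM, > 0).
#' @param hill Hill slope (negative for decreasing viability).
#' @param bottom bottom asymptote in [0, 100].
#' @param concentrations_uM positive, sorted concentration grid; default the
#'   seven-point series 0.01-10 uM.
#' @param reps technical replicates per concentration.
#' @param noiseSd Gaussian noise sd (percentage points).
#' @param seed integer seed.
#' @param cellLine label carried into the output.
#' @return long-format data.frame (cell_line, concentration_uM, replicate,
#'   viability_pct).
#' @export
generatePlate <- function(ic50_uM, hill, bottom = 0,
                          concentrations_uM = c(0.01, 0.032, 0.1, 0.32,
                                                1.0, 3.2, 10),
                          reps = 3, noiseSd = 0, seed = 1,
                          cellLine = "synthetic") {
  stopifnot(ic50_uM > 0, all(concentrations_uM > 0),
            !is.unsorted(concentrations_uM), bottom >= 0, bottom <= 100)
  set.seed(seed)
  out <- expand.grid(concentration_uM = concentrations_uM,
                     replicate = seq_len(reps))
  v <- fourPL(out$concentration_uM, ic50 = ic50_uM, hill = hill,
              bottom = bottom)
  out$viability_pct <- v + rnorm(nrow(out), sd = noiseSd)
  cbind(cell_line = cellLine, out)
}

#' Synthetic gene-set collection with one planted over-represented set
#'
#' Builds \code{nSets} gene sets over the cohort's gene universe; the first
#' set is the planted causal set (so enrichment of recovered causal genes is
#' testable end to end), the rest are random draws.
#'
#' @param truth ground-truth list from \code{\link{generateCohort}}.
#' @param universe character vector of all gene ids.
#' @param nSets number of sets.
#' @param setSize size of the random sets.
#' @param seed integer seed.
#' @return named list of character vectors (a GMT-style collection).
#' @export
generateGeneSets <- function(truth, universe, nSets = 20, setSize = 15,
                             seed = 1) {
  set.seed(seed)
  sets <- list(PLANTED_CAUSAL_PATHWAY = truth$causal_gene_ids)
  for (i in seq_len(nSets - 1)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sample(universe, min(setSize, length(universe)))
  }
  sets
}

#' Synthetic raw cohort reproducing a given curation bookkeeping
#'
#' Constructs a raw cohort whose three curation steps exclude exactly the
#' planted counts: \code{excl[1]} pairs with invalid IC50, \code{excl[2]}
#' pairs on cell lines with missing molecular profiles, and \code{excl[3]}
#' pairs on drugs without structures; the remainder are clean, with
#' \code{nSensitive} of them below 1 uM. Entities are laid out so the three
#' defect classes do not interact.
#'
#' @param nInitial total candidate pairs.
#' @param excl integer vector of three per-step exclusion counts.
#' @param nSensitive how many clean pairs get IC50 < 1 uM.
#' @param seed integer seed.
#' @return a raw (uncurated) \linkS4class{CdrCohort}.
#' @export
simulateCurationCohort <- function(nInitial = 8146,
                                   excl = c(854, 4179, 499),
                                   nSensitive = 1241, seed = 1) {
  stopifnot(length(excl) == 3, sum(excl) < nInitial)
  set.seed(seed)
  nClean <- nInitial - sum(excl)
  stopifnot(nSensitive <= nClean)

  # entity layout: profile-less lines only appear in step-2 pairs;
  # structure-less drugs only in step-3 pairs
  nGoodDrugs <- 70L
  nGoodLines <- max(ceiling((nClean + excl[1]) / (nGoodDrugs - 10)), 60)
  nBadDrugs <- max(1L, ceiling(excl[3] / nGoodLines))
  nBadLines <- max(1L, ceiling(excl[2] / (nBadDrugs + nGoodDrugs)))
  lines <- c(sprintf("BAD_CL%03d", seq_len(nBadLines)),
             sprintf("CL%04d", seq_len(nGoodLines)))
  drugs <- c(sprintf("BAD_D%02d", seq_len(nBadDrugs)),
             sprintf("D%03d", seq_len(nGoodDrugs)))

  pairGrid <- function(ls, ds, n) {
    g <- expand.grid(cell_line_id = ls, drug_id = ds,
                     stringsAsFactors = FALSE)
    stopifnot(nrow(g) >= n)
    g[seq_len(n), , drop = FALSE]
  }
  goodLines <- lines[-seq_len(nBadLines)]
  goodDrugs <- drugs[-seq_len(nBadDrugs)]
  p1 <- pairGrid(goodLines, goodDrugs, excl[1])          # invalid response
  p2 <- pairGrid(lines[seq_len(nBadLines)], drugs, excl[2])  # bad profile
  p3 <- pairGrid(rev(goodLines), drugs[seq_len(nBadDrugs)], excl[3])
  used <- paste(p1$cell_line_id, p1$drug_id)
  grid <- expand.grid(cell_line_id = goodLines, drug_id = goodDrugs,
                      stringsAsFactors = FALSE)
  grid <- grid[!paste(grid$cell_line_id, grid$drug_id) %in% used, ]
  p4 <- grid[seq_len(nClean), , drop = FALSE]

  p1$ic50_uM <- NA_real_
  p2$ic50_uM <- exp(rnorm(nrow(p2)))
  p3$ic50_uM <- exp(rnorm(nrow(p3)))
  ic <- c(runif(nSensitive, 0.05, 0.95), runif(nClean - nSensitive, 1.05, 20))
  p4$ic50_uM <- sample(ic)
  resp <- rbind(p1, p2, p3, p4)

  genes <- sprintf("G%02d", 1:5)
  mkBlock <- function() {
    m <- matrix(rnorm(length(genes) * length(lines)), length(genes),
                length(lines), dimnames = list(genes, lines))
    m[, seq_len(nBadLines)] <- NA  # profile-less lines
    m
  }
  mut <- mkBlock(); mut[!is.na(mut)] <- rbinom(sum(!is.na(mut)), 1, 0.2)
  drugTab <- data.frame(
    id = drugs, name = drugs,
    targets = "G01",
    smiles = c(rep("", nBadDrugs),
               rep_len(.syntheticSmiles, nGoodDrugs)),
    inchi = "", stringsAsFactors = FALSE)
  CdrCohort(
    profiles = list(mutation = mut, cnv = mkBlock(), expression = mkBlock()),
    drugs = drugTab, responses = resp)
}

#' Write a gene-set collection as a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#' @param path GMT path (tab-separated: name, description, genes...).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}
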