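#' @importFrom utils read.csv write.csv head tail
NULL

roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Curate a raw cohort
#'
#' Applies the three standard exclusion steps, in order: (1) pairs with a
#' missing or non-positive IC50 ("invalid response"); (2) pairs whose cell
#' line lacks a required omics block entirely (mutation, CNV or expression
#' all-missing; the optional protein block never triggers exclusion);
#' (3) pairs whose drug has neither SMILES nor InChI. Each step is appended
#' to the curation log with retained/excluded counts that telescope.
#'
#' @param raw A \linkS4class{CdrCohort}, possibly with incomplete records.
#' @return A curated \linkS4class{CdrCohort} containing only fully matched
#'   pairs, with a populated curation log.
#' @export
curateCohort <- function(raw) {
  stopifnot(is(raw, "CdrCohort"))
  rt <- as.data.frame(raw@responseTable)
  n0 <- nrow(rt)
  log <- data.frame(step = "initial", retained = n0, excluded = NA_integer_,
                    reason = "candidate cell line-drug pairs",
                    stringsAsFactors = FALSE)

  # step 1: invalid response
  ok1 <- !is.na(rt$ic50_uM) & rt$ic50_uM > 0
  rt <- rt[ok1, , drop = FALSE]
  log <- rbind(log, data.frame(
    step = "invalid_response", retained = nrow(rt),
    excluded = n0 - nrow(rt),
    reason = "no usable IC50 or invalid response summary"))

  # step 2: incomplete molecular profile (any required block all-NA for line)
  required <- c("mutation", "cnv", "expression")
  an <- SummarizedExperiment::assayNames(raw@profiles)
  complete <- rep(TRUE, ncol(raw@profiles))
  names(complete) <- colnames(raw@profiles)
  for (blk in required) {
    if (blk %in% an) {
      m <- SummarizedExperiment::assay(raw@profiles, blk)
      complete <- complete & !apply(m, 2, function(col) all(is.na(col)))
    } else {
      complete[] <- FALSE
    }
  }
  n1 <- nrow(rt)
  rt <- rt[complete[rt$cell_line_id], , drop = FALSE]
  log <- rbind(log, data.frame(
    step = "incomplete_profile", retained = nrow(rt),
    excluded = n1 - nrow(rt),
    reason = "missing required molecular feature information"))

  # step 3: no usable drug structure
  dt <- as.data.frame(raw@drugTable)
  hasStruct <- !(is.na(dt$smiles) | dt$smiles == "") |
               !(is.na(dt$inchi) | dt$inchi == "")
  names(hasStruct) <- dt$id
  n2 <- nrow(rt)
  rt <- rt[hasStruct[rt$drug_id], , drop = FALSE]
  log <- rbind(log, data.frame(
    step = "no_drug_structure", retained = nrow(rt),
    excluded = n2 - nrow(rt),
    reason = "missing or unusable structural representation fields"))

  if (nrow(rt) == 0) stop("empty cohort after curation")

  keepLines <- unique(rt$cell_line_id)
  keepDrugs <- unique(rt$drug_id)
  vs <- raw@variantSequences[names(raw@variantSequences) %in% keepLines]
  CdrCohort(
    profiles = raw@profiles[, keepLines],
    drugs = raw@drugTable[raw@drugTable$id %in% keepDrugs, , drop = FALSE],
    responses = rt,
    curationLog = log,
    refSequences = raw@refSequences,
    variantSequences = vs)
}

#' Assign binary sensitivity labels from IC50
#'
#' A pair is labeled \code{"sensitive"} iff its IC50 is strictly below the
#' threshold (default 1 uM), otherwise \code{"resistant"}.
#'
#' @param cohort A curated \linkS4class{CdrCohort}.
#' @param threshold_uM positive IC50 threshold in micromolar.
#' @return The cohort with labels filled in.
#' @export
assignLabels <- function(cohort, threshold_uM = 1.0) {
  stopifnot(threshold_uM > 0)
  rt <- cohort@responseTable
  if (any(is.na(rt$ic50_uM))) {
    stop("missing IC50 on a curated record; curation contract violated")
  }
  rt$label <- ifelse(rt$ic50_uM < threshold_uM, "sensitive", "resistant")
  cohort@responseTable <- rt
  cohort
}

#' Label balance summary
#'
#' @param cohort A labeled \linkS4class{CdrCohort}.
#' @return data.frame with per-label counts and percentages (two decimals,
#'   half-up rounding).
#' @export
classBalance <- function(cohort) {
  lab <- cohort@responseTable$label
  if (any(is.na(lab))) stop("all labels must be assigned")
  n <- length(lab)
  lv <- c("sensitive", "resistant")
  cnt <- vapply(lv, function(l) sum(lab == l), integer(1))
  data.frame(label = lv, count = as.integer(cnt),
             percent = roundHalfUp(100 * cnt / n, 2),
             row.names = NULL)
}

#' Read a cohort from a directory of CSV/FASTA files
#'
#' Expects \code{responses.csv} (cell_line_id, drug_id, ic50, optional label),
#' \code{cell_lines.csv} (id, lineage, optional subtype),
#' \code{drugs.csv} (id, name, targets, smiles, inchi),
#' one wide CSV per omics block (\code{mutation.csv}, \code{cnv.csv},
#' \code{expression.csv}, optional \code{protein.csv}; genes x cell lines),
#' and optionally \code{reference.fasta} plus \code{variants_<line>.fasta}.
#'
#' @param dir directory path.
#' @param ic50_units units of the response column: \code{"uM"} (default),
#'   \code{"M"} (converted x 1e6) or \code{"ln_uM"} (natural log of uM,
#'   exponentiated).
#' @return A \linkS4class{CdrCohort}.
#' @export
readCohort <- function(dir, ic50_units = c("uM", "M", "ln_uM")) {
  ic50_units <- match.arg(ic50_units)
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                             check.names = FALSE)
  resp <- rd("responses.csv")
  cls <- rd("cell_lines.csv")
  drugs <- rd("drugs.csv")
  for (col in c("id", "name", "targets", "smiles", "inchi")) {
    if (col %in% colnames(drugs)) {
      v <- as.character(drugs[[col]])
      v[is.na(v)] <- ""
      drugs[[col]] <- v
    }
  }
  ic50 <- resp$ic50_uM
  ic50 <- switch(ic50_units, uM = ic50, M = ic50 * 1e6, ln_uM = exp(ic50))
  resp$ic50_uM <- ic50

  blocks <- list()
  for (blk in c("mutation", "cnv", "expression", "protein")) {
    f <- file.path(dir, paste0(blk, ".csv"))
    if (file.exists(f)) {
      w <- read.csv(f, row.names = 1, check.names = FALSE)
      blocks[[blk]] <- as.matrix(w)
    }
  }
  stopifnot(length(blocks) > 0)
  genes <- rownames(blocks[[1]])
  blocks <- lapply(blocks, function(m) m[genes, cls$id, drop = FALSE])
  cd <- S4Vectors::DataFrame(cls[, setdiff(colnames(cls), "id"), drop = FALSE],
                             row.names = cls$id)
  se <- SummarizedExperiment::SummarizedExperiment(assays = blocks,
                                                   colData = cd)

  refs <- Biostrings::DNAStringSet()
  rf <- file.path(dir, "reference.fasta")
  if (file.exists(rf)) refs <- Biostrings::readDNAStringSet(rf)
  vfiles <- list.files(dir, pattern = "^variants_.*\\.fasta$")
  vs <- list()
  for (vf in vfiles) {
    line <- sub("^variants_(.*)\\.fasta$", "\\1", vf)
    vs[[line]] <- Biostrings::readDNAStringSet(file.path(dir, vf))
  }
  lg <- file.path(dir, "curation_log.csv")
  clog <- if (file.exists(lg)) read.csv(lg, stringsAsFactors = FALSE) else
    data.frame(step = character(), retained = integer(),
               excluded = integer(), reason = character())
  CdrCohort(profiles = se, drugs = drugs, responses = resp,
            curationLog = clog, refSequences = refs, variantSequences = vs)
}

#' Write a cohort to a directory
#'
#' Emits the same file dialect consumed by \code{\link{readCohort}}; the
#' curation log mirrors the audit-table columns (step, retained, excluded,
#' reason).
#'
#' @param cohort A \linkS4class{CdrCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(as.data.frame(cohort@responseTable), "responses.csv")
  cd <- as.data.frame(SummarizedExperiment::colData(cohort@profiles))
  cd <- cbind(id = colnames(cohort@profiles), cd)
  wr(cd, "cell_lines.csv")
  wr(as.data.frame(cohort@drugTable), "drugs.csv")
  for (blk in SummarizedExperiment::assayNames(cohort@profiles)) {
    m <- SummarizedExperiment::assay(cohort@profiles, blk)
    write.csv(as.data.frame(m), file.path(dir, paste0(blk, ".csv")),
              row.names = TRUE)
  }
  if (length(cohort@refSequences) > 0) {
    Biostrings::writeXStringSet(cohort@refSequences,
                                file.path(dir, "reference.fasta"))
  }
  for (line in names(cohort@variantSequences)) {
    Biostrings::writeXStringSet(cohort@variantSequences[[line]],
                                file.path(dir, paste0("variants_", line,
                                                      ".fasta")))
  }
  if (nrow(cohort@curationLog) > 0) {
    wr(as.data.frame(cohort@curationLog), "curation_log.csv")
  }
  invisible(dir)
}
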