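#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData rowData
NULL

#' CdrCohort: a curated cell line-drug response cohort
#'
#' The central container of the package. Molecular profiles (binary mutation
#' calls, copy-number values, normalized expression and, optionally, protein
#' measurements) live in a \linkS4class{SummarizedExperiment} with genes as
#' rows and cell lines as columns. Drugs, response records and the curation
#' audit log are \linkS4class{DataFrame}s; gene sequences (reference and
#' per-cell-line variants) are \link[Biostrings]{DNAStringSet}s.
#'
#' @slot profiles SummarizedExperiment of omics blocks (assays named among
#'   \code{"mutation"}, \code{"cnv"}, \code{"expression"}, \code{"protein"});
#'   colData carries \code{lineage} and optional \code{subtype}.
#' @slot drugTable DataFrame with columns \code{id}, \code{name},
#'   \code{targets} (semicolon-separated gene symbols), \code{smiles},
#'   \code{inchi}, and optionally \code{cytotoxicity_index}.
#' @slot responseTable DataFrame with columns \code{cell_line_id},
#'   \code{drug_id}, \code{ic50_uM} and \code{label} (one of
#'   \code{"sensitive"}, \code{"resistant"}, \code{NA}).
#' @slot curationLog DataFrame with columns \code{step}, \code{retained},
#'   \code{excluded}, \code{reason}; counts telescope.
#' @slot refSequences DNAStringSet of per-gene reference sequences (may be
#'   empty).
#' @slot variantSequences named list of DNAStringSets, one per cell line,
#'   each keyed by gene symbol (may be empty).
#'
#' @export
setClass("CdrCohort",
  slots = c(
    profiles = "SummarizedExperiment",
    drugTable = "DataFrame",
    responseTable = "DataFrame",
    curationLog = "DataFrame",
    refSequences = "ANY",
    variantSequences = "list"
  )
)

setValidity("CdrCohort", function(object) {
  msg <- character()
  rt <- object@responseTable
  need <- c("cell_line_id", "drug_id", "ic50_uM", "label")
  if (!all(need %in% colnames(rt))) {
    msg <- c(msg, paste("responseTable must have columns:",
                        paste(need, collapse = ", ")))
  }
  dt <- object@drugTable
  if (!all(c("id", "name", "smiles", "inchi", "targets") %in% colnames(dt))) {
    msg <- c(msg, "drugTable must have columns id, name, targets, smiles, inchi")
  }
  if (anyDuplicated(dt$id)) msg <- c(msg, "drug ids must be unique")
  cl <- colnames(object@profiles)
  if (anyDuplicated(cl)) msg <- c(msg, "cell line ids must be unique")
  if (nrow(rt) > 0 && all(need %in% colnames(rt))) {
    if (!all(rt$cell_line_id %in% cl)) {
      msg <- c(msg, "responses reference unknown cell line ids")
    }
    if (!all(rt$drug_id %in% dt$id)) {
      msg <- c(msg, "responses reference unknown drug ids")
    }
    bad <- !is.na(rt$ic50_uM) & rt$ic50_uM <= 0
    if (any(bad)) msg <- c(msg, "ic50_uM must be positive where present")
  }
  if ("mutation" %in% SummarizedExperiment::assayNames(object@profiles)) {
    mv <- SummarizedExperiment::assay(object@profiles, "mutation")
    if (!all(mv %in% c(0, 1, NA))) {
      msg <- c(msg, "mutation calls must be in {0,1}")
    }
  }
  lg <- object@curationLog
  if (nrow(lg) > 1) {
    for (k in 2:nrow(lg)) {
      if (!is.na(lg$excluded[k]) &&
          lg$retained[k] + lg$excluded[k] != lg$retained[k - 1]) {
        msg <- c(msg, "curation log counts do not telescope")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CdrCohort
#'
#' @param profiles SummarizedExperiment, or a named list of gene x cell-line
#'   matrices (assays) which is wrapped into one.
#' @param drugs data.frame/DataFrame of drugs.
#' @param responses data.frame/DataFrame of response records; a missing
#'   \code{label} column is added as \code{NA}.
#' @param curationLog optional audit log.
#' @param refSequences optional DNAStringSet of gene reference sequences.
#' @param variantSequences optional named list (by cell line) of DNAStringSets.
#' @return A \linkS4class{CdrCohort}.
#' @export
CdrCohort <- function(profiles, drugs, responses,
                      curationLog = S4Vectors::DataFrame(
                        step = character(), retained = integer(),
                        excluded = integer(), reason = character()),
                      refSequences = Biostrings::DNAStringSet(),
                      variantSequences = list()) {
  if (is.list(profiles) && !is(profiles, "SummarizedExperiment")) {
    profiles <- SummarizedExperiment::SummarizedExperiment(assays = profiles)
  }
  responses <- S4Vectors::DataFrame(responses)
  if (!"label" %in% colnames(responses)) {
    responses$label <- rep(NA_character_, nrow(responses))
  }
  new("CdrCohort",
      profiles = profiles,
      drugTable = S4Vectors::DataFrame(drugs),
      responseTable = responses,
      curationLog = S4Vectors::DataFrame(curationLog),
      refSequences = refSequences,
      variantSequences = variantSequences)
}

#' @describeIn CdrCohort-accessors cell line identifiers
#' @export
cellLineIds <- function(x) colnames(x@profiles)

#' Accessors for CdrCohort
#'
#' @param x A CdrCohort.
#' @name CdrCohort-accessors
#' @return The corresponding component.
NULL

#' @describeIn CdrCohort-accessors gene identifiers
#' @export
geneIds <- function(x) rownames(x@profiles)

#' @describeIn CdrCohort-accessors drug annotation table
#' @export
drugTable <- function(x) x@drugTable

#' @describeIn CdrCohort-accessors response records
#' @export
responseTable <- function(x) x@responseTable

#' @describeIn CdrCohort-accessors curation audit log
#' @export
curationLog <- function(x) x@curationLog

#' @describeIn CdrCohort-accessors omics SummarizedExperiment
#' @export
profiles <- function(x) x@profiles

#' @describeIn CdrCohort-accessors one omics block as a matrix
#' @param block assay name ("mutation", "cnv", "expression", "protein")
#' @export
omicsBlock <- function(x, block) SummarizedExperiment::assay(x@profiles, block)

#' @describeIn CdrCohort-accessors reference gene sequences
#' @export
refSequences <- function(x) x@refSequences

#' @describeIn CdrCohort-accessors per-cell-line variant sequences
#' @export
variantSequences <- function(x) x@variantSequences

setMethod("show", "CdrCohort", function(object) {
  rt <- object@responseTable
  nlab <- sum(!is.na(rt$label))
  cat("CdrCohort with", ncol(object@profiles), "cell lines,",
      nrow(object@profiles), "genes,", nrow(object@drugTable), "drugs\n")
  cat("  responses:", nrow(rt), "pairs (", nlab, "labeled )\n")
  cat("  omics blocks:",
      paste(SummarizedExperiment::assayNames(object@profiles), collapse = ", "),
      "\n")
  if (nrow(object@curationLog) > 0) {
    cat("  curation steps:", nrow(object@curationLog), "| final retained:",
        utils::tail(object@curationLog$retained, 1), "\n")
  }
  invisible(NULL)
})
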