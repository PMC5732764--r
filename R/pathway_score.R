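#' Signed and absolute gene dysregulation scores
#'
#' Combines effect size and significance per gene into the pi-value style
#' score \code{signed = log2FC * -log10(padj)}; the absolute score is its
#' magnitude. A gene with no fold change, or with \code{padj = 1}, scores 0.
#'
#' @param de A \code{DEResult} (or any data frame with \code{gene_id},
#'   \code{log2FC}, \code{padj}).
#' @param eps Floor for \code{padj} keeping \code{-log10} finite
#'   (default 1e-300).
#' @return Data frame \code{gene_id}, \code{signed_score}, \code{abs_score};
#'   genes with missing \code{padj} are skipped and listed in attribute
#'   \code{skipped_genes}.
#' @export
gene_scores <- function(de, eps = 1e-300) {
  stopifnot(all(c("gene_id", "log2FC", "padj") %in% names(de)))
  skip <- is.na(de$padj) | is.na(de$log2FC)
  kept <- de[!skip, , drop = FALSE]
  signed <- kept$log2FC * (-log10(pmax(kept$padj, eps)))
  structure(data.frame(gene_id = kept$gene_id, signed_score = signed,
                       abs_score = abs(signed), stringsAsFactors = FALSE,
                       row.names = NULL),
            skipped_genes = de$gene_id[skip])
}

#' Square-root-n pathway dysregulation score
#'
#' Sums the gene scores of the pathway members present in the score table and
#' divides by the square root of the number of genes actually scored, making
#' scores comparable across pathways of different size.
#'
#' @param scores Output of \code{\link{gene_scores}}.
#' @param pathway Named list element or character vector of gene ids; if a
#'   one-element named list, the name is used as the pathway label.
#' @param mode \code{"signed"} or \code{"absolute"}: which gene score to sum.
#' @param name Pathway label (defaults to the deparsed argument).
#' @return One-row data frame: \code{pathway}, \code{n_genes_scored},
#'   \code{total} (signed or absolute per \code{mode}).
#' @export
pathway_score <- function(scores, pathway, mode = c("absolute", "signed"),
                          name = NULL) {
  mode <- match.arg(mode)
  if (is.list(pathway)) {
    if (is.null(name)) name <- names(pathway)[1]
    pathway <- pathway[[1]]
  }
  if (is.null(name)) name <- "pathway"
  if (anyDuplicated(pathway)) stop("duplicate gene ids in pathway ", name)
  present <- intersect(pathway, scores$gene_id)
  if (length(present) == 0)
    stop("no pathway genes scored for pathway: ", name)
  col <- if (mode == "absolute") "abs_score" else "signed_score"
  vals <- scores[[col]][match(present, scores$gene_id)]
  data.frame(pathway = name, n_genes_scored = length(present),
             total = sum(vals) / sqrt(length(present)),
             stringsAsFactors = FALSE)
}

#' Cross-cohort pathway dysregulation table and ranking
#'
#' Scores every pathway in every cohort (absolute mode) and ranks cohorts
#' within each pathway by descending score. Ties are broken lexicographically
#' by cohort label and flagged.
#'
#' @param de_results Named list of \code{DEResult} objects, one per cohort.
#' @param pathways Named list of gene-id vectors.
#' @param eps Passed to \code{\link{gene_scores}}.
#' @return List with \code{scores} (pathway x cohort matrix of abs totals),
#'   \code{ranking} (data frame \code{pathway}, \code{cohort}, \code{rank},
#'   \code{abs_total}, \code{tie}) and \code{n_genes_scored} (matrix).
#' @export
cross_cohort_table <- function(de_results, pathways, eps = 1e-300) {
  if (is.null(names(de_results)) || any(names(de_results) == ""))
    stop("de_results must be a named list of cohorts")
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stop("pathways must be a named list")
  cohorts <- names(de_results)
  gs <- lapply(de_results, gene_scores, eps = eps)
  m <- matrix(NA_real_, length(pathways), length(cohorts),
              dimnames = list(names(pathways), cohorts))
  nsc <- m
  for (pn in names(pathways)) for (cn in cohorts) {
    ps <- pathway_score(gs[[cn]], pathways[[pn]], mode = "absolute", name = pn)
    m[pn, cn] <- ps$total
    nsc[pn, cn] <- ps$n_genes_scored
  }
  ranking <- do.call(rbind, lapply(names(pathways), function(pn) {
    v <- m[pn, ]
    ord <- order(-v, cohorts)       # descending score, ties lexicographic
    data.frame(pathway = pn, cohort = cohorts[ord], rank = seq_along(ord),
               abs_total = unname(v[ord]),
               tie = duplicated(v[ord]) | duplicated(v[ord], fromLast = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(scores = m, ranking = ranking, n_genes_scored = nsc)
}
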