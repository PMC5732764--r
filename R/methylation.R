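#' Beta-value matrix container
#'
#' CpG x sample matrix of array methylation fractions in [0, 1] with a
#' per-sample diet-group label; a \code{"control"} group must be present and
#' every group non-empty.
#'
#' @param betas CpG x sample numeric matrix in [0, 1] with unique dimnames.
#' @param group Per-sample group labels.
#' @return Object of class \code{BetaMatrix} (list with \code{betas},
#'   \code{group}).
#' @export
BetaMatrix <- function(betas, group) {
  betas <- as.matrix(betas)
  if (is.null(rownames(betas)))
    rownames(betas) <- paste0("cpg", seq_len(nrow(betas)))
  if (is.null(colnames(betas)))
    colnames(betas) <- paste0("s", seq_len(ncol(betas)))
  if (anyDuplicated(rownames(betas))) stop("duplicate cpg ids")
  if (anyDuplicated(colnames(betas))) stop("duplicate sample ids")
  if (any(betas < 0 | betas > 1)) stop("betas must lie in [0, 1]")
  group <- as.character(group)
  if (length(group) != ncol(betas)) stop("one group label per sample required")
  if (!"control" %in% group) stop("a 'control' group is required")
  structure(list(betas = betas, group = group), class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpGs x %d samples (%s)\n",
              nrow(x$betas), ncol(x$betas),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Call variable methylation positions against the control mean
#'
#' For each non-control group and CpG, per-animal deltas are computed against
#' the mean beta of the control samples; a CpG is called hypermethylated in a
#' group when strictly more than \code{threshold} increase is seen in at
#' least \code{min_animals} animals, and hypomethylated symmetrically. The
#' "30% change in absolute methylation" is an absolute beta difference of
#' 0.30, not a relative change. A CpG meeting both criteria is emitted in
#' both directions and flagged \code{dual}.
#'
#' @param beta A \code{\link{BetaMatrix}}.
#' @param threshold Absolute beta-difference threshold in (0, 1),
#'   default 0.30; strict inequality.
#' @param min_animals Minimum supporting animals per call (default 2).
#' @return List with \code{calls} (data frame \code{cpg_id}, \code{group},
#'   \code{direction}, \code{n_supporting}, \code{max_abs_delta},
#'   \code{dual}, and \code{deltas}, a list column of per-animal deltas) and
#'   \code{summary} (hyper/hypo counts per group).
#' @export
call_variable_positions <- function(beta, threshold = 0.30, min_animals = 2) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (min_animals < 1) stop("min_animals must be >= 1")
  ctrl <- beta$group == "control"
  ctrl_mean <- rowMeans(beta$betas[, ctrl, drop = FALSE])
  groups <- setdiff(unique(beta$group), "control")

  out <- list()
  summ <- data.frame(group = groups, hyper = 0L, hypo = 0L,
                     stringsAsFactors = FALSE)
  for (g in groups) {
    d <- beta$betas[, beta$group == g, drop = FALSE] - ctrl_mean
    n_hyper <- rowSums(d > threshold)
    n_hypo <- rowSums(d < -threshold)
    hyper <- n_hyper >= min_animals
    hypo <- n_hypo >= min_animals
    dual <- hyper & hypo
    summ$hyper[summ$group == g] <- sum(hyper)
    summ$hypo[summ$group == g] <- sum(hypo)
    mk <- function(sel, dir, nsup) {
      if (!any(sel)) return(NULL)
      idx <- which(sel)
      data.frame(cpg_id = rownames(d)[idx], group = g, direction = dir,
                 n_supporting = nsup[idx],
                 max_abs_delta = apply(abs(d[idx, , drop = FALSE]), 1, max),
                 dual = dual[idx],
                 deltas = I(lapply(idx, function(i) d[i, ])),
                 stringsAsFactors = FALSE, row.names = NULL)
    }
    out[[paste0(g, "_hyper")]] <- mk(hyper, "hyper", n_hyper)
    out[[paste0(g, "_hypo")]] <- mk(hypo, "hypo", n_hypo)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(cpg_id = character(), group = character(),
                        direction = character(), n_supporting = integer(),
                        max_abs_delta = numeric(), dual = logical(),
                        stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, summary = summ)
}

#' Map called CpG positions to genes
#'
#' Unions the gene symbols of the called CpGs per group and direction
#' (set semantics: a gene hit by several CpGs appears once); CpGs without
#' annotation are tallied separately.
#'
#' @param calls Calls data frame (from \code{\link{call_variable_positions}}).
#' @param annotation Data frame \code{cpg_id}, \code{gene}; one-to-many
#'   mappings allowed.
#' @return Data frame \code{group}, \code{direction}, \code{n_genes},
#'   \code{n_unannotated}, with a list column \code{genes} (sorted unique
#'   symbols).
#' @export
annotate_calls <- function(calls, annotation) {
  stopifnot(all(c("cpg_id", "gene") %in% names(annotation)))
  if (nrow(calls) == 0)
    return(data.frame(group = character(), direction = character(),
                      n_genes = integer(), n_unannotated = integer(),
                      stringsAsFactors = FALSE))
  key <- unique(calls[c("group", "direction")])
  res <- lapply(seq_len(nrow(key)), function(i) {
    sub <- calls[calls$group == key$group[i] &
                 calls$direction == key$direction[i], ]
    ann <- annotation[annotation$cpg_id %in% sub$cpg_id, ]
    genes <- sort(unique(ann$gene[!is.na(ann$gene) & ann$gene != ""]))
    n_unann <- sum(!sub$cpg_id %in% ann$cpg_id)
    data.frame(group = key$group[i], direction = key$direction[i],
               n_genes = length(genes), n_unannotated = n_unann,
               genes = I(list(genes)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail probability of observing at least the given overlap when a
#' \code{n_b}-gene set is drawn without replacement from a universe
#' containing \code{n_a} marked genes: \code{P(X >= overlap)} for
#' X ~ Hypergeometric(universe, n_a, n_b).
#'
#' @param set_a,set_b Either character vectors of gene ids (overlap computed
#'   by intersection) or single set sizes (then \code{overlap} is required).
#' @param universe_size Total genes in the universe.
#' @param overlap Overlap count; required when sizes are given.
#' @return List: \code{n_a}, \code{n_b}, \code{overlap}, \code{p_upper}.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe_size,
                                   overlap = NULL) {
  if (is.character(set_a) || is.character(set_b)) {
    set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
    overlap <- length(intersect(set_a, set_b))
    n_a <- length(set_a); n_b <- length(set_b)
  } else {
    if (is.null(overlap)) stop("overlap required when sizes are given")
    n_a <- as.integer(set_a); n_b <- as.integer(set_b)
  }
  if (n_a > universe_size || n_b > universe_size)
    stop("set sizes exceed the universe")
  if (overlap > min(n_a, n_b)) stop("overlap exceeds the smaller set")
  p <- stats::phyper(overlap - 1, n_a, universe_size - n_a, n_b,
                     lower.tail = FALSE)
  list(n_a = n_a, n_b = n_b, overlap = overlap, p_upper = p)
}

#' Hypergeometric over-representation of a gene list in gene sets
#'
#' Tests each set of a collection for enrichment of the query genes by the
#' upper-tail hypergeometric probability, BH-adjusts across sets, and ranks
#' by p. Coverage is the fraction of each set found in the query.
#'
#' @param genes Character vector of query gene ids.
#' @param collection Named list of gene-id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe_size Genes in the universe; a required, reported choice.
#' @return Data frame \code{set}, \code{set_size}, \code{overlap},
#'   \code{coverage}, \code{p_upper}, \code{padj}, ranked by increasing p
#'   (ties by set name).
#' @export
enrich_gene_sets <- function(genes, collection, universe_size) {
  if (is.null(names(collection)) || any(names(collection) == ""))
    stop("collection must be a named list")
  if (any(lengths(collection) == 0)) stop("empty gene set in collection")
  genes <- unique(genes)
  res <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- unique(collection[[nm]])
    ov <- length(intersect(genes, set))
    p <- stats::phyper(ov - 1, length(set), universe_size - length(set),
                       length(genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov,
               coverage = ov / length(set), p_upper = p,
               stringsAsFactors = FALSE)
  }))
  res$padj <- bh_adjust(res$p_upper)
  res[order(res$p_upper, res$set), , drop = FALSE]
}

#' Overlap network of enriched gene sets
#'
#' Builds the edge list connecting top-ranked sets whose overlap coefficient
#' \code{|A intersect B| / min(|A|, |B|)} reaches the cutoff, together with a
#' node table carrying each set's enrichment p-value and coverage. Edges are
#' ordered deterministically (lexicographic set pairs).
#'
#' @param enrichment Result of \code{\link{enrich_gene_sets}}.
#' @param collection The gene-set collection the enrichment was run on.
#' @param top_n Number of top-ranked sets to include (default 20).
#' @param min_overlap_coef Minimum overlap coefficient for an edge
#'   (default 0.25).
#' @return List with \code{nodes} (\code{set}, \code{p_upper},
#'   \code{coverage}) and \code{edges} (\code{set_a}, \code{set_b},
#'   \code{overlap_coefficient}).
#' @export
overlap_network <- function(enrichment, collection, top_n = 20,
                            min_overlap_coef = 0.25) {
  top <- utils::head(enrichment, top_n)
  nodes <- data.frame(set = top$set, p_upper = top$p_upper,
                      coverage = top$coverage, stringsAsFactors = FALSE)
  sets <- lapply(top$set, function(nm) unique(collection[[nm]]))
  names(sets) <- top$set
  nm_sorted <- sort(top$set)
  edges <- list()
  if (length(nm_sorted) >= 2) {
    for (i in seq_len(length(nm_sorted) - 1)) {
      for (j in (i + 1):length(nm_sorted)) {
        a <- sets[[nm_sorted[i]]]; b <- sets[[nm_sorted[j]]]
        coef <- length(intersect(a, b)) / min(length(a), length(b))
        if (coef >= min_overlap_coef)
          edges[[length(edges) + 1]] <-
            data.frame(set_a = nm_sorted[i], set_b = nm_sorted[j],
                       overlap_coefficient = coef, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(set_a = character(), set_b = character(),
                           overlap_coefficient = numeric(),
                           stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
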