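#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member gene ids. Duplicate
#' members within a set are dropped.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("malformed GMT: need name, description and >= 1 gene")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path, description = "") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression cohort as counts + metadata TSVs
#'
#' @param cohort An \code{\link{ExpressionCohort}}.
#' @param counts_path,meta_path Output paths; the counts table has a
#'   \code{gene_id} first column, the metadata has \code{sample_id},
#'   \code{condition} and (if present) \code{pair_id}.
#' @return Invisibly, the two paths.
#' @export
write_expression_cohort <- function(cohort, counts_path, meta_path) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  cts <- data.frame(gene_id = rownames(cohort$counts), cohort$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(cts, counts_path)
  meta <- data.frame(sample_id = colnames(cohort$counts),
                     condition = cohort$condition, stringsAsFactors = FALSE)
  if (!is.null(cohort$pair_id)) meta$pair_id <- cohort$pair_id
  write_tsv_(meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' Read an expression cohort from counts + metadata TSVs
#'
#' @param counts_path TSV with \code{gene_id} first column then one column
#'   per sample.
#' @param meta_path TSV with \code{sample_id}, \code{condition}, optional
#'   \code{pair_id}.
#' @return An \code{\link{ExpressionCohort}}.
#' @export
read_expression_cohort <- function(counts_path, meta_path) {
  cts <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) stop("metadata lacks some samples")
  ExpressionCohort(m, meta$condition[idx],
                   pair_id = if ("pair_id" %in% names(meta))
                     meta$pair_id[idx] else NULL)
}

#' Write a beta-value matrix and its group table
#'
#' @param beta A \code{\link{BetaMatrix}}.
#' @param beta_path TSV path (first column \code{cpg_id}).
#' @param group_path TSV path (\code{sample_id}, \code{group}).
#' @return Invisibly, the two paths.
#' @export
write_beta_matrix <- function(beta, beta_path, group_path) {
  stopifnot(inherits(beta, "BetaMatrix"))
  b <- data.frame(cpg_id = rownames(beta$betas), beta$betas,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(b, beta_path)
  write_tsv_(data.frame(sample_id = colnames(beta$betas),
                        group = beta$group, stringsAsFactors = FALSE),
             group_path)
  invisible(c(beta_path, group_path))
}

#' Read a beta-value matrix and its group table
#'
#' @param beta_path,group_path Paths written by
#'   \code{\link{write_beta_matrix}}.
#' @return A \code{\link{BetaMatrix}}.
#' @export
read_beta_matrix <- function(beta_path, group_path) {
  b <- utils::read.delim(beta_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(b[, -1, drop = FALSE])
  rownames(m) <- b[[1]]
  g <- utils::read.delim(group_path, stringsAsFactors = FALSE)
  idx <- match(colnames(m), g$sample_id)
  if (anyNA(idx)) stop("group table lacks some samples")
  BetaMatrix(m, g$group[idx])
}

#' Drive all synthetic-data generators from one YAML config
#'
#' The YAML may contain top-level sections \code{expression},
#' \code{survival}, \code{methylome} and \code{xenograft}, each holding the
#' arguments of the corresponding \code{*_sim_config}; outputs and truth
#' tables are written as TSV/CSV under \code{out_dir}. For \code{survival},
#' patient scores are standard-normal draws under the same seed. For
#' \code{methylome}, an optional \code{n_events}/\code{delta_beta}/
#' \code{n_supporting_animals} block drives \code{\link{random_meth_events}}.
#'
#' @param yaml_path Path to the YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the generated objects.
#' @export
simulate_study <- function(yaml_path, out_dir) {
  cfg <- yaml::read_yaml(yaml_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (!is.null(cfg$expression)) {
    e <- cfg$expression
    pw <- lapply(e$pathway_defs, unlist)
    sim <- simulate_expression_cohort(expr_sim_config(
      n_genes = e$n_genes, n_pairs = e$n_pairs, pathway_defs = pw,
      effect_frac = e$effect_frac %||% 0.5,
      effect_scale = e$effect_scale %||% 1,
      nb_dispersion = e$nb_dispersion %||% 0.1,
      lib_size_range = if (is.null(e$lib_size_range)) NULL
                       else unlist(e$lib_size_range),
      seed = e$seed %||% 1L))
    write_expression_cohort(sim$cohort, file.path(out_dir, "counts.tsv"),
                            file.path(out_dir, "samples.tsv"))
    write_tsv_(sim$truth, file.path(out_dir, "expression_truth.tsv"))
    if (length(pw)) write_gmt(pw, file.path(out_dir, "pathways.gmt"))
    out$expression <- sim
  }
  if (!is.null(cfg$survival)) {
    s <- cfg$survival
    conf <- surv_sim_config(n_patients = s$n_patients,
                            baseline_hazard = s$baseline_hazard %||% 0.1,
                            log_hazard_per_unit_score =
                              s$log_hazard_per_unit_score %||% 1,
                            censor_time = s$censor_time %||% 10,
                            admin_horizon = s$admin_horizon %||% 5,
                            seed = s$seed %||% 1L)
    set.seed(conf$seed + 1L)
    scores <- stats::rnorm(conf$n_patients)
    surv <- simulate_survival(scores, conf)
    write_tsv_(surv[c("patient_id", "time_years", "event")],
               file.path(out_dir, "survival.tsv"))
    write_tsv_(surv, file.path(out_dir, "survival_truth.tsv"))
    out$survival <- surv
  }
  if (!is.null(cfg$methylome)) {
    m <- cfg$methylome
    ev <- if (!is.null(m$n_events))
      random_meth_events(m$n_events, m$n_cpgs,
                         delta_beta = m$delta_beta %||% 0.4,
                         n_supporting_animals =
                           m$n_supporting_animals %||% 2,
                         seed = m$seed %||% 1L)
    sim <- simulate_methylome(meth_sim_config(
      n_cpgs = m$n_cpgs,
      animals_per_group = m$animals_per_group %||% 4,
      planted_events = ev,
      noise_sd_logit = m$noise_sd_logit %||% 0.05,
      seed = m$seed %||% 1L))
    write_beta_matrix(sim$beta, file.path(out_dir, "betas.tsv"),
                      file.path(out_dir, "groups.tsv"))
    write_tsv_(sim$truth, file.path(out_dir, "methylome_truth.tsv"))
    out$methylome <- sim
  }
  if (!is.null(cfg$xenograft)) {
    x <- cfg$xenograft
    conf <- traj_sim_config(
      n_animals = x$n_animals %||% 40,
      arms = x$arms %||% c("control", "depleted", "supplemented"),
      recurrence_prob = if (is.null(x$recurrence_prob))
        c(control = 0.70, depleted = 0.40, supplemented = 0.40)
        else unlist(x$recurrence_prob),
      noise_cv = x$noise_cv %||% 0.1,
      seed = x$seed %||% 1L)
    sim <- simulate_xenograft_trajectories(conf)
    utils::write.csv(sim$trajectories,
                     file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE, quote = FALSE)
    write_tsv_(sim$truth, file.path(out_dir, "xenograft_truth.tsv"))
    out$xenograft <- sim
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
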