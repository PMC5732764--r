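#' Expression cohort container
#'
#' Bundles a non-negative integer count matrix (genes x samples) with
#' per-sample condition labels and optional tumor/normal pair labels.
#'
#' @param counts Genes x samples matrix of non-negative integers with unique
#'   row and column names.
#' @param condition Per-sample labels, \code{"tumor"} or \code{"normal"};
#'   each condition needs at least 2 samples.
#' @param pair_id Optional per-sample pair labels for matched designs.
#' @return An object of class \code{ExpressionCohort} (a list with elements
#'   \code{counts}, \code{condition}, \code{pair_id}).
#' @export
ExpressionCohort <- function(counts, condition, pair_id = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) stop("one condition per sample required")
  if (!all(condition %in% c("tumor", "normal")))
    stop("condition must be 'tumor' or 'normal'")
  if (min(table(factor(condition, c("tumor", "normal")))) < 2)
    stop("need at least 2 samples per condition")
  if (!is.null(pair_id) && length(pair_id) != ncol(counts))
    stop("one pair_id per sample required")
  structure(list(counts = counts, condition = condition,
                 pair_id = if (is.null(pair_id)) NULL else as.character(pair_id)),
            class = "ExpressionCohort")
}

#' @export
print.ExpressionCohort <- function(x, ...) {
  cat(sprintf("ExpressionCohort: %d genes x %d samples (%d tumor, %d normal%s)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "tumor"), sum(x$condition == "normal"),
              if (is.null(x$pair_id)) "" else ", paired"))
  invisible(x)
}

#' Configuration for the expression-cohort simulator
#'
#' @param n_genes Number of genes in the universe (ids \code{g1..gN}).
#' @param n_pairs Number of tumor/normal pairs.
#' @param pathway_defs Named list of character vectors of gene ids; effects
#'   are planted inside these sets. All ids must lie in the gene universe and
#'   no set may be empty.
#' @param effect_frac Fraction of each pathway's genes perturbed, in [0, 1].
#' @param effect_scale Absolute log2 fold change planted on each perturbed
#'   gene (random sign); also its mean since the magnitude is fixed.
#' @param nb_dispersion Shared negative-binomial dispersion (> 0).
#' @param lib_size_range Range of expected total counts per sample; default
#'   500 to 1500 expected counts per gene, the regime of deep bulk RNA-seq.
#' @param seed Integer seed; identical configs give identical output.
#' @return A list of class \code{ExprSimConfig}.
#' @export
expr_sim_config <- function(n_genes, n_pairs, pathway_defs = list(),
                            effect_frac = 0.5, effect_scale = 1,
                            nb_dispersion = 0.1, lib_size_range = NULL,
                            seed = 1L) {
  if (is.null(lib_size_range)) lib_size_range <- c(500, 1500) * n_genes
  stopifnot(n_genes >= 1, n_pairs >= 2,
            effect_frac >= 0, effect_frac <= 1,
            nb_dispersion > 0, length(lib_size_range) == 2,
            lib_size_range[1] > 0, lib_size_range[2] >= lib_size_range[1])
  universe <- paste0("g", seq_len(n_genes))
  if (length(pathway_defs)) {
    if (is.null(names(pathway_defs)) || any(names(pathway_defs) == ""))
      stop("pathway_defs must be a named list")
    for (nm in names(pathway_defs)) {
      g <- pathway_defs[[nm]]
      if (length(g) == 0) stop("empty pathway: ", nm)
      if (!all(g %in% universe)) stop("pathway ", nm, " has gene ids outside the universe")
    }
  }
  structure(list(n_genes = n_genes, n_pairs = n_pairs,
                 pathway_defs = pathway_defs, effect_frac = effect_frac,
                 effect_scale = effect_scale, nb_dispersion = nb_dispersion,
                 lib_size_range = lib_size_range, seed = as.integer(seed)),
            class = "ExprSimConfig")
}

#' Simulate a paired tumor/normal expression cohort
#'
#' Gene baseline abundances are drawn log-normally and shared by all samples;
#' counts are negative-binomial with a common dispersion and per-sample
#' library sizes drawn uniformly from \code{lib_size_range}. For each pathway
#' in the config, \code{round(effect_frac * size)} member genes are chosen and
#' their tumor means multiplied by \code{2^(true log2FC)} with
#' \code{|log2FC| = effect_scale} and random sign. A gene claimed by more
#' than one pathway keeps its first planted effect.
#'
#' @param config An \code{\link{expr_sim_config}}.
#' @return List with \code{cohort} (an \code{\link{ExpressionCohort}} with
#'   samples T1..Tn, N1..Nn and pair ids P1..Pn) and \code{truth}, a data
#'   frame with one row per gene (\code{gene_id}, \code{true_lfc},
#'   \code{pathway}; \code{true_lfc = 0} and \code{pathway = NA} for
#'   unperturbed genes).
#' @export
simulate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "ExprSimConfig"))
  set.seed(config$seed)
  ng <- config$n_genes; np <- config$n_pairs
  genes <- paste0("g", seq_len(ng))

  rel <- stats::rlnorm(ng, meanlog = log(50), sdlog = 1)
  prop <- rel / sum(rel)

  lfc <- stats::setNames(numeric(ng), genes)
  pw <- stats::setNames(rep(NA_character_, ng), genes)
  for (nm in names(config$pathway_defs)) {
    members <- config$pathway_defs[[nm]]
    n_eff <- round(config$effect_frac * length(members))
    if (n_eff == 0) next
    chosen <- sample(members, n_eff)
    chosen <- chosen[is.na(pw[chosen])]       # first pathway keeps the gene
    sgn <- sample(c(-1, 1), length(chosen), replace = TRUE)
    lfc[chosen] <- sgn * config$effect_scale
    pw[chosen] <- nm
  }
  if (config$effect_scale == 0) { lfc[] <- 0; pw[] <- NA_character_ }

  n_samples <- 2 * np
  lib <- stats::runif(n_samples, config$lib_size_range[1], config$lib_size_range[2])
  cond <- rep(c("tumor", "normal"), each = np)
  mu <- outer(prop, lib)                      # genes x samples expected counts
  mu[, cond == "tumor"] <- mu[, cond == "tumor"] * 2^lfc
  counts <- matrix(stats::rnbinom(ng * n_samples, mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = ng,
                   dimnames = list(genes, c(paste0("T", seq_len(np)),
                                            paste0("N", seq_len(np)))))
  cohort <- ExpressionCohort(counts, cond,
                             pair_id = rep(paste0("P", seq_len(np)), 2))
  truth <- data.frame(gene_id = genes, true_lfc = unname(lfc),
                      pathway = unname(pw), stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Configuration for the biochemical-recurrence survival simulator
#'
#' @param n_patients Number of patients.
#' @param baseline_hazard Baseline event rate, events per year (> 0).
#' @param log_hazard_per_unit_score Log hazard ratio per unit of (centered)
#'   dysregulation score.
#' @param censor_time Mean of the exponential random-censoring time, years.
#' @param admin_horizon Administrative censoring horizon, years (default 5,
#'   the usual biochemical-recurrence window).
#' @param seed Integer seed.
#' @return A list of class \code{SurvSimConfig}.
#' @export
surv_sim_config <- function(n_patients, baseline_hazard = 0.1,
                            log_hazard_per_unit_score = 1,
                            censor_time = 10, admin_horizon = 5, seed = 1L) {
  stopifnot(n_patients >= 1, baseline_hazard > 0, censor_time > 0,
            admin_horizon > 0)
  structure(list(n_patients = n_patients, baseline_hazard = baseline_hazard,
                 log_hazard_per_unit_score = log_hazard_per_unit_score,
                 censor_time = censor_time, admin_horizon = admin_horizon,
                 seed = as.integer(seed)),
            class = "SurvSimConfig")
}

#' Simulate time to biochemical recurrence given patient scores
#'
#' Event times are exponential with per-patient hazard
#' \code{baseline_hazard * exp(beta * (score - mean(score)))}; the observed
#' time is the minimum of the event time, an exponential censoring draw and
#' the administrative horizon, with \code{event = 1} iff the event came first.
#'
#' @param scores Finite numeric vector of per-patient dysregulation scores.
#' @param config A \code{\link{surv_sim_config}}; its \code{n_patients} must
#'   match \code{length(scores)}.
#' @return Data frame with \code{patient_id}, \code{time_years},
#'   \code{event} (0/1) and the latent \code{score}.
#' @export
simulate_survival <- function(scores, config) {
  stopifnot(inherits(config, "SurvSimConfig"))
  if (length(scores) == 0) stop("scores must be non-empty")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (length(scores) != config$n_patients)
    stop("length(scores) must equal config$n_patients")
  set.seed(config$seed)
  n <- length(scores)
  hz <- config$baseline_hazard *
    exp(config$log_hazard_per_unit_score * (scores - mean(scores)))
  t_event <- stats::rexp(n, rate = hz)
  t_cens <- stats::rexp(n, rate = 1 / config$censor_time)
  obs <- pmin(t_event, t_cens, config$admin_horizon)
  data.frame(patient_id = if (is.null(names(scores)))
               sprintf("pt%03d", seq_len(n)) else names(scores),
             time_years = obs,
             event = as.integer(t_event <= pmin(t_cens, config$admin_horizon)),
             score = as.numeric(scores), stringsAsFactors = FALSE)
}

#' Configuration for the methylome simulator
#'
#' Emulates an array experiment with one control and further diet groups,
#' a few animals per group, and planted hypo/hypermethylation events.
#'
#' @param n_cpgs Number of CpG positions (ids \code{cg000001..}).
#' @param groups Ordered group labels; the first must be \code{"control"}.
#' @param animals_per_group Animals per group (default 4).
#' @param planted_events Data frame with columns \code{cpg_id}, \code{group}
#'   (a non-control group), \code{direction} ("hyper"/"hypo"),
#'   \code{delta_beta} (positive magnitude) and \code{n_supporting_animals};
#'   at most one event per (cpg, group). \code{NULL} for none.
#' @param noise_sd_logit Gaussian noise sd on the logit-beta scale (>= 0).
#' @param seed Integer seed.
#' @return A list of class \code{MethSimConfig}.
#' @export
meth_sim_config <- function(n_cpgs,
                            groups = c("control", "depleted", "supplemented"),
                            animals_per_group = 4, planted_events = NULL,
                            noise_sd_logit = 0.05, seed = 1L) {
  stopifnot(n_cpgs >= 1, animals_per_group >= 1, noise_sd_logit >= 0)
  if (groups[1] != "control") stop("first group must be 'control'")
  if (!is.null(planted_events)) {
    ev <- planted_events
    need <- c("cpg_id", "group", "direction", "delta_beta",
              "n_supporting_animals")
    if (!all(need %in% names(ev))) stop("planted_events lacks required columns")
    if (!all(ev$group %in% groups[-1]))
      stop("planted events must target non-control groups")
    if (!all(ev$direction %in% c("hyper", "hypo")))
      stop("direction must be 'hyper' or 'hypo'")
    if (any(ev$delta_beta <= 0)) stop("delta_beta must be positive")
    if (any(ev$n_supporting_animals > animals_per_group))
      stop("n_supporting_animals exceeds animals_per_group")
    if (anyDuplicated(ev[c("cpg_id", "group")]))
      stop("at most one event per (cpg_id, group)")
    if (!all(ev$cpg_id %in% sprintf("cg%06d", seq_len(n_cpgs))))
      stop("planted event cpg_id outside the CpG universe")
  }
  structure(list(n_cpgs = n_cpgs, groups = groups,
                 animals_per_group = animals_per_group,
                 planted_events = planted_events,
                 noise_sd_logit = noise_sd_logit, seed = as.integer(seed)),
            class = "MethSimConfig")
}

#' Draw a random table of methylation events to plant
#'
#' Helper for building the \code{planted_events} argument of
#' \code{\link{meth_sim_config}}: events are assigned to distinct CpGs drawn
#' uniformly, with the given direction mix across the non-control groups.
#'
#' @param n_events Number of events.
#' @param n_cpgs CpG universe size (must match the sim config).
#' @param groups Non-control group labels to spread events over.
#' @param direction "hyper", "hypo", or "both" (alternating).
#' @param delta_beta Planted beta shift magnitude (default 0.4).
#' @param n_supporting_animals Animals carrying each event (default 2).
#' @param seed Integer seed.
#' @return Data frame suitable for \code{planted_events}.
#' @export
random_meth_events <- function(n_events, n_cpgs,
                               groups = c("depleted", "supplemented"),
                               direction = "both", delta_beta = 0.4,
                               n_supporting_animals = 2, seed = 1L) {
  stopifnot(n_events <= n_cpgs)
  set.seed(seed)
  cpgs <- sprintf("cg%06d", sort(sample.int(n_cpgs, n_events)))
  dir <- switch(direction,
                hyper = rep("hyper", n_events),
                hypo = rep("hypo", n_events),
                both = rep_len(c("hyper", "hypo"), n_events),
                stop("direction must be 'hyper', 'hypo' or 'both'"))
  data.frame(cpg_id = cpgs,
             group = rep_len(groups, n_events),
             direction = dir,
             delta_beta = delta_beta,
             n_supporting_animals = n_supporting_animals,
             stringsAsFactors = FALSE)
}

#' Simulate a grouped beta-value matrix with planted methylation events
#'
#' Every CpG gets a baseline beta drawn uniformly in (0.1, 0.9) shared by all
#' animals; planted events shift exactly \code{n_supporting_animals} randomly
#' chosen animals of the stated group by \code{+delta_beta} (hyper) or
#' \code{-delta_beta} (hypo), clipped into (0, 1) with the achieved shift
#' recorded in the truth table. Gaussian noise is then added on the logit
#' scale and inverse-transformed, so emitted betas always stay in (0, 1).
#'
#' @param config A \code{\link{meth_sim_config}}.
#' @return List with \code{beta} (a \code{\link{BetaMatrix}}) and
#'   \code{truth}, the planted-event table augmented with \code{animals}
#'   (comma-joined sample ids), \code{achieved_delta} and \code{clipped}.
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "MethSimConfig"))
  set.seed(config$seed)
  ng <- length(config$groups); na <- config$animals_per_group
  cpgs <- sprintf("cg%06d", seq_len(config$n_cpgs))
  samples <- paste(rep(config$groups, each = na), seq_len(na), sep = "_")
  group <- rep(config$groups, each = na)

  b0 <- stats::runif(config$n_cpgs, 0.1, 0.9)

  # Planted shifts are realized in full whenever the unit interval allows:
  # baselines of planted CpGs are redrawn inside the range compatible with
  # every event on that CpG; clipping remains the fallback for infeasible
  # deltas (and is recorded in the truth table).
  truth <- config$planted_events
  if (!is.null(truth) && nrow(truth)) {
    for (cp in unique(truth$cpg_id)) {
      ev <- truth[truth$cpg_id == cp, ]
      lo <- max(0.1, 0.001 + max(c(0, ev$delta_beta[ev$direction == "hypo"])))
      hi <- min(0.9, 0.999 - max(c(0, ev$delta_beta[ev$direction == "hyper"])))
      if (lo < hi) b0[match(cp, cpgs)] <- stats::runif(1, lo, hi)
    }
  }
  target <- matrix(b0, nrow = config$n_cpgs, ncol = ng * na,
                   dimnames = list(cpgs, samples))
  if (!is.null(truth) && nrow(truth)) {
    truth$animals <- NA_character_
    truth$achieved_delta <- NA_real_
    truth$clipped <- FALSE
    for (i in seq_len(nrow(truth))) {
      cols <- which(group == truth$group[i])
      hit <- sample(cols, truth$n_supporting_animals[i])
      sgn <- if (truth$direction[i] == "hyper") 1 else -1
      raw <- b0[match(truth$cpg_id[i], cpgs)] + sgn * truth$delta_beta[i]
      clp <- min(max(raw, 0.001), 0.999)
      target[truth$cpg_id[i], hit] <- clp
      truth$animals[i] <- paste(samples[hit], collapse = ",")
      truth$achieved_delta[i] <- clp - b0[match(truth$cpg_id[i], cpgs)]
      truth$clipped[i] <- clp != raw
    }
  } else {
    truth <- data.frame(cpg_id = character(), group = character(),
                        direction = character(), delta_beta = numeric(),
                        n_supporting_animals = integer(),
                        animals = character(), achieved_delta = numeric(),
                        clipped = logical(), stringsAsFactors = FALSE)
  }

  betas <- if (config$noise_sd_logit > 0) {
    stats::plogis(stats::qlogis(target) +
                  stats::rnorm(length(target), sd = config$noise_sd_logit))
  } else target
  dimnames(betas) <- dimnames(target)
  list(beta = BetaMatrix(betas, group), truth = truth)
}

#' Configuration for the xenograft trajectory simulator
#'
#' Emulates castration-recurrent xenograft kinetics: tumors start at the
#' androgen-withdrawal volume, regress exponentially, and a planted fraction
#' per diet arm regrows exponentially from a random onset day. Deterministic
#' volumes are floored at 4 mm3 (a ~2 mm nodule, the practical caliper
#' detection limit).
#'
#' @param n_animals Animals per arm (default 40, a typical cohort).
#' @param arms Diet arm labels.
#' @param start_volume Volume at androgen withdrawal, mm3 (default 300).
#' @param regression_rate Exponential decay rate per day (default log(2)/7,
#'   a one-week half-life).
#' @param growth_rate Regrowth rate per day (default log(2)/10).
#' @param recurrence_prob Per-arm recurrence probability; scalar or named
#'   vector over \code{arms}.
#' @param recurrence_onset_range Days between which regrowth onsets are drawn
#'   uniformly (default 56-252, weeks 8-36).
#' @param follow_up Days of follow-up (default 350, i.e. 50 weeks).
#' @param measurement_interval Days between caliper measurements (default 7).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   measurement noise (default 0.1).
#' @param seed Integer seed.
#' @return A list of class \code{TrajSimConfig}.
#' @export
traj_sim_config <- function(n_animals = 40,
                            arms = c("control", "depleted", "supplemented"),
                            start_volume = 300,
                            regression_rate = log(2) / 7,
                            growth_rate = log(2) / 10,
                            recurrence_prob = c(control = 0.70,
                                                depleted = 0.40,
                                                supplemented = 0.40),
                            recurrence_onset_range = c(56, 252),
                            follow_up = 350, measurement_interval = 7,
                            noise_cv = 0.1, seed = 1L) {
  if (length(recurrence_prob) == 1)
    recurrence_prob <- stats::setNames(rep(recurrence_prob, length(arms)), arms)
  stopifnot(n_animals >= 1, start_volume > 0, regression_rate > 0,
            growth_rate > 0, all(recurrence_prob >= 0),
            all(recurrence_prob <= 1),
            all(arms %in% names(recurrence_prob)),
            follow_up >= measurement_interval, measurement_interval > 0,
            noise_cv >= 0)
  structure(list(n_animals = n_animals, arms = arms,
                 start_volume = start_volume,
                 regression_rate = regression_rate, growth_rate = growth_rate,
                 recurrence_prob = recurrence_prob,
                 recurrence_onset_range = recurrence_onset_range,
                 follow_up = follow_up,
                 measurement_interval = measurement_interval,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "TrajSimConfig")
}

#' Simulate xenograft tumor-volume trajectories
#'
#' @param config A \code{\link{traj_sim_config}}.
#' @return List with \code{trajectories} (data frame \code{animal_id},
#'   \code{arm}, \code{day}, \code{volume_mm3}) and \code{truth} (data frame
#'   \code{animal_id}, \code{arm}, \code{recurrent}, \code{onset_day}).
#' @export
simulate_xenograft_trajectories <- function(config) {
  stopifnot(inherits(config, "TrajSimConfig"))
  set.seed(config$seed)
  days <- seq(0, config$follow_up, by = config$measurement_interval)
  floor_vol <- 4
  sdlog <- sqrt(log(1 + config$noise_cv^2))

  traj <- list(); truth <- list(); k <- 0
  for (arm in config$arms) {
    p <- config$recurrence_prob[[arm]]
    for (a in seq_len(config$n_animals)) {
      k <- k + 1
      id <- sprintf("%s_%02d", arm, a)
      rec <- stats::runif(1) < p
      onset <- if (rec) stats::runif(1, config$recurrence_onset_range[1],
                                     config$recurrence_onset_range[2]) else NA
      v <- pmax(config$start_volume * exp(-config$regression_rate * days),
                floor_vol)
      if (rec) {
        regrow <- days >= onset
        v_on <- max(config$start_volume * exp(-config$regression_rate * onset),
                    floor_vol)
        v[regrow] <- v_on * exp(config$growth_rate * (days[regrow] - onset))
      }
      if (config$noise_cv > 0)
        v <- v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      traj[[k]] <- data.frame(animal_id = id, arm = arm, day = days,
                              volume_mm3 = v, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(animal_id = id, arm = arm, recurrent = rec,
                               onset_day = onset, stringsAsFactors = FALSE)
    }
  }
  list(trajectories = do.call(rbind, traj), truth = do.call(rbind, truth))
}
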