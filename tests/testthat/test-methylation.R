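test_that("variable-position calls apply the delta-beta rule directly", {
  b <- toy_beta(control = rep(0.5, 4), depleted = c(0.90, 0.85, 0.50, 0.50))
  res <- call_variable_positions(b)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$cpg_id, "cg_test")
  expect_equal(res$calls$direction, "hyper")
  expect_equal(res$calls$n_supporting, 2)
  expect_equal(res$summary$hyper[res$summary$group == "depleted"], 1)

  # one supporter is not enough
  b1 <- toy_beta(rep(0.5, 4), c(0.90, 0.50, 0.50, 0.50))
  expect_equal(nrow(call_variable_positions(b1)$calls), 0)

  # strict inequality: a change exactly at the threshold is not a call
  # (binary-exact values so the comparison is not blurred by rounding)
  b2 <- toy_beta(rep(0.5, 4), c(0.75, 0.75, 0.50, 0.50))
  expect_equal(nrow(call_variable_positions(b2, threshold = 0.25)$calls), 0)
  expect_equal(nrow(call_variable_positions(b2, threshold = 0.2495)$calls), 1)

  # hypo direction
  b3 <- toy_beta(rep(0.8, 4), c(0.10, 0.15, 0.80, 0.80))
  expect_equal(call_variable_positions(b3)$calls$direction, "hypo")

  expect_error(call_variable_positions(b3, threshold = 1.2), "threshold")
})

test_that("caller is invariant to row and control-column order", {
  ev <- random_meth_events(20, 200, seed = 61)
  sim <- simulate_methylome(meth_sim_config(200, planted_events = ev,
                                            noise_sd_logit = 0.1, seed = 61))
  base <- call_variable_positions(sim$beta)$calls
  set.seed(62)
  perm_rows <- sample(nrow(sim$beta$betas))
  perm_cols <- c(sample(1:4), 5:12)   # shuffle control animals
  b2 <- BetaMatrix(sim$beta$betas[perm_rows, perm_cols],
                   sim$beta$group[perm_cols])
  shuf <- call_variable_positions(b2)$calls
  key <- function(d) sort(paste(d$cpg_id, d$group, d$direction))
  expect_identical(key(base), key(shuf))
})

test_that("raising threshold or min_animals never adds calls", {
  for (s in 1:5) {
    ev <- random_meth_events(30, 300, seed = s)
    sim <- simulate_methylome(meth_sim_config(300, planted_events = ev,
                                              noise_sd_logit = 0.15, seed = s))
    n1 <- nrow(call_variable_positions(sim$beta, 0.2, 2)$calls)
    n2 <- nrow(call_variable_positions(sim$beta, 0.3, 2)$calls)
    n3 <- nrow(call_variable_positions(sim$beta, 0.4, 2)$calls)
    expect_true(n1 >= n2 && n2 >= n3)
    m2 <- nrow(call_variable_positions(sim$beta, 0.3, 3)$calls)
    m3 <- nrow(call_variable_positions(sim$beta, 0.3, 4)$calls)
    expect_true(n2 >= m2 && m2 >= m3)
  }
})

test_that("planted methylomes are recovered against generator truth", {
  ev <- random_meth_events(50, 1000, seed = 7)
  noiseless <- simulate_methylome(meth_sim_config(1000, planted_events = ev,
                                                  noise_sd_logit = 0, seed = 7))
  calls <- call_variable_positions(noiseless$beta)$calls
  expect_equal(nrow(calls), 50)
  expect_setequal(paste(calls$cpg_id, calls$group, calls$direction),
                  paste(ev$cpg_id, ev$group, ev$direction))
  # per-group summary equals total calls (no dual-direction CpGs here)
  summ <- call_variable_positions(noiseless$beta)$summary
  expect_equal(sum(summ$hyper) + sum(summ$hypo), nrow(calls))
  expect_false(any(calls$dual))
})

test_that("annotation unions genes per group/direction with set semantics", {
  calls <- data.frame(cpg_id = c("c1", "c2", "c3"),
                      group = "depleted",
                      direction = c("hyper", "hyper", "hypo"),
                      stringsAsFactors = FALSE)
  ann <- data.frame(cpg_id = c("c1", "c2", "c2", "c4", "c5"),
                    gene = c("GENEA", "GENEA", "GENEB", "GENEC", "GENED"),
                    stringsAsFactors = FALSE)
  res <- annotate_calls(calls, ann)
  hyper <- res[res$direction == "hyper", ]
  expect_equal(hyper$n_genes, 2)
  expect_setequal(hyper$genes[[1]], c("GENEA", "GENEB"))
  expect_equal(hyper$n_unannotated, 0)
  hypo <- res[res$direction == "hypo", ]
  expect_equal(hypo$n_genes, 0)      # c3 is unannotated
  expect_equal(hypo$n_unannotated, 1)
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  # closed-form toy: drawing all 5 marked genes out of 10
  res <- hypergeometric_overlap(5, 5, 10, overlap = 5)
  expect_equal(res$p_upper, 1 / choose(10, 5), tolerance = 1e-12)

  # zero overlap of tiny sets in a huge universe
  expect_equal(hypergeometric_overlap(3, 3, 1e6, overlap = 0)$p_upper, 1,
               tolerance = 1e-4)

  # set-based interface
  res2 <- hypergeometric_overlap(c("a", "b", "c"), c("b", "c", "d"), 10)
  expect_equal(res2$overlap, 2)
  expect_equal(res2$p_upper, hyper_tail_oracle(2, 3, 10, 3), tolerance = 1e-12)

  # all configurations in small universes
  for (N in c(5, 12, 19)) {
    for (K in 0:N) for (n in 0:N) {
      lo <- max(0, n - (N - K)); hi <- min(n, K)
      for (x in lo:hi) {
        expect_equal(hypergeometric_overlap(K, n, N, overlap = x)$p_upper,
                     hyper_tail_oracle(x, K, N, n), tolerance = 1e-12)
      }
    }
  }
  expect_error(hypergeometric_overlap(5, 3, 10, overlap = 4), "overlap")
  expect_error(hypergeometric_overlap(11, 3, 10, overlap = 1), "universe")
})

test_that("over-representation ranks the matching set first", {
  coll <- list(HIT = paste0("h", 1:20),
               MISS1 = paste0("m", 1:20),
               MISS2 = paste0("q", 1:30))
  res <- enrich_gene_sets(paste0("h", 1:20), coll, universe_size = 100)
  expect_equal(res$set[1], "HIT")
  expect_equal(res$overlap[1], 20)
  expect_equal(res$coverage[1], 1)
  expect_true(all(res$p_upper[res$set != "HIT"] > 0.99))
  expect_true(all(res$padj >= res$p_upper))

  # disjoint query
  res2 <- enrich_gene_sets(paste0("z", 1:10), coll, universe_size = 100)
  expect_true(all(res2$p_upper > 0.99))
})

test_that("planted enrichment is recovered over seeds", {
  hits <- 0
  n_seeds <- 20
  universe <- paste0("u", 1:2000)
  set.seed(99)
  coll <- c(list(TARGET = universe[1:100]),
            lapply(1:10, function(i) universe[sample(2000, 80)]))
  names(coll)[-1] <- paste0("BG", 1:10)
  for (s in 1:n_seeds) {
    set.seed(s)
    query <- c(universe[sample(100, 50)], universe[sample(1901:2000, 50) + 0])
    res <- enrich_gene_sets(query, coll, universe_size = 2000)
    hits <- hits + (res$padj[res$set == "TARGET"] < 0.05)
  }
  expect_gte(hits, 19)
})

test_that("overlap network applies the overlap-coefficient definition", {
  coll <- list(A = paste0("g", 1:10), B = paste0("g", 1:10),
               C = paste0("g", 1:5), D = paste0("x", 1:8))
  enr <- enrich_gene_sets(paste0("g", 1:10), coll, universe_size = 50)
  net <- overlap_network(enr, coll, top_n = 4, min_overlap_coef = 0.25)
  ab <- net$edges[net$edges$set_a == "A" & net$edges$set_b == "B", ]
  expect_equal(ab$overlap_coefficient, 1)         # identical sets
  ac <- net$edges[net$edges$set_a == "A" & net$edges$set_b == "C", ]
  expect_equal(ac$overlap_coefficient, 1)         # nested: C subset of A
  expect_false(any(net$edges$set_a == "D" | net$edges$set_b == "D"))
  expect_equal(nrow(net$nodes), 4)
  # deterministic lexicographic ordering
  expect_true(all(net$edges$set_a < net$edges$set_b))
})
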