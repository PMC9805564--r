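test_that("unweighted running sum matches its closed form", {
  rl <- ranked_list(c("A", "B", "C", "D"), c(4, 3, 2, 1))
  rs <- running_enrichment(rl, c("A", "B"), weight_exponent = 0)
  expect_equal(rs$curve, c(0.5, 1, 0.5, 0))
  expect_equal(rs$es, 1)
  expect_equal(rs$peak_position, 2L)
  expect_equal(rs$hit_positions, c(1L, 2L))

  rs <- running_enrichment(rl, c("C", "D"), weight_exponent = 0)
  expect_equal(rs$es, -1)
  expect_equal(rs$peak_position, 2L)
})

test_that("running sum validates the membership preconditions", {
  rl <- ranked_list(c("A", "B", "C"), 3:1)
  expect_error(running_enrichment(rl, "ZZZ"), "not represented")
  expect_error(running_enrichment(rl, c("A", "B", "C")), "entire")
})

test_that("curve ends at zero and ES stays within [-1, 1]", {
  set.seed(21)
  for (i in 1:50) {
    inst <- random_instance(sample(20:100, 1), sample(3:15, 1))
    rs <- running_enrichment(inst$ranked, inst$members,
                             weight_exponent = sample(c(0, 0.5, 1, 2), 1))
    expect_lt(abs(rs$curve[length(rs$curve)]), 1e-9)
    expect_lte(abs(rs$es), 1)
    expect_equal(rs$es, rs$curve[rs$peak_position])
    expect_equal(abs(rs$es), max(abs(rs$curve)))
  }
})

test_that("weighted ES agrees with the incremental oracle", {
  set.seed(22)
  for (i in 1:50) {
    inst <- random_instance(50, 8)
    rs <- running_enrichment(inst$ranked, inst$members, weight_exponent = 1)
    orc <- oracle_running_es(inst$ranked$score, inst$hit, 1)
    expect_equal(rs$es, orc$es, tolerance = 1e-12)
    expect_equal(rs$peak_position, orc$peak)
  }
})

test_that("ES agrees with fgsea's statistic on random prerank instances", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (i in 1:25) {
    inst <- random_instance(sample(30:120, 1), sample(5:15, 1))
    stats <- stats::setNames(inst$ranked$score, inst$ranked$gene)
    for (p in c(0, 1)) {
      ours <- running_enrichment(inst$ranked, inst$members,
                                 weight_exponent = p)$es
      ref <- fgsea::calcGseaStat(stats, which(inst$hit), gseaParam = p)
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("negating and reversing the ranking negates the ES", {
  set.seed(24)
  for (i in 1:25) {
    inst <- random_instance(60, 10)
    rs1 <- running_enrichment(inst$ranked, inst$members)
    flipped <- ranked_list(inst$ranked$gene, -inst$ranked$score)
    rs2 <- running_enrichment(flipped, inst$members)
    expect_equal(rs2$es, -rs1$es, tolerance = 1e-12)
  }
})

test_that("position-only ES path matches the full-curve path", {
  set.seed(25)
  for (i in 1:50) {
    inst <- random_instance(80, 12)
    for (p in c(0, 1, 1.7)) {
      w_all <- abs(inst$ranked$score)^p
      if (p == 0) w_all <- rep(1, length(w_all))
      fast <- enrichkit:::.es_from_positions(which(inst$hit), w_all, 80)
      full <- running_enrichment(inst$ranked, inst$members,
                                 weight_exponent = p)$es
      expect_equal(fast, full, tolerance = 1e-12)
    }
  }
})

test_that("empirical p-values follow the add-one same-sign estimator", {
  nulls <- seq(0.001, 0.75, length.out = 100)      # 100 positive values
  expect_equal(empirical_pvalue(0.8, nulls), 1 / 101)
  # a null value exactly equal to the observed ES counts (>=)
  expect_equal(empirical_pvalue(max(nulls), nulls), 2 / 101)
  expect_equal(empirical_pvalue(0, nulls), 1)
  # mixed-sign null: only same-sign values used
  mixed <- c(nulls, -nulls)
  expect_equal(empirical_pvalue(0.8, mixed), 1 / 101)
  expect_warning(p <- empirical_pvalue(-0.5, nulls), "undefined-sign")
  expect_equal(p, 1)
})

test_that("NES divides by the same-sign null mean magnitude", {
  expect_equal(normalize_es(0.6, c(0.2, 0.3, 0.4, -0.9)), 2)
  expect_equal(normalize_es(-0.4, c(-0.1, -0.3, 0.5)), -2)
  expect_warning(nes <- normalize_es(-0.4, c(0.1, 0.2)), "undefined")
  expect_true(is.na(nes))
})

test_that("self-normalized null values average to +/- 1", {
  set.seed(26)
  null <- rnorm(2000, sd = 0.3)
  nn <- enrichkit:::.normalize_null(null)
  expect_equal(mean(nn[nn > 0]), 1, tolerance = 1e-12)
  expect_equal(mean(abs(nn[nn < 0])), 1, tolerance = 1e-12)
})

test_that("FDR q-values follow the tail-ratio formula", {
  q <- fdr_qvalues(c(2.5, 3.5), c(1, 2, 3, 4))
  expect_equal(q, c(0.5, 0.5))
  # observed less extreme than every null value of its sign
  expect_equal(fdr_qvalues(0.5, c(1, 2, 3)), 1)
  # every null value less extreme than every observed
  expect_equal(fdr_qvalues(c(5, 6), c(1, 2, 3, 4)), c(0, 0))
  # clipping and monotone enforcement keep q in [0, 1], non-decreasing as
  # |NES| decreases
  set.seed(27)
  obs <- rnorm(50, sd = 2)
  nulls <- rnorm(5000)
  q <- fdr_qvalues(obs, nulls)
  expect_true(all(q >= 0 & q <= 1))
  pos <- order(-obs[obs >= 0])
  qpos <- q[obs >= 0][pos]
  expect_true(all(diff(qpos) >= 0))
  neg <- order(obs[obs < 0])
  qneg <- q[obs < 0][neg]
  expect_true(all(diff(qneg) >= 0))
})

test_that("leading edge takes members at-or-before (or mirrored) the peak", {
  rl <- ranked_list(sprintf("G%02d", 1:10), 10:1)
  rs_pos <- structure(list(curve = numeric(10), hit_positions = c(2L, 5L, 9L),
                           es = 0.4, peak_position = 5L),
                      class = "RunningSum")
  expect_equal(leading_edge(rs_pos, rl), c("G02", "G05"))
  rs_neg <- rs_pos
  rs_neg$es <- -0.4
  expect_equal(leading_edge(rs_neg, rl), c("G05", "G09"))
  # all hits before a positive peak -> the whole matched set
  rs_all <- structure(list(curve = numeric(10), hit_positions = c(1L, 2L, 3L),
                           es = 0.6, peak_position = 8L),
                      class = "RunningSum")
  expect_equal(leading_edge(rs_all, rl), c("G01", "G02", "G03"))
})

test_that("gene-permutation nulls have the default 1000 draws per set", {
  spec <- plant_spec(universe_size = 300, n_sets = 3,
                     set_size_range = c(15, 20), effect_size = 0, seed = 31)
  lib <- make_library(spec)
  rnk <- make_ranked(spec, lib)
  null <- build_null(rnk, lib, enrichment_params(seed = 31))
  expect_length(null$per_set_es, 3L)
  expect_true(all(lengths(null$per_set_es) == 1000L))
})

test_that("null distributions are reproducible and set-order invariant", {
  spec <- plant_spec(universe_size = 200, n_sets = 4,
                     set_size_range = c(15, 20), effect_size = 0, seed = 32)
  lib <- make_library(spec)
  rnk <- make_ranked(spec, lib)
  params <- enrichment_params(n_permutations = 50, seed = 32)
  n1 <- build_null(rnk, lib, params)
  n2 <- build_null(rnk, lib, params)
  expect_identical(n1$per_set_es, n2$per_set_es)
  # reversing library order leaves each set's stream untouched
  rev_lib <- gene_set_library(rev(lib$sets), lib$descriptions)
  n3 <- build_null(rnk, rev_lib, params)
  expect_identical(n3$per_set_es[names(n1$per_set_es)], n1$per_set_es)
})

test_that("gene-permutation null mean matches a Monte-Carlo oracle", {
  set.seed(33)
  n <- 200
  rl <- ranked_list(sprintf("G%03d", 1:n), rnorm(n))
  lib <- gene_set_library(list(S1 = sample(rl$gene, 20)))
  null <- build_null(rl, lib,
                     enrichment_params(n_permutations = 2000, seed = 33))
  # independent simulation: incremental-oracle ES of random subsets
  draws <- vapply(1:10000, function(i) {
    hit <- logical(n)
    hit[sample.int(n, 20)] <- TRUE
    oracle_running_es(rl$score, hit, 1)$es
  }, numeric(1))
  se <- sqrt(stats::var(draws) / 10000 + stats::var(null$per_set_es$S1) / 2000)
  expect_lt(abs(mean(null$per_set_es$S1) - mean(draws)), 3 * se)
})

test_that("phenotype permutation preserves class sizes and reproduces", {
  spec <- plant_spec(universe_size = 120, n_sets = 3,
                     set_size_range = c(15, 20), effect_size = 1,
                     n_samples_per_class = 4, seed = 34)
  lib <- make_library(spec)
  ds <- make_expression(spec, lib)
  params <- enrichment_params(n_permutations = 30,
                              permutation_type = "phenotype", seed = 34)
  n1 <- build_null(ds, lib, params)
  n2 <- build_null(ds, lib, params)
  expect_identical(n1$per_set_es, n2$per_set_es)
  expect_true(all(lengths(n1$per_set_es) == 30L))
  expect_error(build_null(expression_dataset(ds$values), lib, params),
               "phenotypes")
})

test_that("size filtering skips sets and errors when nothing is left", {
  rl <- ranked_list(sprintf("G%03d", 1:100), rnorm(100))
  lib <- gene_set_library(list(TINY = rl$gene[1:3],
                               OK = rl$gene[seq(2, 60, 2)]))
  res <- run_prerank(rl, lib, enrichment_params(n_permutations = 20,
                                                seed = 35))
  expect_equal(res$skipped$term, "TINY")
  expect_equal(res$skipped$reason, "below min_set_size")
  expect_equal(res$results$term, "OK")

  lib_tiny <- gene_set_library(list(TINY = rl$gene[1:3]))
  expect_error(run_prerank(rl, lib_tiny, enrichment_params()),
               "min_set_size")
})

test_that("run_prerank is deterministic under a fixed seed", {
  spec <- plant_spec(universe_size = 400, n_sets = 6,
                     set_size_range = c(15, 30), effect_size = 1, seed = 36)
  lib <- make_library(spec)
  rnk <- make_ranked(spec, lib)
  params <- enrichment_params(n_permutations = 100, seed = 36)
  r1 <- run_prerank(rnk, lib, params)
  r2 <- run_prerank(rnk, lib, params)
  expect_identical(r1$results, r2$results)
})

test_that("phenotype-permutation GSEA recovers a planted set", {
  hits_top <- 0L
  hits_q <- 0L
  for (seed in 1:5) {
    spec <- plant_spec(universe_size = 500, n_sets = 10,
                       set_size_range = c(20, 20), planted_sets = "SET001",
                       effect_size = 2, n_samples_per_class = 5,
                       seed = seed)
    lib <- make_library(spec)
    ds <- make_expression(spec, lib)
    res <- run_gsea(ds, lib,
                    enrichment_params(n_permutations = 200,
                                      permutation_type = "phenotype",
                                      seed = seed))
    top <- res$results$term[which.max(res$results$nes)]
    if (identical(top, "SET001")) hits_top <- hits_top + 1L
    if (res$results$fdr[res$results$term == "SET001"] < 0.05)
      hits_q <- hits_q + 1L
  }
  expect_gte(hits_top, 4L)
  expect_gte(hits_q, 4L)
})

test_that("enrichment reports round-trip through the TSV writer", {
  spec <- plant_spec(universe_size = 300, n_sets = 4,
                     set_size_range = c(15, 25), effect_size = 1.5,
                     seed = 37)
  lib <- make_library(spec)
  rnk <- make_ranked(spec, lib)
  res <- run_prerank(rnk, lib, enrichment_params(n_permutations = 50,
                                                 seed = 37))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$Term, res$results$term)
  expect_equal(back$NES, res$results$nes, tolerance = 1e-12)

  curve_path <- withr::local_tempfile(fileext = ".tsv")
  write_curve_tsv(res, res$results$term[1], rnk, curve_path)
  curve <- utils::read.delim(curve_path)
  expect_equal(nrow(curve), nrow(rnk))
  expect_equal(curve$curve, res$running[[res$results$term[1]]]$curve,
               tolerance = 1e-12)
})
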