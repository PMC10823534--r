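test_that("the default study-like spec validates and has five clusters", {
  spec <- default_study_spec()
  expect_s3_class(spec, "csa_sim_spec")
  expect_equal(nrow(spec$clusters), 5)
  expect_equal(length(spec$genes), 1000)
  expect_equal(length(spec$cell_cycle_genes), 300)
  expect_true(all(abs(colSums(spec$proportions) - 1) < 1e-9))
  # the five mitosis markers are planted in both proliferating clusters
  five <- c("AURKB", "MKI67", "INCENP", "BIRC5", "CDCA8")
  prolif <- spec$clusters$name[spec$clusters$proliferating]
  for (cl in prolif) {
    expect_true(all(five %in%
                      spec$markers$gene[spec$markers$cluster == cl]))
  }
})

test_that("spec validation rejects inconsistent inputs", {
  spec <- default_study_spec()
  bad_prop <- spec$proportions; bad_prop[1, 1] <- bad_prop[1, 1] + 0.1
  expect_error(sim_spec(spec$genes, spec$cell_cycle_genes, spec$clusters,
                        spec$strata, bad_prop, spec$markers),
               "sum to 1")
  bad_mark <- spec$markers
  bad_mark$prop_in[1] <- 0
  expect_error(sim_spec(spec$genes, spec$cell_cycle_genes, spec$clusters,
                        spec$strata, spec$proportions, bad_mark),
               "infeasible")
  bad_fold <- spec$markers
  bad_fold$fold_change[1] <- 0.5
  expect_error(sim_spec(spec$genes, spec$cell_cycle_genes, spec$clusters,
                        spec$strata, spec$proportions, bad_fold),
               "fold_change")
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec <- default_study_spec()
  a <- simulate_counts(spec, seed = 5)
  b <- simulate_counts(spec, seed = 5)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$cluster, b$truth$cluster)
  c <- simulate_counts(spec, seed = 6)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("a fold-free single-cluster spec gives exchangeable genes", {
  genes <- sprintf("G%03d", 1:40)
  spec <- sim_spec(genes, genes[1:5],
                   clusters = data.frame(name = "C1", class = "VEC",
                                         proliferating = FALSE),
                   strata = data.frame(group = "CTL", timepoint = "P28",
                                       n_cells = 2000),
                   proportions = matrix(1, 1, 1),
                   baseline_mu = 0.5, dispersion = 2)
  sim <- simulate_counts(spec, seed = 23)
  # per-gene mean / mu ratios constant across genes within 5%
  ratios <- colMeans(sim$counts$counts) / 0.5
  expect_lt(max(abs(ratios / mean(ratios) - 1)), 0.05)
})

test_that("planted expressing fractions are matched within 0.05", {
  genes <- sprintf("G%03d", 1:50)
  spec <- sim_spec(genes, genes[1:5],
                   clusters = data.frame(name = c("A", "B"),
                                         class = c("VEC", "VEC"),
                                         proliferating = FALSE),
                   strata = data.frame(group = "CTL", timepoint = "P28",
                                       n_cells = 1500),
                   proportions = matrix(c(1 / 3, 2 / 3), 2, 1),
                   markers = data.frame(cluster = "A", gene = "G010",
                                        fold_change = 8, prop_in = 0.6,
                                        prop_out = 0.02))
  sim <- simulate_counts(spec, seed = 29)
  lab <- sim$truth$cluster
  x <- sim$counts$counts[, "G010"]
  expect_lt(abs(mean(x[lab == "A"] > 0) - 0.6), 0.05)
  expect_lt(abs(mean(x[lab == "B"] > 0) - 0.02), 0.02)
})

test_that("planted fold-changes are recovered among expressing cells", {
  spec <- default_study_spec()
  checks <- data.frame(gene = c("CD34", "PDGFRA", "AURKB"),
                       cluster = c("VEC1", "VEC3", "VEC1"),
                       fold = c(4, 8, 6))
  for (s in 1:5) {
    sim <- simulate_counts(spec, seed = s)
    lab <- sim$truth$cluster
    X <- sim$counts$counts
    depth <- rowSums(X)
    for (r in seq_len(nrow(checks))) {
      v <- X[, checks$gene[r]] / depth      # depth-normalized expression
      inn <- lab == checks$cluster[r] & X[, checks$gene[r]] > 0
      # out-group: clusters where the gene is not planted as a marker
      owners <- spec$markers$cluster[spec$markers$gene == checks$gene[r]]
      out <- !(lab %in% owners) & X[, checks$gene[r]] > 0
      got <- mean(v[inn]) / mean(v[out])
      expect_equal(got, checks$fold[r], tolerance = 0.3 * checks$fold[r],
                   label = sprintf("%s seed %d", checks$gene[r], s))
    }
  }
})

test_that("gradient simulation stages the markers where planted", {
  g <- simulate_gradient(n_cells = 600, seed = 11)
  expect_identical(simulate_gradient(n_cells = 600, seed = 11)$counts$counts,
                   g$counts$counts)
  t <- g$truth$t
  norm <- log_normalize(g$counts)
  bins <- cut(t, seq(0, 1, 0.05), include.lowest = TRUE)
  for (i in seq_along(g$truth$markers)) {
    v <- norm$values[, g$truth$markers[i]]
    means <- tapply(v, bins, mean)
    peak <- seq(0.025, 0.975, 0.05)[which.max(means)]
    expect_lt(abs(peak - g$truth$stages[i]), 0.1)
  }
  # no stages -> plain one-population data
  flat <- simulate_gradient(n_cells = 100, markers = character(0),
                            stages = numeric(0), seed = 2)
  expect_equal(nrow(flat$counts$counts), 100)
  expect_error(simulate_gradient(stages = c(0.5, 0.2),
                                 markers = c("A", "B")),
               "increasing")
})

test_that("branched simulation carries aligned arm and depth truth", {
  br <- simulate_branched(300, seed = 3)
  expect_equal(length(br$truth$arm), 300)
  expect_equal(length(br$truth$t), 300)
  # arm modules are expressed where planted (raw scale: the log1p
  # transform compresses the planted ratio)
  X <- br$counts$counts
  m1 <- mean(X[br$truth$arm == 1 & br$truth$t > 0.5, "ARM1_01"])
  m2 <- mean(X[br$truth$arm == 2 & br$truth$t > 0.5, "ARM1_01"])
  expect_gt(m1, 2 * m2)
})
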