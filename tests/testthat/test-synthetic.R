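test_that("generation is reproducible from the seed", {
  cfg <- sim_config(n_sequences = 40, length = 80, seed = 7)
  a <- generate_cluster(cfg)
  b <- generate_cluster(cfg)
  expect_identical(a$cluster$mat, b$cluster$mat)
  expect_identical(a$truth$planted_pairs, b$truth$planted_pairs)
  expect_identical(assign_disease_labels(a$truth, cfg),
                   assign_disease_labels(b$truth, cfg))
  st1 <- generate_toy_structure(a$truth, 0.5, seed = 3)
  st2 <- generate_toy_structure(b$truth, 0.5, seed = 3)
  expect_identical(st1$atoms, st2$atoms)
})

test_that("the reference row is gap-free and planted columns are disjoint", {
  cfg <- sim_config(n_sequences = 50, length = 100, gap_rate = 0.1,
                    n_coevolving_pairs = 4, n_conserved_columns = 10,
                    seed = 9)
  g <- generate_cluster(cfg)
  ref <- g$cluster$mat[g$cluster$reference_index, ]
  expect_false(any(ref == "-"))
  expect_equal(reference_length(g$cluster), 100L)
  planted <- c(g$truth$planted_pairs$pos_i, g$truth$planted_pairs$pos_j)
  expect_false(any(duplicated(planted)))
  expect_length(intersect(planted, g$truth$conserved_columns), 0L)
})

test_that("perfect coupling gives identical row partitions at planted columns", {
  cfg <- sim_config(n_sequences = 20, length = 40, n_coevolving_pairs = 1,
                    coupling_fidelity = 1, gap_rate = 0, seed = 3)
  g <- generate_cluster(cfg)
  p <- g$truth$planted_pairs
  col_i <- g$cluster$mat[, p$pos_i[1]]
  col_j <- g$cluster$mat[, p$pos_j[1]]
  # state partitions identical row by row
  expect_true(all((col_i == "A") == (col_j == "V")))
  expect_true(all((col_i == "S") == (col_j == "T")))
})

test_that("fidelity 0.5 with two states makes planted columns independent", {
  # cross pairs (column i of pair k vs column j of pair l != k) have the
  # same two-state marginal structure but are independent by construction;
  # at fidelity 0.5 the planted pairs must look just like them on average,
  # while at high fidelity they must dwarf them
  mean_scores <- function(fidelity, seed) {
    cfg <- sim_config(n_sequences = 200, length = 300,
                      n_coevolving_pairs = 10, coupling_fidelity = fidelity,
                      n_conserved_columns = 0, gap_rate = 0, seed = seed)
    g <- generate_cluster(cfg)
    p <- g$truth$planted_pairs
    scores <- omes_pairs(g$cluster)
    key <- paste(scores$pos_i, scores$pos_j)
    true_keys <- paste(p$pos_i, p$pos_j)
    cross <- tidyr::expand_grid(k = seq_len(10), l = seq_len(10))
    cross <- cross[cross$k != cross$l, ]
    cross_keys <- paste(pmin(p$pos_i[cross$k], p$pos_j[cross$l]),
                        pmax(p$pos_i[cross$k], p$pos_j[cross$l]))
    c(true = mean(scores$score[key %in% true_keys]),
      cross = mean(scores$score[key %in% cross_keys]))
  }
  m05 <- mean_scores(0.5, seed = 13)
  expect_lt(m05[["true"]], 3 * m05[["cross"]])
  expect_gt(m05[["true"]], m05[["cross"]] / 3)
  m95 <- mean_scores(0.95, seed = 13)
  expect_gt(m95[["true"]], 10 * m95[["cross"]])
})

test_that("label rates follow fold x rate with binomial error", {
  # fold 1: planted and background rates equal within sampling error
  tr <- manual_truth(tibble::tibble(pos_i = seq(1L, 2500L, by = 25L),
                                    pos_j = seq(13L, 2512L, by = 25L)), 10000L)
  cfg1 <- sim_config(n_sequences = 30, length = 10000,
                     n_coevolving_pairs = 100, disease_fold = 1,
                     background_disease_rate = 0.02, seed = 5)
  lab1 <- assign_disease_labels(tr, cfg1, seed = 15)
  rate_planted <- mean(tr$planted_positions %in% lab1$position)
  bg_pos <- setdiff(seq_len(10000), tr$planted_positions)
  rate_bg <- mean(bg_pos %in% lab1$position)
  # both near 0.02; planted set has 200 positions, se ~ 0.01
  expect_lt(abs(rate_planted - rate_bg), 0.03)

  # fold 1.66 at large n: empirical rate ratio approaches 1.66
  tr2 <- manual_truth(tibble::tibble(pos_i = seq(1L, 50000L, by = 25L),
                                     pos_j = seq(13L, 50012L, by = 25L)),
                      200000L)
  cfg2 <- sim_config(n_sequences = 30, length = 200000,
                     n_coevolving_pairs = 2000, disease_fold = 1.66,
                     background_disease_rate = 0.019, seed = 5)
  lab2 <- assign_disease_labels(tr2, cfg2, seed = 16)
  rp <- mean(tr2$planted_positions %in% lab2$position)
  bg2 <- setdiff(seq_len(200000), tr2$planted_positions)
  rb <- mean(bg2 %in% lab2$position)
  expect_equal(rp / rb, 1.66, tolerance = 0.15)

  # rate 0: no labels
  cfg0 <- sim_config(n_sequences = 30, length = 10000,
                     n_coevolving_pairs = 100,
                     background_disease_rate = 0, seed = 5)
  expect_equal(nrow(assign_disease_labels(tr, cfg0)), 0L)

  # fold x rate > 1 clamps with a warning
  cfg_cl <- sim_config(n_sequences = 30, length = 10000,
                       n_coevolving_pairs = 100, disease_fold = 100,
                       background_disease_rate = 0.5, seed = 5)
  expect_warning(labc <- assign_disease_labels(tr, cfg_cl), "clamped")
  expect_true(all(tr$planted_positions %in% labc$position))
})

test_that("toy structures realize the requested contact fraction", {
  pairs100 <- tibble::tibble(pos_i = seq(1L, 1 + 99L * 13L, by = 13L),
                             pos_j = seq(13L, 13L * 100L, by = 13L))
  tr <- manual_truth(pairs100, 1300L)
  # direct distance oracle on the emitted coordinates
  count_contacts <- function(st) {
    a <- st$atoms
    vapply(seq_len(nrow(pairs100)), function(k) {
      ai <- as.matrix(a[a$position == pairs100$pos_i[k], c("x", "y", "z")])
      aj <- as.matrix(a[a$position == pairs100$pos_j[k], c("x", "y", "z")])
      d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
      min(sqrt(pmax(d2, 0)))
    }, numeric(1))
  }
  st0 <- generate_toy_structure(tr, 0, seed = 1)
  expect_true(all(count_contacts(st0) > 8.0))
  st1 <- generate_toy_structure(tr, 1, seed = 1)
  expect_true(all(count_contacts(st1) < 5.5))
  st164 <- generate_toy_structure(tr, 0.164, seed = 1)
  d <- count_contacts(st164)
  expect_equal(sum(d < 5.5), 16L)
  expect_equal(sum(d > 8.0), 84L)
  expect_equal(nrow(st164$contact_pairs), 16L)
  # adjacent backbone spacing ~3.8 A
  ca <- st164$atoms[st164$atoms$elety == "CA", ]
  expect_equal(diff(ca$x[1:2]), 3.8)
})

test_that("infeasible configurations error out", {
  expect_error(sim_config(length = 5, n_coevolving_pairs = 3), "too small")
  # pairs cannot be separated by > 10 on a tiny alignment
  cfg <- sim_config(length = 12, n_coevolving_pairs = 3,
                    n_conserved_columns = 0, seed = 2)
  expect_error(generate_cluster(cfg), "separation")
})
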