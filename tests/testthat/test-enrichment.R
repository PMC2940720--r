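test_that("LOD matches direct rational arithmetic on random tables", {
  set.seed(41)
  for (i in 1:2000) {
    t <- random_table()
    ct <- contingency_table(t["n"], t["d"], t["c"], t["dc"])
    er <- compute_lod(ct)
    expect_equal(er$lod, lod_oracle(t["n"], t["d"], t["c"], t["dc"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(er$fold, 2^er$lod, tolerance = 1e-12)
  }
})

test_that("LOD handles proportional, degenerate and boundary tables", {
  # proportional table: fold 1, LOD 0
  er <- compute_lod(contingency_table(100, 10, 20, 2))
  expect_equal(er$lod, 0)
  expect_equal(er$fold, 1)
  # dc = 0: -Inf, flagged
  er0 <- compute_lod(contingency_table(1000, 10, 50, 0))
  expect_identical(er0$lod, -Inf)
  expect_false(er0$defined)
  # c = 0 or d = 0: explicit error
  expect_error(compute_lod(contingency_table(100, 10, 0, 0)), "undefined")
  expect_error(compute_lod(contingency_table(100, 0, 10, 0)), "undefined")
  # invalid counts refused
  expect_error(contingency_table(100, 10, 20, 15), "inconsistent")
})

test_that("LOD is strictly increasing in dc with margins fixed", {
  lods <- vapply(1:19, function(dc) {
    compute_lod(contingency_table(1000, 20, 50, dc))$lod
  }, numeric(1))
  expect_true(all(diff(lods) > 0))
})

test_that("Fisher test reproduces the closed-form hypergeometric tail", {
  # n=40, d=20, c=20, dc=20: only one arrangement at least this extreme
  p <- fisher_test(contingency_table(40, 20, 20, 20))
  expect_equal(p, 1 / choose(40, 20), tolerance = 1e-12)
  # proportional table: one-sided p >= 0.5
  expect_gte(fisher_test(contingency_table(100, 10, 20, 2)), 0.5)
  # agreement with stats::fisher.test as an independent cross-check
  ct <- contingency_table(500, 40, 60, 12)
  m <- matrix(c(12, 48, 28, 412), 2, byrow = TRUE)
  expect_equal(fisher_test(ct, "two_sided"), fisher.test(m)$p.value)
})

test_that("counting from position sets builds the right table", {
  uni <- tidyr::expand_grid(protein_id = c("A", "B"), position = 1:50)
  dis <- tibble::tibble(protein_id = "A", position = 1:10)
  pred <- tibble::tibble(protein_id = c("A", "A", "B"),
                         position = c(5L, 11L, 1L))
  ct <- count_contingency(uni, dis, pred)
  expect_equal(unlist(ct[c("n", "d", "c", "dc")], use.names = FALSE),
               c(100, 10, 3, 1))
  # labels outside the universe are ignored
  dis2 <- dplyr::bind_rows(dis,
                           tibble::tibble(protein_id = "Z", position = 1L))
  expect_equal(count_contingency(uni, dis2, pred)$d, 10)
})

test_that("permutation null is seeded, centred and add-one corrected", {
  set.seed(43)
  uni <- tibble::tibble(protein_id = "P", position = 1:50000)
  dis <- tibble::tibble(protein_id = "P",
                        position = sample(50000, 2500))
  pred <- tibble::tibble(protein_id = "P",
                         position = sample(50000, 4000))
  pn1 <- permutation_null(uni, dis, pred, reps = 1000, seed = 7)
  pn2 <- permutation_null(uni, dis, pred, reps = 1000, seed = 7)
  expect_identical(pn1$null_lods, pn2$null_lods)
  # null mean near 0 on label-shuffled data
  expect_lt(abs(mean(pn1$null_lods)), 0.02)
  # under a full label shuffle the overlap count is hypergeometric; the
  # null LOD quantiles must match that closed form
  expected_dc <- 4000 * 2500 / 50000
  for (p in c(0.25, 0.5, 0.75)) {
    expect_lt(abs(quantile(pn1$null_lods, p)[[1]] -
                    log2(qhyper(p, 2500, 50000 - 2500, 4000) / expected_dc)),
              0.02)
  }
  # +1 correction keeps p in (0, 1]
  expect_gt(pn1$p_empirical, 0)
  expect_lte(pn1$p_empirical, 1)
})

test_that("column bootstrap is seeded and degenerate alignments give a constant", {
  # every protein has one position: resampling with replacement of a single
  # column reproduces the same data set every time
  res1 <- tibble::tibble(protein_id = paste0("P", 1:40),
                         position = 1L,
                         disease = rep(c(TRUE, FALSE), each = 20),
                         predictor = rep(c(TRUE, FALSE), times = 20))
  cb <- column_bootstrap(res1, reps = 50, seed = 2)
  expect_true(all(cb$boot_lods == cb$observed))
  expect_equal(unname(cb$ci["lower"]), cb$observed)

  set.seed(44)
  res2 <- tibble::tibble(protein_id = rep(c("A", "B"), each = 200),
                         position = rep(1:200, 2),
                         disease = runif(400) < 0.3,
                         predictor = runif(400) < 0.2)
  a <- column_bootstrap(res2, reps = 200, seed = 5)
  b <- column_bootstrap(res2, reps = 200, seed = 5)
  expect_identical(a$boot_lods, b$boot_lods)
  # observed inside its own central 95% bootstrap interval
  expect_gte(a$observed, a$ci[["lower"]])
  expect_lte(a$observed, a$ci[["upper"]])
})

test_that("per-protein LODs flag dc = 0 proteins and score the rest", {
  uni <- tidyr::expand_grid(protein_id = c("A", "B", "C"), position = 1:100)
  dis <- tibble::tibble(protein_id = c("A", "B", rep("C", 10)),
                        position = c(1L, 99L, 1:10))
  pred <- tidyr::expand_grid(protein_id = c("A", "B", "C"), position = 1:20)
  pp <- per_protein_lods(uni, dis, pred)
  a <- pp[pp$protein_id == "A", ]  # d=1, dc=1: fold = (1/20)/(1/100) = 5
  expect_equal(a$lod, log2(5))
  b <- pp[pp$protein_id == "B", ]  # d=1, dc=0 -> -Inf, excluded
  expect_identical(b$lod, -Inf)
  expect_true(b$excluded)
  c_ <- pp[pp$protein_id == "C", ]  # proportional-ish: dc=10? no, dc = 10
  expect_equal(c_$dc, 10)
})

test_that("stratified LOD equals the global LOD on the full universe", {
  set.seed(45)
  uni <- tibble::tibble(protein_id = "P", position = 1:2000)
  dis <- tibble::tibble(protein_id = "P", position = sample(2000, 150))
  pred <- tibble::tibble(protein_id = "P", position = sample(2000, 300))
  st <- stratified_lod(uni, dis, pred,
                       strata = list(all = uni, none = uni[0, ]))
  glob <- compute_lod(count_contingency(uni, dis, pred))
  expect_equal(st$lod[st$stratum == "all"], glob$lod)
  expect_false(st$defined[st$stratum == "none"])
})

test_that("tidiers return one-row summaries", {
  er <- enrich(tibble::tibble(protein_id = "P", position = 1:100),
               tibble::tibble(protein_id = "P", position = 1:10),
               tibble::tibble(protein_id = "P", position = 5:24))
  td <- tidy(er)
  expect_equal(nrow(td), 1L)
  expect_equal(td$dc, 6)
  expect_false(is.na(td$p_fisher))
  pn <- permutation_null(tibble::tibble(protein_id = "P", position = 1:200),
                         tibble::tibble(protein_id = "P", position = 1:30),
                         tibble::tibble(protein_id = "P", position = 11:50),
                         reps = 100, seed = 1)
  expect_equal(nrow(tidy(pn)), 100L)
  expect_equal(glance(pn)$reps, 100)
})
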