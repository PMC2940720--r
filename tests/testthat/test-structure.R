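# two-residue helper: one CB atom each at a chosen distance
two_residue_atoms <- function(pos_i, pos_j, dist) {
  tibble::tibble(position = c(pos_i, pos_j),
                 resid = "ALA", elety = "CB",
                 x = c(0, dist), y = 0, z = 0)
}

test_that("contact definition applies the distance and window boundaries", {
  # min distance 5.4, |i-j| = 15: contact at 5.5
  expect_equal(nrow(contact_map(two_residue_atoms(1, 16, 5.4))), 1L)
  # same distance but |i-j| = 9: inside the 10-position window, no contact
  expect_equal(nrow(contact_map(two_residue_atoms(1, 10, 5.4))), 0L)
  # |i-j| = 10 is still inside the window (separation must exceed it)
  expect_equal(nrow(contact_map(two_residue_atoms(1, 11, 5.4))), 0L)
  expect_equal(nrow(contact_map(two_residue_atoms(1, 12, 5.4))), 1L)
  # distance above the threshold: no contact
  expect_equal(nrow(contact_map(two_residue_atoms(1, 16, 5.6))), 0L)
})

test_that("contact sets shrink as the threshold drops or the window grows", {
  tr <- manual_truth(tibble::tibble(pos_i = c(1L, 20L, 40L),
                                    pos_j = c(15L, 34L, 55L)), 60L)
  st <- generate_toy_structure(tr, contact_fraction = 1, seed = 2)
  n_at <- function(th, w) nrow(contact_map(st$atoms, threshold = th, window = w))
  expect_gte(n_at(8.0, 10), n_at(5.5, 10))
  expect_gte(n_at(5.5, 10), n_at(4.5, 10))
  expect_gte(n_at(5.5, 0), n_at(5.5, 10))
  expect_gte(n_at(5.5, 10), n_at(5.5, 20))
})

test_that("side-chain and C-beta modes agree on unambiguous toy geometry", {
  tr <- manual_truth(tibble::tibble(pos_i = c(5L, 30L), pos_j = c(20L, 50L)), 60L)
  st <- generate_toy_structure(tr, contact_fraction = 0.5, seed = 4)
  key <- function(d) paste(d$pos_i, d$pos_j)
  sc <- contact_map(st$atoms, mode = "sidechain_min")  # 5.5 default
  cb <- contact_map(st$atoms, mode = "cbeta")          # 8.0 default
  planted <- key(tr$planted_pairs)
  expect_setequal(intersect(key(sc), planted), key(st$contact_pairs))
  expect_setequal(intersect(key(cb), planted), key(st$contact_pairs))
})

test_that("glycine falls back to CA in both atom selections", {
  atoms <- tibble::tibble(
    position = c(1L, 1L, 20L), resid = c("GLY", "GLY", "ALA"),
    elety = c("N", "CA", "CB"),
    x = c(10, 0, 3), y = 0, z = 0)
  # GLY has no side chain: CA used, distance 3 -> contact
  expect_equal(nrow(contact_map(atoms, threshold = 5.5, window = 10)), 1L)
  # in cbeta mode residue 1 has no CB either: CA fallback again
  expect_equal(nrow(contact_map(atoms, mode = "cbeta", window = 10)), 1L)
})

test_that("accessibility classes follow the RSA thresholds", {
  rec <- tibble::tibble(position = 1:3, aa = c("A", "A", "A"),
                        asa = c(0, 129, 0.2 * 129))
  out <- classify_accessibility(rec)
  expect_equal(out$class, c("buried", "exposed", "intermediate"))
  expect_equal(out$rsa, c(0, 1, 0.2))
  # order independence: a permutation classifies identically per position
  out2 <- classify_accessibility(rec[c(3, 1, 2), ])
  expect_equal(out2$class[order(out2$position)],
               out$class[order(out$position)])
  # unknown residue types are skipped with a warning
  rec_bad <- tibble::tibble(position = 1:2, aa = c("A", "X"), asa = c(10, 10))
  expect_warning(out3 <- classify_accessibility(rec_bad), "unknown")
  expect_equal(nrow(out3), 1L)
})

test_that("contact overlap summarises selected pairs against contacts", {
  sel <- tibble::tibble(pos_i = c(1L, 2L, 3L), pos_j = c(20L, 30L, 40L))
  contacts <- tibble::tibble(pos_i = 1L, pos_j = 20L, min_dist = 4.2)
  ov <- contact_overlap(sel, contacts)
  expect_equal(ov$n_contact, 1L)
  expect_equal(ov$fraction_contact, 1 / 3)
  expect_setequal(ov$non_contact_positions, c(2L, 3L, 30L, 40L))
  expect_true(ov$positions$has_contact_correlation[ov$positions$position == 1])
  # zero contacts: all correlated positions are non-contact
  ov0 <- contact_overlap(sel, contacts[0, ])
  expect_equal(ov0$fraction_contact, 0)
  expect_setequal(ov0$non_contact_positions,
                  c(sel$pos_i, sel$pos_j))
  # all pairs in contact
  ov1 <- contact_overlap(sel, dplyr::mutate(sel, min_dist = 4))
  expect_equal(ov1$fraction_contact, 1)
  expect_length(ov1$non_contact_positions, 0L)
})

test_that("PDB round trip preserves toy coordinates and contacts", {
  tr <- manual_truth(tibble::tibble(pos_i = c(3L, 25L), pos_j = c(18L, 40L)), 50L)
  st <- generate_toy_structure(tr, contact_fraction = 1, seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, f)
  atoms2 <- read_structure_pdb(f)
  expect_equal(nrow(atoms2), nrow(st$atoms))
  key <- function(d) paste(d$pos_i, d$pos_j)
  expect_setequal(intersect(key(contact_map(atoms2)), key(tr$planted_pairs)),
                  key(st$contact_pairs))
})
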