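# Independent oracles used to cross-check the package implementations.

AA20_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Brute-force OMES score for one column pair of a character matrix:
# explicit loop over rows filling a residue-pair count table, then the sum
# over observed pairs of (obs - exp)^2 / n_valid. Independent of the
# compiled scan in every step.
omes_oracle <- function(mat, col_i, col_j) {
  joint <- list()
  ci <- integer(0)
  cj <- integer(0)
  nv <- 0L
  for (s in seq_len(nrow(mat))) {
    x <- mat[s, col_i]
    y <- mat[s, col_j]
    if (x == "-" || y == "-") next
    nv <- nv + 1L
    kxy <- paste(x, y)
    joint[[kxy]] <- (joint[[kxy]] %||% 0L) + 1L
    ci[x] <- (if (is.na(ci[x])) 0L else ci[x]) + 1L
    cj[y] <- (if (is.na(cj[y])) 0L else cj[y]) + 1L
  }
  if (nv == 0L) return(NA_real_)
  score <- 0
  for (kxy in names(joint)) {
    xy <- strsplit(kxy, " ", fixed = TRUE)[[1L]]
    n_ex <- ci[[xy[1L]]] * cj[[xy[2L]]] / nv
    score <- score + (joint[[kxy]] - n_ex)^2 / nv
  }
  score
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random gappy alignment as a character matrix (rows = sequences)
random_alignment <- function(n, l, gap_rate = 0.05, n_letters = 6) {
  letters20 <- AA20_TEST[seq_len(n_letters)]
  mat <- matrix(sample(letters20, n * l, replace = TRUE), nrow = n)
  if (gap_rate > 0) mat[runif(n * l) < gap_rate] <- "-"
  rownames(mat) <- paste0("s", seq_len(n))
  mat
}

# direct rational-arithmetic LOD oracle
lod_oracle <- function(n, d, c, dc) {
  log2((as.numeric(dc) * as.numeric(n)) / (as.numeric(c) * as.numeric(d)))
}

# random valid contingency table
random_table <- function() {
  n <- sample(50:100000, 1)
  d <- sample(1:max(1, floor(n / 3)), 1)
  c <- sample(1:max(1, floor(n / 3)), 1)
  dc <- sample(0:min(d, c), 1)
  if ((d - dc) > (n - c)) dc <- d - (n - c)
  c(n = n, d = d, c = c, dc = dc)
}

# a synthetic_truth object without running the generator (for structure
# tests that only need planted pair geometry)
manual_truth <- function(pairs, length) {
  structure(list(protein_id = "MAN1", planted_pairs = pairs,
                 conserved_columns = integer(0),
                 planted_positions = sort(c(pairs$pos_i, pairs$pos_j)),
                 length = length),
            class = "synthetic_truth")
}
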