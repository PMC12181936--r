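# Shared fixtures, computed lazily and cached for the whole test run (the
# chemistry-backed landscape is the expensive piece).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_landscape <- function() {
  cached("landscape", generate_landscape())
}

test_pipeline <- function() {
  cached("pipeline", suppressMessages(suppressWarnings(
    run_categorization_pipeline(test_landscape())
  )))
}

# Canonical test structures.
smiles_pfoa <- "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
smiles_pfos <- "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
smiles_sebacamidine <-
  "NC(=N)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(=N)N"

# A symmetric distance matrix with given upper-triangle values, row-named.
dist_matrix <- function(values, ids = NULL) {
  n <- (1 + sqrt(1 + 8 * length(values))) / 2
  stopifnot(n == round(n))
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- values
  d <- d + t(d)
  ids <- ids %||% paste0("s", seq_len(n))
  dimnames(d) <- list(ids, ids)
  d
}

random_dist_matrix <- function(n) {
  dist_matrix(runif(n * (n - 1) / 2))
}

# Binary feature rows as a 0/1 matrix from lists of set bit positions.
bits_from_sets <- function(sets, n_bits = 16, ids = NULL) {
  m <- matrix(0L, nrow = length(sets), ncol = n_bits)
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  rownames(m) <- ids %||% paste0("s", seq_along(sets))
  m
}

# Synthetic classifier fixture: three structurally separable classes with
# distinct fingerprint signatures.
make_model_fixture <- function(n_per_class = 40, n_bits = 64, seed = 61) {
  set.seed(seed)
  classes <- c("alpha", "beta", "gamma")
  rows <- list()
  for (i in seq_along(classes)) {
    base <- rep(0L, n_bits)
    base[((i - 1) * 20 + 1):((i - 1) * 20 + 10)] <- 1L
    for (j in seq_len(n_per_class)) {
      bits <- base
      flip <- sample(n_bits, 3)
      bits[flip] <- 1L - bits[flip]
      rows[[length(rows) + 1]] <- bits
    }
  }
  bits <- do.call(rbind, rows)
  ids <- sprintf("m%03d", seq_len(nrow(bits)))
  rownames(bits) <- ids
  labels <- rep(classes, each = n_per_class)
  asn <- tibble::tibble(
    substance_id = ids,
    primary_category = rep(c("P1", "P2", "P3"), each = n_per_class),
    chain_length = rep(c(3, 8, 5), each = n_per_class),
    terminal_label = labels
  )
  list(bits = bits, assignments = asn)
}

# Independent hypergeometric tail-sum oracle for the one-sided Fisher test
# (enrichment direction): P(X >= a) with row/column margins fixed.
fisher_oracle_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  r1 <- a + b
  c1 <- a + c_
  k <- seq(a, min(r1, c1))
  sum(stats::dhyper(k, c1, n - c1, r1))
}
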