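# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# The standard synthetic study conditions (low-noise fixture).
fixture_sim <- function() {
  cached("sim", simulate_dataset(generator_config(seed = 11)))
}

fixture_db <- function() {
  cached("db", build_lcla_database(fixture_sim()$raw))
}

# A smaller library/database for the slower SVM paths.
fixture_small_db <- function() {
  cached("small_db", {
    sim <- simulate_dataset(generator_config(
      n_scaffolds = 8L, n_per_scaffold = 6L, n_cell_lines = 5L, seed = 21))
    build_lcla_database(sim$raw)
  })
}

fixture_reference <- function() {
  cached("reference", similarity_reference(fixture_db(), radius = 8L))
}

# Random sparse binary fingerprint matrix.
random_fp_matrix <- function(n, n_bits = 128L, n_on = 12L, seed = 1L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    m <- matrix(0L, n, n_bits)
    for (i in seq_len(n)) m[i, sample.int(n_bits, n_on)] <- 1L
    rownames(m) <- sprintf("R%03d", seq_len(n))
    m
  })
}

# Independent Tanimoto on explicit bit-index sets.
tanimoto_sets <- function(a_bits, b_bits) {
  u <- length(union(a_bits, b_bits))
  if (u == 0L) return(0)
  length(intersect(a_bits, b_bits)) / u
}

# A tiny raw activity table written by hand (see test-curation.R for the
# trace): exercises endpoint filtering, salts, conflicts and the
# minimum-sensitive cell-line filter.
toy_raw_table <- function() {
  data.frame(
    compound_id = c("a", "a", "b", "b", "c", "d", "e", "f", "g", "h", "h", "i"),
    smiles = c("c1ccccc1CCO", "c1ccccc1CCO", "c1ccccc1CCN", "c1ccccc1CCN",
               "c1ccccc1CCC.Cl", "c1ccccc1CC", "c1ccccc1C", "c1ccncc1C",
               "c1ccncc1CC", "c1ccncc1CCC", "c1ccncc1CCC", "c1ccncc1CCO"),
    cell_line_id = c("X", "X", "X", "X", "X", "X", "X", "Y", "Y", "X", "X", "X"),
    assay_type = c("IC50", "GI50", "IC50", "CC50", "IC50", "EC50", "IC50",
                   "IC50", "IC50", "IC50", "IC50", "IC50"),
    standard_value = c(1, 2, 0.5, 50, 3, 1, 2000, 1, 20, 4, 6, 9),
    standard_units = c("uM", "uM", "uM", "uM", "uM", "uM", "nM",
                       "uM", "uM", "uM", "uM", "uM"),
    standard_relation = "=",
    stringsAsFactors = FALSE
  )
}
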