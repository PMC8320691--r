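# Shared in-code fixtures: the nitronate monooxygenase worked example
# (KEGG R00025) in two flavours, and small random generators for
# property-style tests.

r00025_formulas <- function() {
  reaction_tbl(
    "R00025",
    substrates = data.frame(
      id = c("ethylnitronate", "oxygen", "reduced_FMN"),
      formula = c("C2H4NO2", "O2", "C17H23N4O9P")
    ),
    products = data.frame(
      id = c("acetaldehyde", "nitrite", "FMN", "water"),
      formula = c("C2H4O", "HNO2", "C17H21N4O9P", "H2O")
    )
  )
}

# Masses as printed at 4 decimals in the worked example.
r00025_printed <- function() {
  reaction_tbl(
    "R00025",
    substrates = data.frame(
      id = c("ethylnitronate", "oxygen", "reduced_FMN"),
      mass = c(74.0242, 31.9898, 458.1202)
    ),
    products = data.frame(
      id = c("acetaldehyde", "nitrite", "FMN", "water"),
      mass = c(44.0262, 47.0007, 456.1046, 18.0105)
    )
  )
}

rand_formula <- function() {
  els <- c("C", "H", "N", "O", "P", "S", "Cl", "Br")
  pick <- sample(els, sample(2:5, 1))
  counts <- sample(1:12, length(pick), replace = TRUE)
  names(counts) <- pick
  format_formula(reactomics:::as_chem_formula(counts))
}

rand_delta <- function() {
  els <- sample(c("C", "H", "N", "O", "S"), sample(1:3, 1))
  counts <- sample(c(-4:-1, 1:4), length(els), replace = TRUE)
  names(counts) <- els
  reactomics:::as_comp_delta(counts)
}

# Small random peak table with a few planted correlated pairs, for oracle
# comparisons that need non-trivial edges.
rand_peak_table <- function(n_features = 20, n_samples = 10, n_pairs = 3,
                            pair_pmd = 2.0157) {
  gen_peak_table(
    n_features = n_features, n_samples = n_samples, sigma = 0.05,
    planted_pairs = tibble::tibble(pmd = pair_pmd, n = n_pairs,
                                   type = "static", ratio = 1.5),
    biomarker = NULL, seed = NULL
  )
}

welch_by_hand <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
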