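# Seeded generators with known ground truth. All randomness is wrapped in
# withr::with_seed when a seed is supplied, so outputs are bit-reproducible.

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code() else withr::with_seed(seed, code())
}

#' Generate synthetic reactions with planted composition deltas
#'
#' Builds single-substrate/single-product reactions whose substrate equals a
#' random base formula plus a planted composition delta, so every reaction's
#' PMD is known in closed form (the delta's mass). Reactions beyond the
#' planted counts receive deltas drawn from `other_deltas`.
#'
#' @param n_reactions Total number of reactions (default 50).
#' @param planted Named integer vector: delta string -> number of reactions
#'   carrying it (default `c("+2H" = 30)`, i.e. a dominant hydrogenation
#'   signal).
#' @param other_deltas Delta strings for the remaining reactions (sampled
#'   uniformly).
#' @param seed Optional integer seed.
#' @return A list: `reactions` (long reaction table) and `manifest`
#'   (tibble `reaction_id`, `composition`, `expected_pmd` at full
#'   precision).
#' @export
gen_reactions <- function(n_reactions = 50, planted = c("+2H" = 30),
                          other_deltas = c("+O", "+C2H", "+2HO", "+C2O",
                                           "+S3O"),
                          seed = NULL) {
  if (n_reactions < 1) stop("`n_reactions` must be >= 1", call. = FALSE)
  if (sum(planted) > n_reactions) {
    stop("planted counts exceed `n_reactions`", call. = FALSE)
  }
  with_opt_seed(seed, function() {
    n_other <- n_reactions - sum(planted)
    deltas <- c(rep(names(planted), planted),
                if (n_other > 0) sample(other_deltas, n_other, replace = TRUE))
    deltas <- sample(deltas)  # shuffle order
    rows <- purrr::map(seq_len(n_reactions), function(i) {
      d <- parse_delta(deltas[i])
      # base formula with enough of every element to absorb losses
      base <- c(C = sample(6:20, 1), H = sample(10:30, 1),
                N = sample(0:3, 1), O = sample(3:8, 1))
      loss <- -pmin(d[names(d) %in% names(base)], 0L)
      for (el in names(loss)) {
        base[el] <- max(base[el], loss[[el]] + 1L)
      }
      sub <- base
      for (el in names(d)) {
        sub[el] <- sum(sub[names(sub) == el]) + d[[el]]
      }
      rid <- sprintf("SR%03d", i)
      reaction_tbl(
        rid,
        substrates = data.frame(id = paste0(rid, "_S"),
                                formula = format_formula(as_chem_formula(sub))),
        products = data.frame(id = paste0(rid, "_P"),
                              formula = format_formula(as_chem_formula(base)))
      )
    }) |> purrr::list_rbind()
    manifest <- tibble::tibble(
      reaction_id = sprintf("SR%03d", seq_len(n_reactions)),
      composition = deltas,
      expected_pmd = abs(vapply(deltas, function(d) delta_mass(parse_delta(d)),
                                numeric(1), USE.NAMES = FALSE))
    )
    list(reactions = rows, manifest = manifest)
  })
}

default_planted_pairs <- function() {
  tibble::tibble(
    pmd = c(14.0157, 14.0157),
    n = c(5L, 5L),
    type = c("static", "dynamic"),
    ratio = c(2, 2)
  )
}

#' Generate a synthetic peak table with planted PMD structure
#'
#' Emulates an LC-MS peak table: features with random m/z carry log-normal
#' multiplicative intensity noise (sigma on the log scale) around a sample-
#' varying latent level. Planted static pairs share one latent per pair, so
#' their intensity ratio is stable (RSD roughly `100*sqrt(2)*sigma`
#' percent); dynamic pairs use independent latents. A planted biomarker
#' multiplies the affected group's biomarker-pair intensities by
#' `1 - effect`, and optional Br doublets sit at the isotopologue spacing
#' with a fixed intensity ratio. m/z values are reported to 4 decimals and
#' intensities to 2, matching the CSV dialect of the readers/writers.
#'
#' @param n_features Total features including planted ones (default 100).
#' @param n_samples Total samples (default 100, split half case / half
#'   control).
#' @param case_fraction Fraction of samples labelled `"case"` (default 0.5).
#' @param sigma Log-normal technical noise sd on the log scale (default
#'   0.1).
#' @param tau Log-normal between-sample biological variation sd (default
#'   0.5).
#' @param planted_pairs Tibble `pmd`, `n`, `type` ("static"/"dynamic"),
#'   `ratio` (low-m/z over high-m/z base intensity ratio); default five
#'   static and five dynamic pairs at 14.0157 Da (a CH2 step).
#' @param biomarker List `pmd`, `n_pairs`, `effect`, `group`: static pairs
#'   at `pmd` whose features are scaled by `1 - effect` in `group`. Default
#'   two pairs at 2.0157 Da (a 2H step, 4 features) with a 30% decrease in
#'   cases, mirroring a dehydrogenation biomarker reaction. Set `NULL` to
#'   omit.
#' @param n_br Number of planted Br isotopologue doublets (default 0).
#' @param br_spacing Doublet spacing in Da (default 1.998).
#' @param br_ratio Partner/monoisotopic intensity ratio (default 0.97).
#' @param mz_range m/z range for random features (default `c(100, 800)`).
#' @param seed Optional integer seed.
#' @return A list: `peaks` (peak table), `samples` (tibble `sample_id`,
#'   `group`), `manifest` (list with `pairs` tibble -- `from`, `to`, `pmd`,
#'   `type`, `role` in planted/biomarker/br -- and the generator settings).
#' @export
gen_peak_table <- function(n_features = 100, n_samples = 100,
                           case_fraction = 0.5, sigma = 0.1, tau = 0.5,
                           planted_pairs = default_planted_pairs(),
                           biomarker = list(pmd = 2.0157, n_pairs = 2,
                                            effect = 0.3, group = "case"),
                           n_br = 0, br_spacing = 1.998, br_ratio = 0.97,
                           mz_range = c(100, 800), seed = NULL) {
  planted_pairs <- tibble::as_tibble(planted_pairs)
  n_bio <- if (is.null(biomarker)) 0L else as.integer(biomarker$n_pairs)
  n_pair_feats <- 2L * (sum(planted_pairs$n) + n_bio + n_br)
  if (sum(planted_pairs$n) + n_bio + n_br > n_features / 2) {
    stop("planted pair count exceeds n_features/2", call. = FALSE)
  }
  with_opt_seed(seed, function() {
    n_case <- round(case_fraction * n_samples)
    samples <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n_samples)),
      group = c(rep("case", n_case), rep("control", n_samples - n_case))
    )
    is_case <- samples$group == "case"

    pair_specs <- planted_pairs[rep(seq_len(nrow(planted_pairs)),
                                    planted_pairs$n), ]
    pair_specs$role <- "planted"
    if (n_bio > 0L) {
      pair_specs <- dplyr::bind_rows(
        pair_specs,
        tibble::tibble(pmd = biomarker$pmd, n = 1L, type = "static",
                       ratio = 1, role = "biomarker")[rep(1, n_bio), ]
      )
    }
    if (n_br > 0L) {
      pair_specs <- dplyr::bind_rows(
        pair_specs,
        tibble::tibble(pmd = br_spacing, n = 1L, type = "static",
                       ratio = 1 / br_ratio, role = "br")[rep(1, n_br), ]
      )
    }
    n_pairs <- nrow(pair_specs)
    n_noise <- n_features - 2L * n_pairs

    feats <- list(); intens <- list(); manifest_pairs <- list()
    fid <- 0L
    next_id <- function() {
      fid <<- fid + 1L
      sprintf("F%04d", fid)
    }
    for (pi in seq_len(n_pairs)) {
      spec <- pair_specs[pi, ]
      base_mz <- round(stats::runif(1, mz_range[1], mz_range[2]), 4)
      id_lo <- next_id(); id_hi <- next_id()
      amp <- 10^stats::runif(1, 4, 6)
      if (spec$type == "static") {
        lat <- exp(stats::rnorm(n_samples, 0, tau))
        i_lo <- spec$ratio * amp * lat * exp(stats::rnorm(n_samples, 0, sigma))
        i_hi <- amp * lat * exp(stats::rnorm(n_samples, 0, sigma))
      } else {
        i_lo <- spec$ratio * amp * exp(stats::rnorm(n_samples, 0, tau)) *
          exp(stats::rnorm(n_samples, 0, sigma))
        i_hi <- amp * exp(stats::rnorm(n_samples, 0, tau)) *
          exp(stats::rnorm(n_samples, 0, sigma))
      }
      if (spec$role == "biomarker") {
        aff <- if (biomarker$group == "case") is_case else !is_case
        i_lo[aff] <- i_lo[aff] * (1 - biomarker$effect)
        i_hi[aff] <- i_hi[aff] * (1 - biomarker$effect)
      }
      feats[[length(feats) + 1L]] <- tibble::tibble(
        feature_id = c(id_lo, id_hi),
        mz = c(base_mz, base_mz + spec$pmd)
      )
      intens[[length(intens) + 1L]] <- rbind(i_lo, i_hi)
      manifest_pairs[[length(manifest_pairs) + 1L]] <- tibble::tibble(
        from = id_lo, to = id_hi, pmd = spec$pmd, type = spec$type,
        ratio = spec$ratio, role = spec$role
      )
    }
    if (n_noise > 0L) {
      for (ni in seq_len(n_noise)) {
        id <- next_id()
        amp <- 10^stats::runif(1, 4, 6)
        feats[[length(feats) + 1L]] <- tibble::tibble(
          feature_id = id,
          mz = round(stats::runif(1, mz_range[1], mz_range[2]), 4)
        )
        intens[[length(intens) + 1L]] <- matrix(
          amp * exp(stats::rnorm(n_samples, 0, tau)) *
            exp(stats::rnorm(n_samples, 0, sigma)),
          nrow = 1
        )
      }
    }
    peaks <- purrr::list_rbind(feats)
    im <- round(do.call(rbind, intens), 2)
    colnames(im) <- samples$sample_id
    peaks <- dplyr::bind_cols(peaks, tibble::as_tibble(im))
    manifest <- list(
      pairs = purrr::list_rbind(manifest_pairs),
      biomarker = biomarker,
      sigma = sigma, tau = tau, n_br = n_br, br_ratio = br_ratio,
      br_spacing = br_spacing
    )
    list(peaks = peaks, samples = samples, manifest = manifest)
  })
}

#' Generate endogenous and exogenous compound pools with known connectivity
#'
#' Endogenous compounds sit on chains sharing one mass step, so the pooled
#' top-frequency PMDs (the step and its low multiples) link each chain into
#' a near-complete subgraph: chain lengths are chosen so the mean node
#' degree matches `target_degree["endogenous"]`. Exogenous compounds form
#' sparse pairs and triplets on the same step, reproducing the weakly
#' connected periphery seen for xenobiotics; the pair/triplet mix is chosen
#' to match `target_degree["exogenous"]`.
#'
#' @param n_endogenous,n_exogenous Pool sizes (defaults 55 and 120).
#' @param target_degree Named target mean degrees (default
#'   `c(endogenous = 4.5, exogenous = 1.7)`, the contrast reported for
#'   toxin-database compounds).
#' @param step Shared mass step in Da (default 14.0157, a CH2 unit).
#' @param mz_range Chain base-mass range (default `c(100, 600)`).
#' @param seed Optional integer seed.
#' @return A list: `endogenous` and `exogenous` compound tibbles
#'   (`compound_id`, `name`, `mass`) and a `manifest` with the chain
#'   layout. With `n_exogenous = 0` the exogenous tibble is empty.
#' @export
gen_compound_pools <- function(n_endogenous = 55, n_exogenous = 120,
                               target_degree = c(endogenous = 4.5,
                                                 exogenous = 1.7),
                               step = 14.0157, mz_range = c(100, 600),
                               seed = NULL) {
  if (n_endogenous < 2) stop("`n_endogenous` must be >= 2", call. = FALSE)
  # chain of length L, fully linked by the step's multiples, gives degree
  # L-1 to each member; mix lengths floor(t)+1 and floor(t)+2 to hit the
  # target mean degree t.
  chain_lengths <- function(n, target) {
    lo <- floor(target) + 1
    hi <- lo + 1
    frac_hi <- target - (lo - 1)  # fraction of nodes needing degree lo
    lens <- integer(0)
    left <- n
    while (left > 0) {
      want_hi <- frac_hi * n - sum(lens[lens == hi]) > hi / 2
      l <- if (want_hi && left >= hi) hi else min(lo, left)
      if (left - l == 1) l <- l + 1  # avoid a stranded singleton
      l <- min(l, left)
      lens <- c(lens, l)
      left <- left - l
    }
    lens
  }
  exo_lengths <- function(n, target) {
    # pairs (degree 1) and triplets (degree 2): fraction in triplets
    # f3 = target - 1
    f3 <- min(max(target - 1, 0), 1)
    n3 <- round(f3 * n / 3)
    rem <- n - 3 * n3
    if (rem %% 2 == 1) {
      if (n3 > 0) { n3 <- n3 - 1; rem <- rem + 3 } else rem <- rem - 1
    }
    c(rep(3L, n3), rep(2L, rem %/% 2))
  }
  with_opt_seed(seed, function() {
    make_pool <- function(lens, prefix) {
      masses <- purrr::map(lens, function(l) {
        base <- round(stats::runif(1, mz_range[1], mz_range[2]), 4)
        base + step * (seq_len(l) - 1)
      })
      mass <- unlist(masses)
      tibble::tibble(
        compound_id = sprintf("%s%03d", prefix, seq_along(mass)),
        name = sprintf("%s%03d", prefix, seq_along(mass)),
        mass = round(mass, 4)
      )
    }
    lens_endo <- chain_lengths(n_endogenous, target_degree[["endogenous"]])
    endo <- make_pool(lens_endo, "E")
    if (n_exogenous > 0) {
      lens_exo <- exo_lengths(n_exogenous, target_degree[["exogenous"]])
      exo <- make_pool(lens_exo, "X")
    } else {
      lens_exo <- integer(0)
      exo <- tibble::tibble(compound_id = character(0), name = character(0),
                            mass = numeric(0))
    }
    list(endogenous = endo, exogenous = exo,
         manifest = list(step = step, chain_lengths_endogenous = lens_endo,
                         chain_lengths_exogenous = lens_exo,
                         target_degree = target_degree))
  })
}
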