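# A peak table is a wide tibble: `feature_id`, `mz`, optional `rt`
# (seconds), and one numeric intensity column per sample.

peak_sample_cols <- function(t) {
  setdiff(names(t), c("feature_id", "mz", "rt"))
}

validate_peak_table <- function(t) {
  t <- tibble::as_tibble(t)
  if (!all(c("feature_id", "mz") %in% names(t))) {
    stop("peak table needs `feature_id` and `mz` columns", call. = FALSE)
  }
  if (anyDuplicated(t$feature_id)) {
    stop("duplicate feature ids in peak table", call. = FALSE)
  }
  if (!is.numeric(t$mz) || any(is.na(t$mz)) || any(t$mz <= 0)) {
    stop("`mz` must be positive and complete", call. = FALSE)
  }
  sc <- peak_sample_cols(t)
  if (length(sc) > 0L) {
    num <- vapply(t[sc], is.numeric, logical(1))
    if (!all(num)) {
      stop("non-numeric intensity column(s): ",
           paste(sc[!num], collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(sc)) stop("duplicate sample ids", call. = FALSE)
    neg <- vapply(t[sc], function(x) any(x < 0, na.rm = TRUE), logical(1))
    if (any(neg)) stop("negative intensities found", call. = FALSE)
  }
  t$feature_id <- as.character(t$feature_id)
  t
}

intensity_matrix <- function(t) {
  sc <- peak_sample_cols(t)
  m <- as.matrix(t[sc])
  rownames(m) <- t$feature_id
  m
}

#' Find PMD-related peak pairs in a peak table
#'
#' Returns every unordered feature pair whose m/z difference, rounded to
#' `digits` decimals, matches a value in `pmd_set`. Pairs are oriented with
#' the lower m/z feature first and returned in a canonical order, so the
#' result is independent of input row order.
#'
#' @param t A peak table (`feature_id`, `mz`, optional `rt`, intensity
#'   columns).
#' @param pmd_set Numeric PMD values to match, or the string `"all"` to keep
#'   every pair (the full frequency spectrum).
#' @param digits Decimals for PMD matching (default 2, the precision at
#'   which experimental m/z differences are compared).
#' @param rt_min_gap Optional minimum retention-time separation in seconds:
#'   when `rt` is present, pairs co-eluting closer than this are dropped as
#'   likely adducts/isotopologues of one compound.
#' @return A tibble: `from`, `to` (feature ids, `mz_from < mz_to`),
#'   `mz_from`, `mz_to`, `pmd_observed` (unrounded), `pmd` (rounded).
#' @export
find_pairs <- function(t, pmd_set, digits = 2, rt_min_gap = NULL) {
  t <- validate_peak_table(t)
  if (missing(pmd_set) || length(pmd_set) == 0L) {
    stop("`pmd_set` must be non-empty (or \"all\")", call. = FALSE)
  }
  all_pmds <- identical(pmd_set, "all")
  if (!all_pmds && !is.numeric(pmd_set)) {
    stop("`pmd_set` must be numeric or \"all\"", call. = FALSE)
  }
  ord <- order(t$mz, t$feature_id)
  t <- t[ord, ]
  n <- nrow(t)
  if (n < 2L) {
    return(tibble::tibble(from = character(0), to = character(0),
                          mz_from = numeric(0), mz_to = numeric(0),
                          pmd_observed = numeric(0), pmd = numeric(0)))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]  # i < j, so mz_i <= mz_j
  d_obs <- t$mz[j] - t$mz[i]
  d <- round_pmd(d_obs, digits)
  keep <- if (all_pmds) rep(TRUE, length(d)) else
    d %in% round_pmd(pmd_set, digits)
  if (!is.null(rt_min_gap) && "rt" %in% names(t)) {
    keep <- keep & !(abs(t$rt[j] - t$rt[i]) < rt_min_gap)
  }
  out <- tibble::tibble(
    from = t$feature_id[i][keep], to = t$feature_id[j][keep],
    mz_from = t$mz[i][keep], mz_to = t$mz[j][keep],
    pmd_observed = d_obs[keep], pmd = d[keep]
  )
  dplyr::arrange(out, .data$pmd, .data$from, .data$to)
}

# Statistics for one pair of intensity vectors. Samples where either
# intensity is zero or missing are excluded; fewer than 3 usable samples
# leaves the statistics NA.
pair_stat_one <- function(x, y) {
  use <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  n <- sum(use)
  if (n < 3L) {
    return(c(n_used = n, pearson_r = NA_real_, ratio_rsd = NA_real_))
  }
  r <- suppressWarnings(stats::cor(x[use], y[use]))
  ratio <- x[use] / y[use]
  rsd <- 100 * stats::sd(ratio) / mean(ratio)
  c(n_used = n, pearson_r = r, ratio_rsd = rsd)
}

#' Compute intensity statistics for peak pairs
#'
#' For each pair, the Pearson correlation of the two features' intensities
#' and the percent relative standard deviation (RSD) of the per-sample
#' intensity ratio. The ratio is oriented as lower-m/z over higher-m/z
#' intensity (RSD is orientation-sensitive, so the convention is fixed).
#' Samples where either intensity is zero are excluded; pairs with fewer
#' than 3 usable samples keep NA statistics and are retained.
#'
#' @param t The peak table the pairs came from.
#' @param pairs A pair tibble from [find_pairs()].
#' @return `pairs` with `n_used`, `pearson_r` and `ratio_rsd` columns added.
#' @export
pair_statistics <- function(t, pairs) {
  t <- validate_peak_table(t)
  m <- intensity_matrix(t)
  miss <- setdiff(unique(c(pairs$from, pairs$to)), rownames(m))
  if (length(miss) > 0L) {
    stop("pair feature(s) absent from peak table: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  st <- purrr::map2(pairs$from, pairs$to,
                    function(a, b) pair_stat_one(m[a, ], m[b, ]))
  st <- do.call(rbind, st)
  pairs$n_used <- if (nrow(pairs) > 0L) as.integer(st[, "n_used"]) else integer(0)
  pairs$pearson_r <- if (nrow(pairs) > 0L) as.numeric(st[, "pearson_r"]) else numeric(0)
  pairs$ratio_rsd <- if (nrow(pairs) > 0L) as.numeric(st[, "ratio_rsd"]) else numeric(0)
  pairs
}

#' Classify peak pairs as static or dynamic
#'
#' A pair is a static PMD when its intensity ratio is stable across samples:
#' ratio RSD below `rsd_cutoff` percent and Pearson correlation above
#' `cor_cutoff`. Only static pairs are usable for relative quantification;
#' all other pairs (including those with missing statistics) are dynamic.
#'
#' @param pairs A pair tibble with statistics (see [pair_statistics()]).
#' @param rsd_cutoff Percent RSD threshold (default 30).
#' @param cor_cutoff Correlation threshold (default 0.6). Set to `-1` to
#'   classify on RSD alone.
#' @return `pairs` with a logical `static` column added.
#' @export
classify_static <- function(pairs, rsd_cutoff = 30, cor_cutoff = 0.6) {
  if (!all(c("pearson_r", "ratio_rsd") %in% names(pairs))) {
    stop("run pair_statistics() first", call. = FALSE)
  }
  pairs$static <- !is.na(pairs$ratio_rsd) & !is.na(pairs$pearson_r) &
    pairs$ratio_rsd < rsd_cutoff & pairs$pearson_r > cor_cutoff
  pairs
}

#' Relative quantification of a PMD across samples
#'
#' Sums, per sample, the intensities of all features participating in at
#' least one static pair at the given PMD. Each feature is counted once even
#' when it occurs in several pairs, so the sum is over the union of
#' contributing features.
#'
#' @param t The peak table.
#' @param pairs Classified pairs (see [classify_static()]).
#' @param pmd_value The rounded PMD to quantify (matched against the `pmd`
#'   column).
#' @return A tibble `sample_id`, `intensity`; zero rows (with a warning)
#'   when no static pair matches.
#' @export
quantify_pmd <- function(t, pairs, pmd_value) {
  t <- validate_peak_table(t)
  if (!"static" %in% names(pairs)) {
    stop("run classify_static() first", call. = FALSE)
  }
  sel <- pairs$static & abs(pairs$pmd - pmd_value) < 1e-8
  if (!any(sel)) {
    warning("no static pair at PMD ", pmd_value, call. = FALSE)
    return(tibble::tibble(sample_id = character(0), intensity = numeric(0)))
  }
  feats <- unique(c(pairs$from[sel], pairs$to[sel]))
  m <- intensity_matrix(t)
  sums <- colSums(m[feats, , drop = FALSE], na.rm = TRUE)
  tibble::tibble(sample_id = names(sums), intensity = unname(sums))
}

check_groups <- function(groups) {
  groups <- tibble::as_tibble(groups)
  if (!all(c("sample_id", "group") %in% names(groups))) {
    stop("`groups` needs `sample_id` and `group` columns", call. = FALSE)
  }
  groups$sample_id <- as.character(groups$sample_id)
  groups$group <- as.character(groups$group)
  tab <- table(groups$group)
  if (length(tab) != 2L) {
    stop("need exactly two groups, got ", length(tab), call. = FALSE)
  }
  if (any(tab < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  groups
}

#' Differential (biomarker-reaction) analysis of PMD intensities
#'
#' For each candidate PMD, sums the static-pair feature intensities per
#' sample (see [quantify_pmd()]) and compares the two groups with a Welch
#' two-sample two-sided t-test. When several PMDs are tested, raw p-values
#' are Benjamini-Hochberg adjusted across them. The direction reports the
#' group with the higher mean.
#'
#' @param t The peak table.
#' @param pairs Classified pairs (see [classify_static()]).
#' @param groups A tibble `sample_id`, `group` with exactly two groups of at
#'   least 2 samples each.
#' @param pmds PMD values to test; default all PMDs with at least one static
#'   pair.
#' @return A `pmd_differential` tibble: `pmd`, `n_features`, `group1`,
#'   `mean1`, `group2`, `mean2`, `statistic`, `df`, `p_value`, `p_adj`,
#'   `direction`. The per-sample sums used are stored in the `"quant"`
#'   attribute for plotting.
#' @export
differential_pmd <- function(t, pairs, groups, pmds = NULL) {
  t <- validate_peak_table(t)
  groups <- check_groups(groups)
  if (!"static" %in% names(pairs)) {
    stop("run classify_static() first", call. = FALSE)
  }
  if (is.null(pmds)) {
    pmds <- sort(unique(pairs$pmd[pairs$static]))
  }
  if (length(pmds) == 0L) {
    stop("no static PMDs to test", call. = FALSE)
  }
  glev <- sort(unique(groups$group))
  quant_all <- purrr::map(pmds, function(p) {
    q <- suppressWarnings(quantify_pmd(t, pairs, p))
    if (nrow(q) == 0L) return(NULL)
    q$pmd <- p
    q
  }) |> purrr::list_rbind()
  if (is.null(quant_all) || nrow(quant_all) == 0L) {
    quant_all <- tibble::tibble(sample_id = character(0),
                                intensity = numeric(0), pmd = numeric(0))
  }
  rows <- purrr::map(pmds, function(p) {
    sel <- pairs$static & abs(pairs$pmd - p) < 1e-8
    nf <- length(unique(c(pairs$from[sel], pairs$to[sel])))
    q <- quant_all[!is.na(match(quant_all$pmd, p)), ]
    if (nrow(q) == 0L) {
      return(tibble::tibble(pmd = p, n_features = 0L, group1 = glev[1],
                            mean1 = NA_real_, group2 = glev[2],
                            mean2 = NA_real_, statistic = NA_real_,
                            df = NA_real_, p_value = NA_real_,
                            direction = NA_character_))
    }
    q <- dplyr::inner_join(q, groups, by = "sample_id")
    x <- q$intensity[q$group == glev[1]]
    y <- q$intensity[q$group == glev[2]]
    tt <- stats::t.test(x, y, var.equal = FALSE)
    dir <- if (isTRUE(all.equal(mean(x), mean(y)))) NA_character_ else
      glev[which.max(c(mean(x), mean(y)))]
    tibble::tibble(pmd = p, n_features = nf, group1 = glev[1],
                   mean1 = mean(x), group2 = glev[2], mean2 = mean(y),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   direction = dir)
  }) |> purrr::list_rbind()
  rows$p_adj <- stats::p.adjust(rows$p_value, method = "BH")
  rows <- dplyr::select(rows, "pmd", "n_features", "group1", "mean1",
                        "group2", "mean2", "statistic", "df", "p_value",
                        "p_adj", "direction")
  if (!is.null(quant_all) && nrow(quant_all) > 0L) {
    quant_all <- dplyr::inner_join(quant_all, groups, by = "sample_id")
  }
  attr(rows, "quant") <- quant_all
  class(rows) <- c("pmd_differential", class(rows))
  rows
}

#' Frequency spectrum of all pairwise PMDs in a peak table
#'
#' Histogram of the rounded m/z differences of every unordered feature pair
#' (optionally capped at `max_pmd`), returned as a PMD database usable by
#' [top_k_pmds()]. High-frequency values indicate recurring reaction-like
#' relationships in the data. Per-pair source ids are not stored (the
#' all-pairs list grows quadratically); use [find_pairs()] to retrieve the
#' pairs behind a value of interest.
#'
#' @param t A peak table with at least 2 features.
#' @param digits Decimals for PMD rounding (default 2).
#' @param max_pmd Keep only PMDs up to this value (default `Inf`).
#' @return A `pmd_db` tibble: `pmd`, `frequency`, `isomer`.
#' @export
pmd_frequency_spectrum <- function(t, digits = 2, max_pmd = Inf) {
  t <- validate_peak_table(t)
  if (nrow(t) < 2L) stop("need at least 2 features", call. = FALSE)
  mz <- sort(t$mz)
  n <- length(mz)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- round_pmd(mz[idx[, 2]] - mz[idx[, 1]], digits)
  d <- d[d <= max_pmd]
  tab <- table(d)
  db <- tibble::tibble(pmd = as.numeric(names(tab)),
                       frequency = as.integer(tab)) |>
    dplyr::mutate(isomer = .data$pmd == 0) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$pmd)
  new_pmd_db(db, digits, NULL, "peak")
}

#' Screen for halogenated (Br-type) features by isotopologue spacing
#'
#' Flags features that have a partner peak `isotope_pmd` Da above them (the
#' \eqn{^{81}}Br/\eqn{^{79}}Br isotopologue spacing, ~1.998 Da) whose
#' median per-sample intensity ratio (partner over monoisotopic peak) falls
#' in `ratio_window` -- approximately 1:1 for one bromine.
#'
#' @param t A peak table.
#' @param isotope_pmd Isotopologue spacing in Da (default 1.998).
#' @param ratio_window Acceptable partner/monoisotopic intensity-ratio range
#'   (default `c(0.5, 2)`).
#' @param digits Decimals for spacing matching (default 2).
#' @return A tibble with one row per candidate (feature, partner) doublet:
#'   `feature_id`, `mz`, `partner_id`, `partner_mz`, `median_ratio`,
#'   `flagged`. Features without a partner at the spacing do not appear.
#' @export
halogen_screen <- function(t, isotope_pmd = 1.998, ratio_window = c(0.5, 2),
                           digits = 2) {
  t <- validate_peak_table(t)
  pairs <- find_pairs(t, pmd_set = isotope_pmd, digits = digits)
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(feature_id = character(0), mz = numeric(0),
                          partner_id = character(0), partner_mz = numeric(0),
                          median_ratio = numeric(0), flagged = logical(0)))
  }
  m <- intensity_matrix(t)
  ratio <- purrr::map2_dbl(pairs$from, pairs$to, function(a, b) {
    x <- m[a, ]; y <- m[b, ]
    use <- !is.na(x) & !is.na(y) & x > 0 & y > 0
    if (!any(use)) return(NA_real_)
    stats::median(y[use] / x[use])
  })
  tibble::tibble(
    feature_id = pairs$from, mz = pairs$mz_from,
    partner_id = pairs$to, partner_mz = pairs$mz_to,
    median_ratio = ratio,
    flagged = !is.na(ratio) & ratio >= ratio_window[1] &
      ratio <= ratio_window[2]
  )
}

#' Mass defect of m/z values
#'
#' The difference between an exact mass and its nearest integer nominal
#' mass. Halogens such as Br shift the defect strongly negative, which makes
#' a defect window a cheap secondary screen alongside [halogen_screen()].
#'
#' @param mz Numeric m/z values.
#' @return Numeric defects in Da, in (-0.5, 0.5].
#' @export
mass_defect <- function(mz) {
  mz - round(mz)
}

#' Filter a peak table by mass-defect window
#'
#' @param t A peak table.
#' @param defect_range Length-2 numeric window (Da) of retained defects.
#' @return The rows of `t` whose `mz` defect lies inside the window.
#' @export
mass_defect_screen <- function(t, defect_range) {
  t <- validate_peak_table(t)
  d <- mass_defect(t$mz)
  t[d >= defect_range[1] & d <= defect_range[2], ]
}
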