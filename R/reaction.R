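# Normalize compound input to a tibble with columns
# compound_id, name, formula, mass. Mass is computed from the formula when
# absent; consistency between a supplied mass and the formula is checked to
# 0.001 Da.
as_compound_tbl <- function(x, compute_mass = TRUE) {
  x <- tibble::as_tibble(x)
  if (!"compound_id" %in% names(x)) {
    if ("id" %in% names(x)) {
      x <- dplyr::rename(x, compound_id = "id")
    } else {
      stop("compound table needs a `compound_id` (or `id`) column",
           call. = FALSE)
    }
  }
  if (!"name" %in% names(x)) x$name <- x$compound_id
  if (!"formula" %in% names(x)) x$formula <- NA_character_
  if (!"mass" %in% names(x)) x$mass <- NA_real_
  x$compound_id <- as.character(x$compound_id)
  x$mass <- as.numeric(x$mass)
  if (compute_mass) {
    need <- is.na(x$mass) & !is.na(x$formula)
    if (any(need)) {
      x$mass[need] <- monoisotopic_mass(x$formula[need])
    }
  }
  both <- !is.na(x$mass) & !is.na(x$formula)
  if (any(both)) {
    dev <- abs(x$mass[both] - monoisotopic_mass(x$formula[both]))
    if (any(dev > 0.001)) {
      off <- x$compound_id[both][dev > 0.001]
      warning("supplied mass differs from formula mass by > 0.001 Da for: ",
              paste(off, collapse = ", "), call. = FALSE)
    }
  }
  if (any(!is.na(x$mass) & x$mass <= 0)) {
    stop("compound masses must be positive", call. = FALSE)
  }
  dplyr::select(x, "compound_id", "name", "formula", "mass",
                dplyr::everything())
}

#' Build a reaction table
#'
#' A reaction is stored as a long tibble with one row per participating
#' compound and a `role` column ("substrate" or "product"). A reaction needs
#' at least one substrate and one product. Several reactions can be stacked
#' in one table and are distinguished by `reaction_id`.
#'
#' @param id Reaction identifier.
#' @param substrates,products Data frames (or lists coercible to them) with
#'   columns `compound_id` (or `id`), and `formula` and/or `mass`; `name` is
#'   optional. Masses are computed from formulas when absent.
#' @param annotation Optional free-text annotation (enzyme, reaction class).
#' @return A tibble with columns `reaction_id`, `role`, `compound_id`,
#'   `name`, `formula`, `mass`, `annotation`.
#' @examples
#' reaction_tbl("r1",
#'   substrates = data.frame(id = "a", formula = "C2H6"),
#'   products   = data.frame(id = "b", formula = "C2H4"))
#' @export
reaction_tbl <- function(id, substrates, products, annotation = NA_character_) {
  s <- as_compound_tbl(substrates)
  p <- as_compound_tbl(products)
  if (nrow(s) < 1L || nrow(p) < 1L) {
    stop("a reaction needs at least one substrate and one product",
         call. = FALSE)
  }
  dplyr::bind_rows(
    dplyr::mutate(s, role = "substrate"),
    dplyr::mutate(p, role = "product")
  ) |>
    dplyr::mutate(reaction_id = as.character(id),
                  annotation = annotation) |>
    dplyr::select("reaction_id", "role", "compound_id", "name", "formula",
                  "mass", "annotation")
}

# Split a (possibly multi-)reaction table, validating roles and masses.
split_reactions <- function(reactions) {
  reactions <- tibble::as_tibble(reactions)
  req <- c("reaction_id", "role", "compound_id", "mass")
  miss <- setdiff(req, names(reactions))
  if (length(miss) > 0L) {
    stop("reaction table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  split(reactions, factor(reactions$reaction_id,
                          levels = unique(reactions$reaction_id)))
}

one_reaction <- function(reactions) {
  rs <- split_reactions(reactions)
  if (length(rs) != 1L) {
    stop("expected a single reaction, got ", length(rs),
         " reaction ids; filter first", call. = FALSE)
  }
  rs[[1]]
}

check_reaction_masses <- function(r) {
  bad <- r$compound_id[is.na(r$mass)]
  if (length(bad) > 0L) {
    stop("missing mass for compound(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!any(r$role == "substrate") || !any(r$role == "product")) {
    stop("reaction '", r$reaction_id[1],
         "' needs at least one substrate and one product", call. = FALSE)
  }
  invisible(r)
}

#' PMD matrix of a reaction
#'
#' The full substrates-by-products grid of absolute mass differences,
#' rounded to `digits` decimals: entry (k, i) is `pmd(S_k, P_i, digits)`.
#'
#' @param reactions A reaction table (see [reaction_tbl()]) holding exactly
#'   one reaction.
#' @param digits Decimals for PMD rounding (default 3).
#' @return A tibble with one row per substrate/product pair: `reaction_id`,
#'   `substrate`, `product`, `substrate_mass`, `product_mass`, `pmd`.
#'   Substrate/product order follows the input row order. The rounding
#'   precision is stored in the `"digits"` attribute.
#' @export
pmd_matrix <- function(reactions, digits = 3) {
  r <- check_reaction_masses(one_reaction(reactions))
  s <- r[r$role == "substrate", ]
  p <- r[r$role == "product", ]
  grid <- tidyr::expand_grid(si = seq_len(nrow(s)), pi = seq_len(nrow(p)))
  out <- tibble::tibble(
    reaction_id = r$reaction_id[1],
    substrate = s$compound_id[grid$si],
    product = p$compound_id[grid$pi],
    substrate_mass = s$mass[grid$si],
    product_mass = p$mass[grid$pi],
    pmd = pmd(s$mass[grid$si], p$mass[grid$pi], digits)
  )
  attr(out, "digits") <- digits
  out
}

#' Minimum substrate PMD of a reaction
#'
#' For substrate k, the smallest PMD against any product, together with the
#' product achieving it. On ties the first product (input order) is reported;
#' the PMD value is unaffected by the tie-break.
#'
#' @inheritParams pmd_matrix
#' @param substrate Substrate selector: an integer index into the reaction's
#'   substrate list (input order) or a substrate `compound_id`.
#' @return A one-row tibble: `reaction_id`, `substrate_id`, `product_id`,
#'   `pmd`.
#' @export
substrate_pmd <- function(reactions, substrate, digits = 3) {
  r <- check_reaction_masses(one_reaction(reactions))
  s <- r[r$role == "substrate", ]
  p <- r[r$role == "product", ]
  if (is.numeric(substrate)) {
    if (substrate < 1 || substrate > nrow(s)) {
      stop("substrate index out of range (1..", nrow(s), ")", call. = FALSE)
    }
    k <- as.integer(substrate)
  } else {
    k <- match(as.character(substrate), s$compound_id)
    if (is.na(k)) {
      stop("no substrate with id '", substrate, "'", call. = FALSE)
    }
  }
  d <- pmd(s$mass[k], p$mass, digits)
  i <- which.min(d)
  tibble::tibble(reaction_id = r$reaction_id[1],
                 substrate_id = s$compound_id[k],
                 product_id = p$compound_id[i],
                 pmd = d[i])
}

# Composition annotation for a substrate/argmin-product pair: the delta of
# the heavier compound's formula minus the lighter one's, matching the sign
# convention of an absolute mass difference. NA when either formula is
# missing.
pair_composition <- function(f_sub, m_sub, f_prod, m_prod) {
  if (is.na(f_sub) || is.na(f_prod)) return(NA_character_)
  if (m_sub >= m_prod) {
    format_delta(formula_delta(f_sub, f_prod))
  } else {
    format_delta(formula_delta(f_prod, f_sub))
  }
}

#' Reaction PMD: the deduplicated set of substrate PMDs
#'
#' For each reaction, every substrate contributes its minimum PMD against the
#' products; duplicate values (after rounding) are collapsed to one, with
#' composition annotations unioned. When both compounds of a minimizing pair
#' carry formulas, the PMD is annotated with the elemental-composition delta
#' (heavier minus lighter), e.g. `"+2H"`.
#'
#' @param reactions A reaction table; may hold several reactions.
#' @param digits Decimals for PMD rounding (default 3).
#' @return A tibble with columns `reaction_id`, `pmd`, `composition`
#'   (`";"`-separated when several substrate pairs share one rounded value),
#'   `substrate_ids`, `product_ids`. Row order follows first substrate
#'   occurrence within each reaction.
#' @examples
#' r <- reaction_tbl("r1",
#'   substrates = data.frame(id = "a", formula = "C2H6"),
#'   products   = data.frame(id = "b", formula = "C2H4"))
#' reaction_pmd(r)
#' @export
reaction_pmd <- function(reactions, digits = 3) {
  rs <- split_reactions(reactions)
  purrr::map(rs, function(r) {
    check_reaction_masses(r)
    s <- r[r$role == "substrate", ]
    p <- r[r$role == "product", ]
    per_sub <- purrr::map(seq_len(nrow(s)), function(k) {
      d <- pmd(s$mass[k], p$mass, digits)
      i <- which.min(d)
      tibble::tibble(
        pmd = d[i],
        composition = pair_composition(s$formula[k], s$mass[k],
                                       p$formula[i], p$mass[i]),
        substrate_id = s$compound_id[k],
        product_id = p$compound_id[i]
      )
    }) |> purrr::list_rbind()
    per_sub |>
      dplyr::group_by(.data$pmd) |>
      dplyr::summarise(
        composition = paste(sort(unique(stats::na.omit(.data$composition))),
                            collapse = ";"),
        substrate_ids = paste(.data$substrate_id, collapse = ";"),
        product_ids = paste(unique(.data$product_id), collapse = ";"),
        .order = min(dplyr::cur_group_rows()),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$.order) |>
      dplyr::mutate(
        reaction_id = r$reaction_id[1],
        composition = dplyr::if_else(.data$composition == "",
                                     NA_character_, .data$composition)
      ) |>
      dplyr::select("reaction_id", "pmd", "composition", "substrate_ids",
                    "product_ids")
  }) |> purrr::list_rbind()
}

new_pmd_db <- function(tbl, digits, source, type) {
  out <- tibble::as_tibble(tbl)
  attr(out, "digits") <- digits
  attr(out, "source") <- source
  attr(out, "type") <- type
  class(out) <- c("pmd_db", class(out))
  out
}

#' Mine a reaction set into a PMD frequency database
#'
#' Each reaction contributes each of its (deduplicated) reaction-PMD values
#' at most once; the frequency of a PMD value is the number of contributing
#' reactions. Zero PMDs (isomer pairs) are retained but flagged, since they
#' carry isomer rather than reaction information; [top_k_pmds()] excludes
#' them by default.
#'
#' @param reactions A reaction table holding one or more reactions.
#' @param digits Decimals for PMD rounding (default 3).
#' @param source_name Optional provenance label stored on the result.
#' @return A `pmd_db` tibble: `pmd`, `frequency`, `compositions`
#'   (`";"`-separated union), `sources` (contributing reaction ids),
#'   `isomer` (TRUE for PMD 0), sorted by decreasing frequency then
#'   increasing PMD. Reactions with compounds lacking both mass and formula
#'   are skipped with a warning reporting the count.
#' @export
build_reaction_pmd_db <- function(reactions, digits = 3, source_name = NULL) {
  rs <- split_reactions(reactions)
  if (length(rs) == 0L) {
    stop("no reactions supplied", call. = FALSE)
  }
  usable <- vapply(rs, function(r) !any(is.na(r$mass)), logical(1))
  if (!any(usable)) {
    stop("no reaction has complete masses", call. = FALSE)
  }
  if (any(!usable)) {
    warning(sum(!usable), " reaction(s) skipped for missing masses",
            call. = FALSE)
  }
  rp <- reaction_pmd(dplyr::bind_rows(rs[usable]), digits = digits)
  db <- rp |>
    dplyr::group_by(.data$pmd) |>
    dplyr::summarise(
      frequency = dplyr::n_distinct(.data$reaction_id),
      compositions = paste(
        sort(unique(unlist(strsplit(stats::na.omit(.data$composition), ";",
                                    fixed = TRUE)))),
        collapse = ";"),
      sources = paste(unique(.data$reaction_id), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      compositions = dplyr::if_else(.data$compositions == "",
                                    NA_character_, .data$compositions),
      isomer = .data$pmd == 0
    ) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$pmd)
  new_pmd_db(db, digits, source_name, "reaction")
}

#' Deduplicate a compound table
#'
#' @param compounds A compound table (`compound_id`, `name`, `formula`,
#'   `mass`).
#' @param unique_by `"formula"` (canonicalized formula string), `"mass"`
#'   (mass rounded to `digits`), or `"auto"` (formula when available for all
#'   compounds, else mass).
#' @param digits Decimals used for the mass key.
#' @return The first compound row per key.
#' @export
dedupe_compounds <- function(compounds, unique_by = c("auto", "formula", "mass"),
                             digits = 3) {
  unique_by <- match.arg(unique_by)
  x <- as_compound_tbl(compounds)
  if (unique_by == "auto") {
    unique_by <- if (all(!is.na(x$formula))) "formula" else "mass"
  }
  key <- if (unique_by == "formula") {
    if (any(is.na(x$formula))) {
      stop("unique_by = 'formula' but some compounds lack formulas",
           call. = FALSE)
    }
    vapply(x$formula, function(f) format_formula(parse_formula(f)),
           character(1))
  } else {
    as.character(round_pmd(x$mass, digits))
  }
  x[!duplicated(key), ]
}

#' Mine a compound set into a pairwise-PMD frequency database
#'
#' Compounds are deduplicated first; then every unordered pair of unique
#' compounds contributes its PMD once, so frequencies count unique pairs.
#' This represents "common reactions between chemicals" when no explicit
#' reaction database is available.
#'
#' @param compounds A compound table with at least 2 unique compounds.
#' @param digits Decimals for PMD rounding (default 3).
#' @param unique_by Deduplication key, see [dedupe_compounds()].
#' @param source_name Optional provenance label.
#' @return A `pmd_db` tibble: `pmd`, `frequency`, `compositions` (when
#'   formulas are available, the heavier-minus-lighter delta strings),
#'   `sources` (pair ids `"a|b"`), `isomer`.
#' @export
compound_pairwise_pmd_db <- function(compounds, digits = 3,
                                     unique_by = "auto", source_name = NULL) {
  x <- dedupe_compounds(compounds, unique_by = unique_by, digits = digits)
  n <- nrow(x)
  if (n < 2L) {
    stop("need at least 2 unique compounds, got ", n, call. = FALSE)
  }
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  have_f <- all(!is.na(x$formula))
  comp <- if (have_f) {
    mapply(pair_composition, x$formula[i], x$mass[i], x$formula[j], x$mass[j],
           USE.NAMES = FALSE)
  } else {
    rep(NA_character_, length(i))
  }
  pairs <- tibble::tibble(
    pmd = pmd(x$mass[i], x$mass[j], digits),
    composition = comp,
    pair = paste0(x$compound_id[i], "|", x$compound_id[j])
  )
  db <- pairs |>
    dplyr::group_by(.data$pmd) |>
    dplyr::summarise(
      frequency = dplyr::n(),
      compositions = paste(sort(unique(stats::na.omit(.data$composition))),
                           collapse = ";"),
      sources = paste(.data$pair, collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      compositions = dplyr::if_else(.data$compositions == "",
                                    NA_character_, .data$compositions),
      isomer = .data$pmd == 0
    ) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$pmd)
  new_pmd_db(db, digits, source_name, "compound")
}

#' Highest-frequency PMD values of a database
#'
#' @param db A `pmd_db` (or any data frame with `pmd` and `frequency`
#'   columns).
#' @param k Number of values to return (default 10, the usual network
#'   screening depth).
#' @param exclude_zero Drop the PMD 0 (isomer) entry first (default TRUE).
#' @return Numeric vector of PMD values, frequency-descending (ties broken
#'   by increasing PMD). If fewer than `k` entries exist, all are returned
#'   with a warning.
#' @export
top_k_pmds <- function(db, k = 10, exclude_zero = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  x <- tibble::as_tibble(db)
  if (exclude_zero) x <- x[x$pmd != 0, ]
  x <- x[order(-x$frequency, x$pmd), ]
  if (k > nrow(x)) {
    warning("requested k = ", k, " but only ", nrow(x),
            " PMD entries available; returning all", call. = FALSE)
    k <- nrow(x)
  }
  x$pmd[seq_len(k)]
}
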