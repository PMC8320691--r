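# File dialects: comma-separated UTF-8 CSV for peak tables (m/z written at
# a fixed 4 decimals, never scientific notation, so rounding is
# reproducible); TSV for compounds and PMD databases; JSON for reactions
# and manifests.

#' Read a peak table CSV
#'
#' Expects a header row with `feature_id`, `mz`, optional `rt`, and one
#' numeric column per sample. Duplicate feature ids are rejected; missing
#' intensities are read as 0 (a message reports the count); malformed
#' numeric cells raise an error naming the location.
#'
#' @param path CSV file path.
#' @return A validated peak-table tibble.
#' @export
read_peak_table <- function(path) {
  t <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(t)
  if (nrow(probs) > 0L) {
    stop("malformed cell at row ", probs$row[1], ", column ", probs$col[1],
         ": expected ", probs$expected[1], call. = FALSE)
  }
  if (!"mz" %in% names(t)) stop("missing `mz` column", call. = FALSE)
  sc <- peak_sample_cols(t)
  bad <- sc[!vapply(t[sc], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    stop("non-numeric intensity column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_na <- sum(vapply(t[sc], function(x) sum(is.na(x)), integer(1)))
  if (n_na > 0L) {
    message(n_na, " missing intensities read as 0")
    t[sc] <- lapply(t[sc], function(x) ifelse(is.na(x), 0, x))
  }
  validate_peak_table(t)
}

#' Write a peak table CSV
#'
#' m/z is written with a fixed 4 decimals and intensities in plain (never
#' scientific) notation, so a written table re-reads to the same values.
#'
#' @param t A peak table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(t, path) {
  t <- validate_peak_table(t)
  out <- t
  out$mz <- formatC(out$mz, format = "f", digits = 4)
  sc <- peak_sample_cols(out)
  out[sc] <- lapply(out[sc], function(x) {
    sub("\\.?0+$", "", formatC(x, format = "f", digits = 6))
  })
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample_id`, `group`.
#' @return A tibble `sample_id`, `group`.
#' @export
read_sample_groups <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(g))) {
    stop("sample metadata needs `sample_id` and `group` columns",
         call. = FALSE)
  }
  g$sample_id <- as.character(g$sample_id)
  g$group <- as.character(g$group)
  tibble::as_tibble(g)
}

#' Read a compound table TSV
#'
#' Columns: `id`, `name`, `formula`, `monoisotopic_mass` (any of the last
#' two may be empty per row; mass is computed from the formula when
#' absent).
#'
#' @param path TSV file path.
#' @return A compound tibble (`compound_id`, `name`, `formula`, `mass`).
#' @export
read_compounds <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("monoisotopic_mass" %in% names(x)) {
    x <- dplyr::rename(x, mass = "monoisotopic_mass")
  }
  as_compound_tbl(x)
}

#' Write a compound table TSV
#'
#' @param compounds A compound tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  x <- as_compound_tbl(compounds)
  x <- dplyr::rename(x, id = "compound_id", monoisotopic_mass = "mass")
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read reactions from JSON or equation TSV
#'
#' JSON: an array of objects `{id, substrates: [{id, name, formula, mass}],
#' products: [...], annotation}`. TSV: two columns, reaction id and an
#' equation string of formulas such as `"C2H6+O2=C2H4+H2O2"` (compound ids
#' are the formulas themselves).
#'
#' @param path File path; format chosen by extension (`.json` else TSV).
#' @param recompute_mass Recompute all masses from formulas, ignoring any
#'   supplied mass (default FALSE).
#' @return A long reaction table (see [reaction_tbl()]).
#' @export
read_reactions <- function(path, recompute_mass = FALSE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- purrr::map(raw, function(r) {
      side <- function(s) {
        purrr::map(s, function(cpd) {
          tibble::tibble(
            compound_id = cpd$id %||% cpd$formula,
            name = cpd$name %||% cpd$id %||% cpd$formula,
            formula = cpd$formula %||% NA_character_,
            mass = as.numeric(cpd$mass %||% NA_real_)
          )
        }) |> purrr::list_rbind()
      }
      reaction_tbl(r$id, side(r$substrates), side(r$products),
                   annotation = r$annotation %||% NA_character_)
    }) |> purrr::list_rbind()
  } else {
    eqs <- readr::read_tsv(path, col_names = c("reaction_id", "equation"),
                           show_col_types = FALSE, progress = FALSE,
                           comment = "#")
    out <- purrr::map2(eqs$reaction_id, eqs$equation, function(rid, eq) {
      sides <- strsplit(eq, "=", fixed = TRUE)[[1]]
      if (length(sides) != 2L) {
        stop("equation needs exactly one '=': '", eq, "'", call. = FALSE)
      }
      parse_side <- function(s) {
        fs <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
        tibble::tibble(compound_id = fs, name = fs, formula = fs,
                       mass = NA_real_)
      }
      reaction_tbl(rid, parse_side(sides[1]), parse_side(sides[2]))
    }) |> purrr::list_rbind()
  }
  if (recompute_mass) {
    has_f <- !is.na(out$formula)
    out$mass[has_f] <- monoisotopic_mass(out$formula[has_f])
  }
  out
}

#' Write a PMD database
#'
#' @param db A `pmd_db` tibble.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_pmd_db <- function(db, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- tibble::as_tibble(db)
  if (format == "tsv") {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    jsonlite::write_json(
      list(digits = attr(db, "digits"), source = attr(db, "source"),
           type = attr(db, "type"), entries = x),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Export a PMD network
#'
#' GraphML keeps the PMD edge label as a string attribute (float map keys
#' are not portable); the TSV edge list has columns `source`, `target`,
#' `pmd`, `pearson_r`.
#'
#' @param net A `pmd_network`.
#' @param path Output path.
#' @param format `"graphml"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(net, "pmd_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    e <- dplyr::rename(net$edges, source = "from", target = "to")
    readr::write_tsv(e, path, progress = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
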