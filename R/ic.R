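IC_BINS <- c("(0,1)", "[1,2)", "[2,3)", "[3,4)", "[4,Inf)", "undefined")

ic_bin <- function(ic) {
  dplyr::case_when(
    is.na(ic) ~ "undefined",
    ic < 1 ~ "(0,1)",
    ic < 2 ~ "[1,2)",
    ic < 3 ~ "[2,3)",
    ic < 4 ~ "[3,4)",
    TRUE ~ "[4,Inf)"
  )
}

#' Read an HPO-style phenotype annotation table
#'
#' Parses the tab-separated curated annotation dialect used by phenotype
#' annotation releases: no header, `#` comment lines, the disease source
#' database and its identifier in the first two columns and the ontology
#' term id in the fifth. Column positions can be overridden.
#'
#' @param path File path.
#' @param db_col,db_id_col,term_col 1-based column positions of the disease
#'   database, disease identifier and ontology term id.
#' @return A tibble with columns `disease_id` (database:identifier) and
#'   `term_id`.
#' @export
read_phenotype_annotations <- function(path, db_col = 1, db_id_col = 2,
                                       term_col = 5) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < max(db_col, db_id_col, term_col)) {
    abort("annotation file has fewer columns than expected")
  }
  tibble::tibble(
    disease_id = paste(raw[[db_col]], raw[[db_id_col]], sep = ":"),
    term_id = raw[[term_col]]
  )
}

#' Information content of ontology terms from curated annotations
#'
#' The probability of a term is its share of the annotation records,
#' \eqn{p(t) = n(t) / N}, and its information content is
#' \eqn{IC(t) = -\log_{10} p(t)}: rare, specific terms score high. Terms of
#' the universe absent from the annotations have no defined probability and
#' are classified `undefined` (`ic = NA`).
#'
#' @param annotations A data frame with a `term_id` column (one row per
#'   annotation record, e.g. from [read_phenotype_annotations()]); must be
#'   non-empty.
#' @param terms The term universe: a character vector of term ids or a
#'   [ontology()] object (its non-obsolete terms).
#' @return A tibble of class `synsub_ic` with columns `term_id`, `n`, `p`,
#'   `ic`, `bin`, one row per universe term.
#' @examples
#' ann <- tibble::tibble(term_id = c(rep("a", 99), "b"))
#' information_content(ann, c("a", "b", "c"))
#' @export
information_content <- function(annotations, terms) {
  stopifnot(is.data.frame(annotations), "term_id" %in% names(annotations))
  if (nrow(annotations) == 0) abort("annotations are empty")
  if (inherits(terms, "synsub_ontology")) terms <- active_terms(terms)$id
  stopifnot(is.character(terms), length(terms) > 0)
  terms <- unique(terms)
  unknown <- setdiff(unique(annotations$term_id), terms)
  if (length(unknown) > 0) {
    inform(sprintf("%d annotated term id(s) outside the term universe (kept in the denominator)",
                   length(unknown)))
  }
  total <- nrow(annotations)
  counts <- dplyr::count(annotations, .data$term_id)
  out <- tibble::tibble(term_id = terms)
  out <- dplyr::left_join(out, counts, by = "term_id")
  out$n <- dplyr::coalesce(out$n, 0L)
  out$p <- out$n / total
  out$ic <- ifelse(out$p > 0, -log10(out$p), NA_real_)
  if (any(out$p == 1)) {
    warn("a term carries every annotation record (p = 1, ic = 0)")
  }
  out$bin <- ic_bin(out$ic)
  structure(out, class = c("synsub_ic", class(out)),
            n_records = total)
}

#' Bin terms by information content
#'
#' Tabulates a term universe into the half-open IC bins
#' `(0,1)`, `[1,2)`, `[2,3)`, `[3,4)` plus `undefined` (and `[4,Inf)` if any
#' term reaches it), with percentages over the universe.
#'
#' @param ic_table An [information_content()] result (or any data frame with
#'   a `bin` column).
#' @return A tibble with columns `bin`, `n_terms`, `pct_terms`.
#' @export
bin_ic <- function(ic_table) {
  stopifnot(is.data.frame(ic_table), "bin" %in% names(ic_table))
  bins <- intersect(IC_BINS, unique(c(ic_table$bin, setdiff(IC_BINS, "[4,Inf)"))))
  out <- dplyr::count(
    dplyr::mutate(tibble::as_tibble(ic_table),
                  bin = factor(.data$bin, levels = bins)),
    .data$bin, name = "n_terms", .drop = FALSE
  )
  out$bin <- as.character(out$bin)
  out$pct_terms <- 100 * out$n_terms / max(sum(out$n_terms), 1L)
  out
}
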