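# Readers and writers for the plain-text formats the pipeline exchanges:
# tab-separated expression matrices (genes as rows), sample label tables and
# one-symbol-per-line gene panels.

#' Read a gene-by-sample expression matrix
#'
#' Expects tab-separated text with a header row of sample identifiers and the
#' first column holding gene identifiers.  Values must be finite,
#' non-negative FPKM; duplicate gene or sample identifiers, missing cells and
#' ragged rows are rejected.  Round-trips bit-exactly with
#' [write_expression_matrix()] for finite decimal values.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  tab <- suppressWarnings(
    readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    stop_format(sprintf(
      "malformed expression matrix (%s): first problem at line %d",
      path, prob$row[1] + 1L
    ))
  }
  if (ncol(tab) < 2) stop_format("expression matrix needs a gene column and at least one sample")
  gene_ids <- tab[[1]]
  dup <- which(duplicated(gene_ids))
  if (length(dup) > 0) {
    stop_format(sprintf(
      "duplicate gene identifier '%s' at line %d", gene_ids[dup[1]], dup[1] + 1L
    ))
  }
  sample_ids <- names(tab)[-1]
  if (anyDuplicated(sample_ids)) {
    stop_format(sprintf(
      "duplicate sample identifier '%s' in header",
      sample_ids[duplicated(sample_ids)][1]
    ))
  }
  vals <- suppressWarnings(vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab), dimnames = list(gene_ids, sample_ids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_format(sprintf(
      "non-numeric or missing value for gene '%s', sample '%s'",
      gene_ids[bad[1]], sample_ids[bad[2]]
    ))
  }
  if (any(!is.finite(vals))) stop_domain("expression matrix contains non-finite values")
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop_domain(sprintf(
      "negative expression value for gene '%s', sample '%s'",
      gene_ids[bad[1]], sample_ids[bad[2]]
    ))
  }
  vals
}

#' Write a gene-by-sample expression matrix
#'
#' @param x Numeric matrix with gene row names and sample column names.
#' @param path Output TSV path.
#' @param gene_column Name of the first (gene identifier) column.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path, gene_column = "gene_id") {
  check_expression_matrix(x)
  tab <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[1] <- gene_column
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read or write per-sample outcome labels
#'
#' The label table is tab-separated with columns `sample_id`, `timepoint`
#' (`pre`/`post`), `agvhd` (0/1), `alive` (0/1) and `onset_day` (positive,
#' present only when `agvhd == 1`).
#'
#' @param path TSV path.
#' @return `read_cohort_labels()` returns a validated tibble.
#' @export
read_cohort_labels <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      timepoint = readr::col_character(),
      agvhd = readr::col_double(),
      alive = readr::col_double(),
      onset_day = readr::col_double()
    ),
    progress = FALSE
  )
  validate_cohort_labels(tab)
}

#' @rdname read_cohort_labels
#' @param labels Label tibble as described above.
#' @export
write_cohort_labels <- function(labels, path) {
  validate_cohort_labels(labels)
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}

validate_cohort_labels <- function(labels) {
  required <- c("sample_id", "timepoint", "agvhd", "alive")
  missing <- setdiff(required, names(labels))
  if (length(missing) > 0) {
    stop_format(sprintf("label table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(labels$sample_id)) {
    stop_format(sprintf(
      "duplicate sample_id '%s' in label table",
      labels$sample_id[duplicated(labels$sample_id)][1]
    ))
  }
  if (!all(labels$timepoint %in% c("pre", "post"))) {
    stop_format("`timepoint` must be 'pre' or 'post'")
  }
  as_binary(labels$agvhd, "agvhd")
  as_binary(labels$alive, "alive")
  if (!"onset_day" %in% names(labels)) labels$onset_day <- NA_real_
  bad_onset <- !is.na(labels$onset_day) & (labels$agvhd != 1 | labels$onset_day <= 0)
  if (any(bad_onset)) {
    stop_format(sprintf(
      "onset_day must be positive and present only for aGvHD cases (sample '%s')",
      labels$sample_id[bad_onset][1]
    ))
  }
  tibble::as_tibble(labels)
}

#' Normalise printed gene symbols
#'
#' Cleans gene symbols as they appear in published panel tables: surrounding
#' whitespace is removed, a parenthetical suffix is split off as an alias
#' (`"TFRC (CD71)"` gives symbol `TFRC`, alias `CD71`), a leading run of
#' digits immediately followed by letters is stripped — the classic
#' spreadsheet date-mangling artifact that turns `SEPT9` into `43717SEPT9` —
#' and the result is upper-cased.  Purely numeric tokens are rejected rather
#' than silently emptied.  The operation is idempotent on its own output.
#'
#' @param raw Character vector of raw symbols.
#' @return Tibble with columns `symbol` and `alias` (`NA` when absent).
#' @examples
#' normalize_symbol(c("TFRC (CD71)", "43717SEPT9", "FOXO3"))
#' @export
normalize_symbol <- function(raw) {
  if (length(raw) == 0) {
    return(tibble::tibble(symbol = character(), alias = character()))
  }
  if (!is.character(raw) || anyNA(raw)) stop_format("symbols must be non-missing character strings")
  x <- trimws(raw)
  has_alias <- grepl("\\(([^)]*)\\)", x)
  alias <- ifelse(has_alias, sub(".*\\(([^)]*)\\).*", "\\1", x), NA_character_)
  alias <- toupper(trimws(alias))
  alias[!is.na(alias) & alias == ""] <- NA_character_
  sym <- trimws(sub("\\s*\\([^)]*\\)", "", x))
  if (any(grepl("^[0-9]+$", sym))) {
    stop_format(sprintf(
      "purely numeric gene symbol '%s' is not allowed", sym[grepl("^[0-9]+$", sym)][1]
    ))
  }
  sym <- sub("^[0-9]+(?=[A-Za-z])", "", sym, perl = TRUE)
  sym <- toupper(sym)
  if (any(sym == "")) {
    stop_format(sprintf("symbol '%s' is empty after normalisation", raw[sym == ""][1]))
  }
  tibble::tibble(symbol = sym, alias = alias)
}

#' Read a gene panel file
#'
#' One raw symbol per line; blank lines are ignored; symbols are normalised
#' with [normalize_symbol()]; printed order is preserved; duplicates (after
#' normalisation) are rejected.
#'
#' @param path Path to a panel text file.
#' @param name Panel name (defaults to the file name without extension).
#' @return A `gene_panel`: tibble with columns `symbol`, `alias` and a
#'   `panel_name` attribute.
#' @seealso [bundled_panel()] for the panels shipped with the package.
#' @export
read_gene_panel <- function(path, name = NULL) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  panel <- normalize_symbol(lines)
  dup <- duplicated(panel$symbol)
  if (any(dup)) {
    stop_format(sprintf("duplicate gene symbol '%s' in panel", panel$symbol[dup][1]))
  }
  structure(panel,
    panel_name = name %||% sub("\\.[^.]*$", "", basename(path)),
    class = c("gene_panel", class(panel))
  )
}

#' Gene panels bundled with the package
#'
#' The two post-transplant predictor panels shipped as plain-text fixtures:
#' the 92-gene aGvHD panel and the 20-gene overall-survival panel, transcribed
#' in printed order (including the raw `"TFRC (CD71)"` and `"43717SEPT9"`
#' tokens, which [normalize_symbol()] cleans on read).
#'
#' @param which `"agvhd_post"` (92 genes) or `"survival_post"` (20 genes).
#' @return A `gene_panel` tibble.
#' @examples
#' nrow(bundled_panel("agvhd_post"))
#' @export
bundled_panel <- function(which = c("agvhd_post", "survival_post")) {
  which <- match.arg(which)
  file <- switch(which,
    agvhd_post = "panel_agvhd_post_92.txt",
    survival_post = "panel_survival_post_20.txt"
  )
  read_gene_panel(
    system.file("extdata", file, package = "gmbayes", mustWork = TRUE),
    name = which
  )
}

#' Restrict an expression matrix to a gene panel
#'
#' @param x Genes-by-samples matrix.
#' @param panel A `gene_panel`, or a character vector of gene identifiers.
#' @param policy `"strict"` errors if any panel gene is absent from the
#'   matrix; `"intersect"` keeps the overlap and records the missing genes in
#'   the `missing_genes` attribute of the result.
#' @return The sub-matrix with rows in panel order.
#' @export
align_panel <- function(x, panel, policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  check_expression_matrix(x)
  symbols <- if (is.data.frame(panel)) panel$symbol else as.character(panel)
  missing <- setdiff(symbols, rownames(x))
  if (policy == "strict" && length(missing) > 0) {
    stop_domain(sprintf(
      "panel gene(s) absent from matrix: %s",
      paste(missing, collapse = ", ")
    ))
  }
  keep <- symbols[symbols %in% rownames(x)]
  out <- x[keep, , drop = FALSE]
  attr(out, "missing_genes") <- missing
  out
}
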