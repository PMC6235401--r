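#' Construct a linkage matrix
#'
#' A linkage matrix records, for each species x gene cell, the outcome of a
#' male/female PCR assay: `M` (male-only amplification, i.e. Y-linkage),
#' `MF` (amplification in both sexes, i.e. autosomal or X linkage), `F`
#' (failure in both sexes, a candidate genomic loss) or `NA` (not tested /
#' assay failure). The container is a tibble whose first column is
#' `species` and whose remaining columns are genes.
#'
#' @param df A data frame with a `species` column and one character column
#'   per gene, cells in `M`/`MF`/`F`/`NA`.
#' @return A `linkage_matrix` (tibble subclass).
#' @examples
#' linkage_matrix(data.frame(
#'   species = c("nannoptera", "pseudoobscura"),
#'   ORY = c("MF", "MF")
#' ))
#' @export
linkage_matrix <- function(df) {
  df <- as_tibble(df)
  if (!"species" %in% names(df)) {
    abort("linkage matrix needs a 'species' column")
  }
  df <- dplyr::relocate(df, species)
  if (ncol(df) < 2L) abort("linkage matrix has no gene columns")
  df$species <- trimws(as.character(df$species))
  if (any(!nzchar(df$species))) abort("empty species names in linkage matrix")
  dup <- unique(df$species[duplicated(df$species)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated species rows: %s", paste(dup, collapse = ", ")))
  }
  for (g in names(df)[-1]) {
    df[[g]] <- normalize_states(df[[g]], g, df$species)
  }
  class(df) <- c("linkage_matrix", class(tibble()))
  df
}

# synonym map for observation states; extended via the `synonyms` argument
# of read_linkage_matrix
.STATE_SYNONYMS <- setNames(
  c(
    "M", "M", "M",
    "MF", "MF", "MF", "MF", "MF",
    "F", "F", "F",
    NA_character_, NA_character_, NA_character_, NA_character_
  ),
  c(
    "m", "male", "y",
    "mf", "male+female", "both", "ax", "a/x",
    "f", "fail", "failed",
    "na", "-", "", "?"
  )
)

normalize_states <- function(x, gene, species, synonyms = character()) {
  x <- trimws(as.character(x))
  key <- tolower(x)
  out <- ifelse(is.na(x), NA_character_, unname(.STATE_SYNONYMS[key]))
  extra <- synonyms
  if (length(extra) > 0) {
    names(extra) <- tolower(names(extra))
    hit <- !is.na(x) & key %in% names(extra)
    out[hit] <- unname(extra[key[hit]])
  }
  bad <- !is.na(x) & !(key %in% c(names(.STATE_SYNONYMS), names(extra)))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "unknown linkage state '%s' at species '%s', gene '%s' (expected M/MF/F/NA)",
      x[i], species[i], gene
    ))
  }
  out
}

#' @export
print.linkage_matrix <- function(x, ...) {
  cat(sprintf(
    "<linkage_matrix> %d species x %d genes\n",
    nrow(x), ncol(x) - 1L
  ))
  NextMethod()
}

#' Gene names of a linkage matrix
#' @param matrix A `linkage_matrix`.
#' @return Character vector of gene column names.
#' @export
linkage_genes <- function(matrix) {
  setdiff(names(matrix), "species")
}

#' Read a species x gene linkage matrix from delimited text
#'
#' Expects a header row of gene names and a first column of species names;
#' cells are matched case-insensitively against the canonical tokens `M`,
#' `MF`, `F`, `NA` and a synonym map (`"male"`, `"male+female"`, `"fail"`,
#' `"-"`, ...). Tab-separated by default; comma-separated via `delim = ","`.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @param synonyms Optional named character vector of extra state synonyms,
#'   e.g. `c("male-only" = "M")`.
#' @return A [linkage_matrix()].
#' @export
read_linkage_matrix <- function(path, delim = "\t", synonyms = character()) {
  if (!file.exists(path)) abort(sprintf("linkage matrix file not found: '%s'", path))
  df <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, show_col_types = FALSE
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort(sprintf("empty or column-less linkage matrix: '%s'", path))
  }
  names(df)[1] <- "species"
  if (length(synonyms) > 0) {
    for (g in names(df)[-1]) {
      df[[g]] <- normalize_states(df[[g]], g, df[[1]], synonyms = synonyms)
    }
  }
  linkage_matrix(df)
}

#' Write a linkage matrix to delimited text
#'
#' Round-trips cell-for-cell with [read_linkage_matrix()]; `NA` cells are
#' written as the literal token `NA`.
#'
#' @param matrix A `linkage_matrix`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_linkage_matrix <- function(matrix, path, delim = "\t") {
  stopifnot(inherits(matrix, "linkage_matrix"))
  readr::write_delim(as_tibble(matrix), path, delim = delim, na = "NA")
  invisible(path)
}

#' Pivot a linkage matrix to long form
#'
#' @param matrix A `linkage_matrix`.
#' @return A tibble with columns `species`, `gene`, `state`.
#' @export
linkage_long <- function(matrix) {
  tidyr::pivot_longer(
    as_tibble(matrix), -species,
    names_to = "gene", values_to = "state"
  )
}

#' Gene class labels: ancestrally Y-linked vs control genes
#'
#' For "re-acquisition" contingency tables the genes are split into those
#' present on the ancestral Y of the focal clade and control genes (male
#' genes that are autosomal in the clade ancestor but Y-linked elsewhere,
#' hence acquirable by the Y). The two sets must be disjoint.
#'
#' @param ancestral_Y Character vector of gene names on the ancestral Y.
#' @param control Character vector of control gene names.
#' @return A `gene_class_labels` list.
#' @export
gene_class_labels <- function(ancestral_Y, control) {
  ancestral_Y <- unique(as.character(ancestral_Y))
  control <- unique(as.character(control))
  shared <- intersect(ancestral_Y, control)
  if (length(shared) > 0) {
    abort(sprintf(
      "gene class labels overlap: %s", paste(shared, collapse = ", ")
    ))
  }
  structure(
    list(ancestral_Y = ancestral_Y, control = control),
    class = "gene_class_labels"
  )
}

#' Read gene class labels from a two-column TSV (gene, class)
#'
#' Classes are `ancestral_Y` and `control` (synonyms `Y`/`ancestral` and
#' `ctrl` accepted, case-insensitively).
#'
#' @param path Path to the TSV file.
#' @return A [gene_class_labels()] object.
#' @export
read_gene_labels <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE
  )
  if (ncol(df) < 2L) abort("labels file needs columns: gene, class")
  names(df)[1:2] <- c("gene", "class")
  cls <- tolower(trimws(df$class))
  anc <- df$gene[cls %in% c("ancestral_y", "ancestral", "y")]
  ctl <- df$gene[cls %in% c("control", "ctrl")]
  unknown <- df$class[!cls %in% c("ancestral_y", "ancestral", "y", "control", "ctrl")]
  if (length(unknown) > 0) {
    abort(sprintf("unknown gene class label(s): %s", paste(unique(unknown), collapse = ", ")))
  }
  gene_class_labels(anc, ctl)
}

#' Validate a tree / linkage-matrix pair
#'
#' Collects problems into a report instead of failing: errors make the
#' dataset unusable (species in the matrix missing from the tree), warnings
#' flag degraded analyses (all-`NA` gene columns, which are uninformative;
#' missing branch lengths, which disable exposure and rate estimation;
#' tree tips never observed in the matrix).
#'
#' @param tree A `phylo` object.
#' @param matrix A `linkage_matrix`.
#' @return A `validation_report` with fields `errors` and `warnings`
#'   (character vectors); `is_valid(report)` is `TRUE` iff no errors.
#' @export
validate_dataset <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "linkage_matrix"))
  errors <- character()
  warnings <- character()

  missing_sp <- setdiff(matrix$species, tree$tip.label)
  if (length(missing_sp) > 0) {
    errors <- c(errors, sprintf(
      "species in matrix but not in tree: %s", paste(missing_sp, collapse = ", ")
    ))
  }
  extra_tips <- setdiff(tree$tip.label, matrix$species)
  if (length(extra_tips) > 0) {
    warnings <- c(warnings, sprintf(
      "tree tips without matrix rows (treated as NA): %s",
      paste(extra_tips, collapse = ", ")
    ))
  }
  all_na <- linkage_genes(matrix)[vapply(
    linkage_genes(matrix),
    function(g) all(is.na(matrix[[g]])), logical(1)
  )]
  if (length(all_na) > 0) {
    warnings <- c(warnings, sprintf(
      "gene column(s) entirely NA, uninformative: %s", paste(all_na, collapse = ", ")
    ))
  }
  if (!has_branch_lengths(tree)) {
    warnings <- c(warnings,
      "tree has no branch lengths: exposure/rate estimation unavailable")
  }
  structure(
    list(errors = errors, warnings = warnings),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (length(x$errors) == 0 && length(x$warnings) == 0) {
    cat("  dataset OK\n")
  }
  for (e in x$errors) cat("  error:   ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Is a validated dataset usable?
#' @param report A `validation_report`.
#' @return `TRUE` iff the report carries no errors.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  length(report$errors) == 0L
}
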