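#' Load a packaged worked-example dataset
#'
#' The package ships small datasets transcribed from published figures and
#' tables of the Drosophila Y-chromosome gene-content survey they illustrate:
#'
#' * `"fig2_ory"` — the eight-species ORY example: tree
#'   `(mel,(vir,((aca,nan),(imm,(afr,(bog,dav))))));` with ORY amplifying in
#'   both sexes (`MF`) in *D. nannoptera* and the three *Zaprionus* species
#'   (`afr`, `bog`, `dav`) and male-only (`M`) elsewhere. Dollo parsimony
#'   with an ancestrally Y-linked root infers exactly two movement events.
#' * `"fig1_pairs"` — the four-gene PCR comparison of *D. nannoptera*
#'   (single ORY movement) and *D. pseudoobscura* (whole-Y incorporation:
#'   all genes `MF`).
#' * `"montium_partial"` — a partial encoding of the *montium*-subgroup
#'   matrix. Only facts stated in running text are encoded (the full
#'   40-species matrix is not published in the main text): the *auraria*
#'   clade is entirely `MF`; the *kikkawai* clade keeps `kl-2` and `WDY`
#'   male-only; *D. parvula* and *D. kanapiae* share `kl-5` and `PRY` on the
#'   Y; *D. nikananu* has `kl-5`, `PRY`, `ORY`, `ARY` male-only while its
#'   sister *D. diplacantha* has the same four genes `MF`. Unstated cells
#'   are `NA`. The element `summary` is a one-row synthetic clade-level
#'   matrix recording, per gene, whether the gene is Y-linked in at least
#'   one *montium* species (from the published table footnotes); it is the
#'   input that reproduces the 9/2/0/4 re-acquisition table. `labels`
#'   classifies the 11 ancestrally Y-linked genes versus the 4 control
#'   genes.
#' * `"table1_counts"` — the published 2x2 re-acquisition table
#'   (9, 2; 0, 4): ancestrally Y-linked genes with/without Y-linkage in at
#'   least one *montium* species, versus control genes.
#'
#' @param name One of `"fig2_ory"`, `"fig1_pairs"`, `"montium_partial"`,
#'   `"table1_counts"`.
#' @return A list with elements among `tree` (`phylo`), `matrix`
#'   (`linkage_matrix`), `labels` (`gene_class_labels`), `summary`
#'   (`linkage_matrix`), `counts` (`contingency_2x2`).
#' @examples
#' fx <- load_fixture("fig2_ory")
#' fx$matrix
#' @export
load_fixture <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  path <- function(f) {
    system.file("extdata", f, package = "ycontent", mustWork = TRUE)
  }
  switch(name,
    fig2_ory = list(
      tree = read_tree_file(path("fig2_ory.nwk")),
      matrix = read_linkage_matrix(path("fig2_ory.tsv"))
    ),
    fig1_pairs = list(
      matrix = read_linkage_matrix(path("fig1_pairs.tsv"))
    ),
    montium_partial = list(
      tree = read_tree_file(path("montium_partial.nwk")),
      matrix = read_linkage_matrix(path("montium_partial.tsv")),
      summary = read_linkage_matrix(path("montium_summary.tsv")),
      labels = read_gene_labels(path("montium_labels.tsv"))
    ),
    table1_counts = {
      df <- readr::read_tsv(path("table1_counts.tsv"), show_col_types = FALSE)
      list(counts = contingency_2x2(
        df$moved_to_Y[1], df$not_moved[1],
        df$moved_to_Y[2], df$not_moved[2]
      ))
    },
    abort(sprintf(
      "unknown fixture '%s' (available: fig2_ory, fig1_pairs, montium_partial, table1_counts)",
      name
    ))
  )
}

#' List the packaged fixture files and their checksums
#'
#' Fixtures are immutable inputs; tests compare these MD5 sums against
#' frozen values so accidental edits are caught.
#'
#' @return A tibble with columns `file` and `md5`.
#' @export
fixture_checksums <- function() {
  dir <- system.file("extdata", package = "ycontent", mustWork = TRUE)
  files <- sort(list.files(dir))
  tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
}

#' Export the packaged fixtures to a directory
#'
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_fixtures <- function(dir) {
  src <- system.file("extdata", package = "ycontent", mustWork = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- file.copy(list.files(src, full.names = TRUE), dir, overwrite = TRUE)
  if (!all(ok)) abort("failed to copy fixture files")
  invisible(dir)
}
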