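#' Load the 116-region anatomical label table
#'
#' The bundled table is the standard 116-region automated anatomical
#' labelling (AAL) parcellation used to extract regional time series:
#' 90 cerebral regions (45 per hemisphere) plus 26 cerebellar/vermal
#' regions (9 per cerebellar hemisphere, 8 vermis).  Left/right homologue
#' regions occupy consecutive indices and share an abbreviation.
#'
#' @param path optional path to an alternative TSV with columns
#'   `index`, `name`, `abbreviation`, `division`; defaults to the bundled
#'   fixture.
#' @return a `region_table` data frame with columns `index` (integer
#'   1..116), `name`, `abbreviation` and `division` (one of `"cerebrum"`,
#'   `"cerebellum"`, `"vermis"`).
#' @examples
#' rt <- load_region_table()
#' nrow(rt)                        # 116
#' table(rt$division)
#' @export
load_region_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal116_regions.tsv", package = "phasenet")
  }
  if (!nzchar(path) || !file.exists(path)) stopf("region table file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    index = "integer", name = "character",
    abbreviation = "character", division = "character"
  ))
  validate_region_table(tab)
  class(tab) <- c("region_table", "data.frame")
  tab
}

validate_region_table <- function(tab) {
  need <- c("index", "name", "abbreviation", "division")
  if (!all(need %in% names(tab))) {
    stopf("region table must have columns: %s", paste(need, collapse = ", "))
  }
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    if (is.na(row$index) || !nzchar(row$name) || !nzchar(row$abbreviation) ||
        !row$division %in% c("cerebrum", "cerebellum", "vermis")) {
      stopf("malformed region table row %d", r)
    }
  }
  if (nrow(tab) != 116) stopf("region table must have 116 rows, got %d", nrow(tab))
  if (!identical(sort(tab$index), 1:116)) stopf("region indices must be exactly 1..116")
  n_cer <- sum(tab$division == "cerebrum")
  n_sub <- sum(tab$division %in% c("cerebellum", "vermis"))
  if (n_cer != 90 || n_sub != 26) {
    stopf("expected 90 cerebral and 26 cerebellar+vermal regions, got %d/%d", n_cer, n_sub)
  }
  invisible(tab)
}

#' Look up regions by index or abbreviation
#'
#' @param table a `region_table` from [load_region_table()]
#' @param key an integer region index or a character abbreviation
#'   (case sensitive, e.g. `"Ins"` matches both insular regions)
#' @return the matching rows of `table`; zero rows if nothing matches.
#' @examples
#' rt <- load_region_table()
#' region_lookup(rt, 31)$name
#' region_lookup(rt, "PUT")$index  # c(73, 74)
#' @export
region_lookup <- function(table, key) {
  stopifnot(inherits(table, "region_table"))
  if (is.numeric(key)) {
    table[table$index %in% as.integer(key), , drop = FALSE]
  } else if (is.character(key)) {
    table[table$abbreviation %in% key, , drop = FALSE]
  } else {
    stopf("key must be an integer index or a character abbreviation")
  }
}

#' @export
print.region_table <- function(x, ...) {
  if (is.null(x$division)) {           # column subset: plain display
    print(as.data.frame(x))
    return(invisible(x))
  }
  cat(sprintf(
    "Anatomical region table: %d regions (%d cerebrum, %d cerebellum, %d vermis)\n",
    nrow(x), sum(x$division == "cerebrum"),
    sum(x$division == "cerebellum"), sum(x$division == "vermis")
  ))
  print(utils::head(as.data.frame(x), 6))
  cat("...\n")
  invisible(x)
}
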