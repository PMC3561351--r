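#' Write / read one subject's regional time series as TSV
#'
#' Rows are regions, columns time samples; a header row carries sample
#' indices and row names carry region indices.  The sampling interval and
#' group label travel in `# key: value` comment lines at the top.
#'
#' @param subject a `subject_ts`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_subject_tsv <- function(subject, path) {
  stopifnot(inherits(subject, "subject_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id: %s", subject$subject_id),
    sprintf("# group: %s", subject$group),
    sprintf("# sampling_interval: %.10g", subject$sampling_interval)
  ), con)
  df <- as.data.frame(subject$data)
  names(df) <- sprintf("t%d", seq_len(ncol(subject$data)))
  write.table(cbind(region = seq_len(nrow(df)), df), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_tsv
#' @param path file written by [write_subject_tsv()]
#' @return for the reader, a `subject_ts`
#' @export
read_subject_tsv <- function(path) {
  if (!file.exists(path)) stopf("subject file not found: %s", path)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- function(key, default = NA_character_) {
    line <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(line)) return(default)
    trimws(sub(sprintf("^# %s:", key), "", line[1]))
  }
  tab <- read.delim(path, comment.char = "#", check.names = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(X) <- NULL
  structure(
    list(
      subject_id = meta("subject_id", basename(path)),
      group = meta("group", "control"),
      data = X,
      sampling_interval = as.numeric(meta("sampling_interval", "1"))
    ),
    class = "subject_ts"
  )
}

#' Write / read a square network matrix as dense TSV
#'
#' Header row and first column carry region indices; weighted values are
#' printed at 6 decimal places, binary matrices as integers.
#'
#' @param M square matrix
#' @param path output file
#' @export
write_network_tsv <- function(M, path) {
  M <- unclass(M)
  vals <- if (all(M %in% c(0, 1))) {
    matrix(as.integer(M), nrow(M))
  } else {
    matrix(sprintf("%.6f", M), nrow(M))
  }
  df <- cbind(region = seq_len(nrow(M)), as.data.frame(vals))
  names(df) <- c("region", sprintf("r%d", seq_len(ncol(M))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  if (!file.exists(path)) stopf("network file not found: %s", path)
  tab <- read.delim(path, check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  M
}

#' Write a cohort to disk (per-subject TSVs, manifest, truth file)
#'
#' @param cohort a `cohort` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return path to the manifest TSV, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    paths[i] <- file.path(dir, sprintf("%s.tsv", s$subject_id))
    write_subject_tsv(s, paths[i])
  }
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, function(s) s$subject_id, character(1)),
    group = vapply(cohort$subjects, function(s) s$group, character(1)),
    path = basename(paths),
    stringsAsFactors = FALSE
  )
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- cohort$truth$planted_edges
  truth <- if (is.null(edges) || nrow(edges) == 0) {
    data.frame(i = integer(0), j = integer(0))
  } else {
    data.frame(i = pmin(edges[, 1], edges[, 2]), j = pmax(edges[, 1], edges[, 2]))
  }
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort back from a manifest TSV
#'
#' @param manifest path to a `manifest.tsv` written by [write_cohort()]
#' @return a `cohort` (the `truth` slot is populated when `truth.tsv`
#'   sits next to the manifest)
#' @export
read_cohort <- function(manifest) {
  if (!file.exists(manifest)) stopf("manifest not found: %s", manifest)
  dir <- dirname(manifest)
  man <- read.delim(manifest, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    s <- read_subject_tsv(file.path(dir, man$path[i]))
    s$subject_id <- man$subject_id[i]
    s$group <- man$group[i]
    s
  })
  tpath <- file.path(dir, "truth.tsv")
  truth <- list(planted_edges = NULL)
  if (file.exists(tpath)) {
    tt <- read.delim(tpath)
    if (nrow(tt) > 0) truth$planted_edges <- as.matrix(tt)
  }
  structure(list(subjects = subjects, truth = truth), class = "cohort")
}
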