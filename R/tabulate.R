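# Stratified count table, molecular-weight summary, and novelty annotation.

.COL_KEYS <- c("N", "NH", "NH2", "N/N", "N/NH", "N/NH2",
               "NH/NH", "NH/NH2", "NH2/NH2", "total")

.size_row_key <- function(sizes) paste(sizes, collapse = ",")

.row_keys_for <- function(scaffolds) {
  size_keys <- unique(vapply(scaffolds, function(s)
    .size_row_key(s$ring_sizes), character(1)))
  # singles ascending, then pairs in lexicographic order
  singles <- sort(as.integer(size_keys[!grepl(",", size_keys)]))
  pairs <- size_keys[grepl(",", size_keys)]
  if (length(pairs) > 0L) {
    pm <- do.call(rbind, lapply(strsplit(pairs, ","), as.integer))
    pairs <- pairs[order(pm[, 1], pm[, 2])]
  }
  c(as.character(singles), pairs, .RING_TYPES, "total")
}

#' Build the stratified scaffold count table
#'
#' Cross-tabulates a scaffold set by row stratum and amine-type column.
#' Rows are the single ring sizes, then the ring-size pairs, then the four
#' ring topologies, then a total row; columns are the nine amine-type
#' profiles (N, NH, NH2 and their pairwise combinations) plus a total.
#' Each scaffold increments exactly one size row and one type row, so the
#' size block and the type block each sum to the total row. Totals are
#' always derived, never stored independently.
#'
#' @param scaffolds List of `scaffold` objects (may be empty, in which case
#'   the default size rows 5, 6, 7 and their pairs are emitted with zeros).
#' @param novel Optional logical vector, named by canonical key, marking
#'   scaffolds absent from a reference collection (see
#'   [annotate_novelty()]); adds a parallel novel-count matrix.
#' @return A `count_table`: list with `row_keys`, `col_keys`, integer
#'   matrix `counts`, and optionally `novel_counts`.
#' @export
build_table <- function(scaffolds, novel = NULL) {
  if (length(scaffolds) == 0L) {
    sizes <- 5:7
    pair_keys <- character(0)
    for (i in seq_along(sizes)) {
      for (j in i:length(sizes)) {
        pair_keys <- c(pair_keys, .size_row_key(c(sizes[i], sizes[j])))
      }
    }
    rows <- c(as.character(sizes), pair_keys, .RING_TYPES, "total")
  } else {
    rows <- .row_keys_for(scaffolds)
  }
  counts <- matrix(0L, nrow = length(rows), ncol = length(.COL_KEYS),
                   dimnames = list(rows, .COL_KEYS))
  novel_counts <- if (is.null(novel)) NULL else counts
  for (s in scaffolds) {
    col <- s$column_key
    if (!col %in% .COL_KEYS) stop("malformed amine profile '", col, "'")
    srow <- .size_row_key(s$ring_sizes)
    trow <- s$ring_type
    inc <- rbind(c(srow, col), c(trow, col))
    counts[inc] <- counts[inc] + 1L
    if (!is.null(novel_counts) && isTRUE(novel[[s$key]])) {
      novel_counts[inc] <- novel_counts[inc] + 1L
    }
  }
  derive <- function(m) {
    size_rows <- rows[!rows %in% c(.RING_TYPES, "total")]
    m["total", ] <- colSums(m[size_rows, , drop = FALSE])
    m[, "total"] <- rowSums(m[, setdiff(.COL_KEYS, "total"), drop = FALSE])
    storage.mode(m) <- "integer"
    m
  }
  counts <- derive(counts)
  if (!is.null(novel_counts)) novel_counts <- derive(novel_counts)
  structure(list(row_keys = rows, col_keys = .COL_KEYS, counts = counts,
                 novel_counts = novel_counts), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  m <- x$counts
  if (!is.null(x$novel_counts)) {
    m <- matrix(paste(x$novel_counts, x$counts, sep = "/"),
                nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  }
  print(as.data.frame(m))
  invisible(x)
}

#' Molecular-weight summary of a scaffold set
#'
#' Count, mean and standard deviation (population form) of the molecular
#' weights of a unique scaffold set.
#'
#' @param scaffolds Non-empty list of `scaffold` objects.
#' @return List with `n`, `mean_mw`, `sd_mw` (Da).
#' @export
summary_stats <- function(scaffolds) {
  if (length(scaffolds) == 0L) stop("summary statistics undefined for an empty set")
  w <- vapply(scaffolds, function(s) s$formula$weight, numeric(1))
  list(n = length(w), mean_mw = mean(w),
       sd_mw = sqrt(mean((w - mean(w))^2)))
}

#' Annotate scaffold novelty against a reference list
#'
#' Flags each scaffold as novel when its canonical key is absent from a
#' user-supplied reference collection of SMILES strings and/or canonical
#' keys — an offline stand-in for a database occurrence lookup. SMILES
#' entries are parsed and canonicalized before comparison; entries that
#' parse as neither are skipped with a warning.
#'
#' @param scaffolds List of `scaffold` objects.
#' @param reference Character vector of SMILES or canonical keys.
#' @return List with `novel` (logical vector named by canonical key),
#'   `n_novel`, `n_total`, and `n_skipped` (unparseable reference entries).
#' @export
annotate_novelty <- function(scaffolds, reference) {
  ref_keys <- character(0)
  n_skipped <- 0L
  for (entry in reference) {
    entry <- trimws(entry)
    if (!nzchar(entry)) next
    if (grepl("^[CN]+:", entry)) {  # already a canonical key
      ref_keys <- c(ref_keys, entry)
      next
    }
    g <- tryCatch(parse_smiles(entry), error = function(e) NULL)
    if (is.null(g)) {
      warning("skipping unparseable reference entry: ", entry, call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    ref_keys <- c(ref_keys, canonical_key(g))
  }
  keys <- vapply(scaffolds, function(s) s$key, character(1))
  novel <- !(keys %in% ref_keys)
  names(novel) <- keys
  list(novel = novel, n_novel = sum(novel), n_total = length(novel),
       n_skipped = n_skipped)
}

#' Write the pipeline outputs
#'
#' Writes the count table as CSV (cells rendered `novel/total` when a
#' novelty annotation is present), the scaffold set as a tab-separated
#' SMILES file, and a JSON summary with the scaffold count, molecular
#' weight statistics and per-row totals.
#'
#' @param table A `count_table`.
#' @param stats A summary from [summary_stats()].
#' @param scaffolds List of `scaffold` objects.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(table, stats, scaffolds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(table = file.path(dir, "count_table.csv"),
             scaffolds = file.path(dir, "scaffolds.smi"),
             summary = file.path(dir, "summary.json"))
  write_count_table(table, paths[["table"]])
  write_scaffolds(scaffolds, paths[["scaffolds"]])
  row_totals <- as.list(table$counts[, "total"])
  jsonlite::write_json(
    list(n = stats$n, mean_mw = round(stats$mean_mw, 4),
         sd_mw = round(stats$sd_mw, 4), row_totals = row_totals),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a count table as CSV
#'
#' Header row is the column keys; the first column holds the row keys.
#' Cells are plain totals, or `novel/total` when the table carries a
#' novelty annotation.
#'
#' @param table A `count_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  m <- table$counts
  cells <- if (is.null(table$novel_counts)) {
    matrix(as.character(m), nrow = nrow(m))
  } else {
    matrix(paste(table$novel_counts, m, sep = "/"), nrow = nrow(m))
  }
  lines <- c(paste(c("stratum", table$col_keys), collapse = ","),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(shQuote(table$row_keys[i], type = "cmd"), cells[i, ]),
                     collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path CSV file path.
#' @return A `count_table` (novelty column restored when present).
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-1], ",(?=(?:[^\"]*\"[^\"]*\")*[^\"]*$)", perl = TRUE)
  rows <- vapply(body, function(x) gsub("\"", "", x[1]), character(1))
  cells <- do.call(rbind, lapply(body, `[`, -1))
  has_novel <- any(grepl("/", cells, fixed = TRUE))
  split2 <- function(which) {
    matrix(as.integer(vapply(strsplit(cells, "/", fixed = TRUE), function(p)
      if (length(p) == 2L) p[which] else p[1], character(1))),
      nrow = length(rows), dimnames = list(rows, header))
  }
  counts <- if (has_novel) split2(2L) else
    matrix(as.integer(cells), nrow = length(rows), dimnames = list(rows, header))
  novel <- if (has_novel) split2(1L) else NULL
  structure(list(row_keys = rows, col_keys = header, counts = counts,
                 novel_counts = novel), class = "count_table")
}
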