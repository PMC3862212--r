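#' Construct a count table
#'
#' A count table holds per-category, per-sample sequence counts from one of the
#' four data sources: wild-type or HPRT-mutant cells, sequenced after mass
#' culture (MC) or from single-cell-derived isolates (SC).
#'
#' @param counts a K x S matrix of non-negative integers (categories in rows,
#'   samples in columns), or anything coercible to one.
#' @param categories character vector of K unique category labels (CDR3 types).
#'   Defaults to `rownames(counts)`.
#' @param samples character vector of S unique sample labels (subjects).
#'   Defaults to `colnames(counts)`.
#' @param source_tag one of `"WT-MC"`, `"MT-MC"`, `"WT-SC"`, `"MT-SC"`.
#' @return an integer matrix of class `"count_table"` with category row names,
#'   sample column names and a `source_tag` attribute.
#' @examples
#' count_table(matrix(c(1, 2, 3, 4), 2), c("a", "b"), c("s1", "s2"), "WT-MC")
#' @export
count_table <- function(counts, categories = rownames(counts),
                        samples = colnames(counts),
                        source_tag = c("WT-MC", "MT-MC", "WT-SC", "MT-SC")) {
  source_tag <- match.arg(source_tag)
  counts <- as.matrix(counts)
  if (is.null(categories)) stop("category labels are required")
  if (is.null(samples)) stop("sample labels are required")
  if (anyDuplicated(categories)) stop("duplicate category labels")
  if (anyDuplicated(samples)) stop("duplicate sample labels")
  if (nrow(counts) != length(categories) || ncol(counts) != length(samples))
    stop("counts dimensions do not match label lengths")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 categories[bad[1, 1]], samples[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(categories, samples)
  structure(counts, source_tag = source_tag,
            class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d categories x %d samples, total %d\n",
              attr(x, "source_tag"), nrow(x), ncol(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Read a count table from a tab-separated file
#'
#' The file is UTF-8 TSV: a header row of sample labels, a first column of
#' category labels, an integer body. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @inheritParams count_table
#' @return a [count_table()].
#' @export
read_count_table <- function(path, source_tag) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   check.names = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty count table body in ", path)
  categories <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative cell at row '%s', column '%s' in %s",
                 categories[bad[1, 1]], colnames(body)[bad[1, 2]], path))
  }
  count_table(num, categories, colnames(body), source_tag)
}

#' Write a count table to a tab-separated file
#'
#' @param x a [count_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(type = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-sample bottleneck metadata
#'
#' @param sample sample labels.
#' @param s number of cells subjected to 6-thioguanine selection (positive).
#' @param f HPRT mutant frequency, in (0, 1). The product `s * f` is the
#'   expected number of bottleneck survivors.
#' @return a data frame of class `"sample_meta"`.
#' @export
sample_meta <- function(sample, s, f) {
  s <- rep_len(as.numeric(s), length(sample))
  f <- rep_len(as.numeric(f), length(sample))
  if (any(!is.finite(s) | s <= 0 | s != round(s)))
    stop("s must be a positive integer count of treated cells")
  if (any(!is.finite(f) | f <= 0 | f >= 1))
    stop("f must lie strictly within (0, 1)")
  structure(data.frame(sample = as.character(sample), s = s, f = f,
                       stringsAsFactors = FALSE),
            class = c("sample_meta", "data.frame"))
}

#' Read per-sample metadata from a tab-separated file
#'
#' Expects columns `sample`, `s`, `f`.
#'
#' @param path file path.
#' @return a [sample_meta()] data frame.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("sample", "s", "f")
  if (!all(need %in% names(df)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  sample_meta(df$sample, df$s, df$f)
}

align_categories <- function(tables) {
  cats <- unique(unlist(lapply(tables, rownames)))
  lapply(tables, function(tb) {
    if (is.null(tb)) return(NULL)
    out <- matrix(0L, length(cats), ncol(tb), dimnames = list(cats, colnames(tb)))
    out[rownames(tb), ] <- tb
    count_table(out, cats, colnames(tb), attr(tb, "source_tag"))
  })
}

#' Assemble a four-source T-cell receptor dataset
#'
#' Aligns the four count tables on one shared, ordered category list
#' (categories absent from a table are zero-filled) and attaches per-sample
#' bottleneck metadata.
#'
#' @param wt_mc,mt_mc,wt_sc,mt_sc [count_table()] objects (any may be `NULL`).
#' @param meta optional [sample_meta()]; required by any analysis that touches
#'   MT-MC data (the Poisson bottleneck needs `s` and `f`).
#' @return a list of class `"tcr_dataset"` with elements `tables` (named list)
#'   and `meta`.
#' @export
tcr_dataset <- function(wt_mc = NULL, mt_mc = NULL, wt_sc = NULL, mt_sc = NULL,
                        meta = NULL) {
  tables <- list(wt_mc = wt_mc, mt_mc = mt_mc, wt_sc = wt_sc, mt_sc = mt_sc)
  if (all(vapply(tables, is.null, logical(1L))))
    stop("at least one count table is required")
  tags <- c(wt_mc = "WT-MC", mt_mc = "MT-MC", wt_sc = "WT-SC", mt_sc = "MT-SC")
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!is.null(tb)) {
      if (!inherits(tb, "count_table")) stop(nm, " is not a count_table")
      if (!identical(attr(tb, "source_tag"), unname(tags[nm])))
        stop(nm, " has source_tag ", attr(tb, "source_tag"),
             " but should be ", tags[nm])
    }
  }
  tables <- align_categories(tables)
  if (!is.null(meta)) {
    if (!inherits(meta, "sample_meta")) stop("meta must be a sample_meta")
    if (!is.null(tables$mt_mc)) {
      miss <- setdiff(colnames(tables$mt_mc), meta$sample)
      if (length(miss))
        stop("metadata missing for MT-MC samples: ", paste(miss, collapse = ", "))
    }
  }
  structure(list(tables = tables, meta = meta), class = "tcr_dataset")
}

#' @export
print.tcr_dataset <- function(x, ...) {
  k <- length(dataset_categories(x))
  cat(sprintf("tcr_dataset: %d categories\n", k))
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    if (is.null(tb)) {
      cat(sprintf("  %-6s <absent>\n", nm))
    } else {
      cat(sprintf("  %-6s %d samples, totals: %s\n", nm, ncol(tb),
                  paste(colSums(tb), collapse = " ")))
    }
  }
  cat(if (is.null(x$meta)) "  meta:  <absent>\n" else
    sprintf("  meta:  s*f = %s\n", paste(x$meta$s * x$meta$f, collapse = " ")))
  invisible(x)
}

dataset_categories <- function(dataset) {
  for (tb in dataset$tables) if (!is.null(tb)) return(rownames(tb))
  character()
}

#' Pool wild-type counts across samples and protocols
#'
#' Combining multinomial counts governed by a common probability vector keeps
#' the multinomial form, so WT counts are summed over samples and over the MC
#' and SC protocols into a single category count vector.
#'
#' @param dataset a [tcr_dataset()].
#' @return a named integer vector `X` over the shared category list; its sum is
#'   the pooled WT total `m`.
#' @export
pool_wildtype <- function(dataset) {
  stopifnot(inherits(dataset, "tcr_dataset"))
  tabs <- dataset$tables[c("wt_mc", "wt_sc")]
  tabs <- tabs[!vapply(tabs, is.null, logical(1L))]
  if (!length(tabs)) stop("no wild-type tables present")
  cats <- dataset_categories(dataset)
  x <- setNames(integer(length(cats)), cats)
  for (tb in tabs) {
    if (!identical(rownames(tb), cats)) stop("mismatched category lists")
    x <- x + rowSums(tb)
  }
  x
}

#' Pool mutant counts across samples and protocols
#'
#' @param dataset a [tcr_dataset()].
#' @param protocols which MT tables to pool.
#' @return a named integer vector over the shared category list.
#' @export
pool_mutant <- function(dataset, protocols = c("mc", "sc")) {
  stopifnot(inherits(dataset, "tcr_dataset"))
  protocols <- match.arg(protocols, c("mc", "sc"), several.ok = TRUE)
  tabs <- dataset$tables[paste0("mt_", protocols)]
  tabs <- tabs[!vapply(tabs, is.null, logical(1L))]
  if (!length(tabs)) stop("no mutant tables present")
  cats <- dataset_categories(dataset)
  y <- setNames(integer(length(cats)), cats)
  for (tb in tabs) y <- y + rowSums(tb)
  y
}

#' The bundled six-patient J-region dataset
#'
#' Counts of the 13 J-region CDR3 types for six melanoma patients (blood), from
#' both the mass-culture and single-cell-derived-isolates protocols, for
#' wild-type and HPRT-mutant cells. The per-sample bottleneck metadata (cells
#' treated `s` and mutant frequency `f`) was not published with the count
#' tables; it must be supplied by the user, or an explicit documented default
#' (`s = 1e6`, `f = 1e-5`, consistent with the reported mutant-frequency range
#' of 1e-6 to 1e-5 per mononuclear cell) can be requested.
#'
#' @param meta a [sample_meta()] data frame, a path to a metadata TSV, or
#'   `NULL`.
#' @param default_meta if `TRUE` and `meta` is `NULL`, attach the documented
#'   default metadata (with a message). Never applied silently.
#' @return a [tcr_dataset()].
#' @examples
#' d <- jregion_dataset()
#' colSums(d$tables$mt_mc)  # per-patient MT-MC sequencing totals
#' @export
jregion_dataset <- function(meta = NULL, default_meta = FALSE) {
  path <- function(nm) system.file("extdata", nm, package = "cpmult",
                                   mustWork = TRUE)
  if (is.character(meta)) meta <- read_sample_meta(meta)
  if (is.null(meta) && isTRUE(default_meta)) {
    message("using default bottleneck metadata: s = 1e6, f = 1e-5 per sample")
    meta <- sample_meta(LETTERS[1:6], s = 1e6, f = 1e-5)
  }
  tcr_dataset(
    wt_mc = read_count_table(path("jregion_wt_mc.tsv"), "WT-MC"),
    mt_mc = read_count_table(path("jregion_mt_mc.tsv"), "MT-MC"),
    wt_sc = read_count_table(path("jregion_wt_sc.tsv"), "WT-SC"),
    mt_sc = read_count_table(path("jregion_mt_sc.tsv"), "MT-SC"),
    meta = meta
  )
}
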