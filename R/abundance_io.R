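#' Construct a genus-level abundance table
#'
#' An abundance table is a taxa-by-samples matrix of non-negative finite
#' values with a declared unit. Percent tables must have columns summing to
#' 100 (relative tolerance 1e-6), fraction tables to 1 (tolerance 1e-9);
#' count tables are unconstrained. Taxa and sample identifiers must be
#' unique (case-sensitive). Taxa labelled \code{unclassified_*} are ordinary
#' taxa and receive no special handling.
#'
#' @param values numeric matrix, taxa in rows, samples in columns, with
#'   dimnames giving taxon and sample identifiers.
#' @param unit one of \code{"counts"}, \code{"fraction"}, \code{"percent"}.
#' @return an object of class \code{abund_table}.
#' @export
abundance_table <- function(values, unit = c("percent", "fraction", "counts")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("'values' must be a numeric matrix (taxa x samples)")
  }
  taxa <- rownames(values)
  samples <- colnames(values)
  if (is.null(taxa) || is.null(samples)) {
    stop_validation("'values' must carry taxon rownames and sample colnames")
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation(sprintf(
      "negative or non-finite abundance at taxon '%s', sample '%s'",
      taxa[bad[1, 1]], samples[bad[1, 2]]
    ))
  }
  dup_t <- taxa[duplicated(taxa)]
  if (length(dup_t) > 0) {
    stop_validation(sprintf("duplicate taxon identifier: '%s'", dup_t[1]))
  }
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0) {
    stop_validation(sprintf("duplicate sample identifier: '%s'", dup_s[1]))
  }
  check_closure(values, unit)
  structure(list(values = values, unit = unit), class = "abund_table")
}

check_closure <- function(values, unit) {
  sums <- colSums(values)
  if (unit == "percent") {
    off <- which(abs(sums - 100) > 100 * 1e-6)
    if (length(off) > 0) {
      stop_validation(sprintf(
        "percent table: sample '%s' sums to %.8g, not 100",
        colnames(values)[off[1]], sums[off[1]]
      ))
    }
  } else if (unit == "fraction") {
    off <- which(abs(sums - 1) > 1e-9)
    if (length(off) > 0) {
      stop_validation(sprintf(
        "fraction table: sample '%s' sums to %.10g, not 1",
        colnames(values)[off[1]], sums[off[1]]
      ))
    }
  }
  invisible(TRUE)
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf(
    "Abundance table: %d taxa x %d samples (unit: %s)\n",
    nrow(x$values), ncol(x$values), x$unit
  ))
  invisible(x)
}

#' @rdname abundance_table
#' @param x an \code{abund_table}.
#' @export
taxa <- function(x) rownames(x$values)

#' @rdname abundance_table
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a genus abundance table from TSV
#'
#' The canonical dialect is tab-delimited UTF-8 with a "." decimal
#' separator: first header cell \code{taxon}, remaining header cells sample
#' identifiers, first column taxon names. Duplicate taxon rows are an error,
#' never silently merged.
#'
#' @param path path to the TSV file.
#' @param unit declared unit of the stored values.
#' @return an \code{\link{abundance_table}}.
#' @export
read_abundance_table <- function(path, unit = c("percent", "fraction", "counts")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    stop_validation(sprintf("abundance table file not found: '%s'", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop_validation(sprintf("'%s': need a header plus at least one taxon row", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_exp <- length(cells[[1]])
  widths <- lengths(cells)
  if (any(widths != ncol_exp)) {
    bad <- which(widths != ncol_exp)[1]
    stop_validation(sprintf(
      "'%s': ragged row %d (has %d fields, header has %d)",
      path, bad, widths[bad], ncol_exp
    ))
  }
  header <- cells[[1]]
  samples <- header[-1]
  body <- cells[-1]
  taxa <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(taxa, samples))
  for (i in seq_along(body)) {
    row <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1]
      stop_validation(sprintf(
        "'%s': non-numeric cell at taxon '%s', sample '%s'",
        path, taxa[i], samples[j]
      ))
    }
    vals[i, ] <- row
  }
  abundance_table(vals, unit = unit)
}

#' Write an abundance table as canonical TSV
#'
#' Values are written with \code{format(..., digits = 17)} so that a
#' read-write-read round trip is bit-identical.
#'
#' @param x an \code{abund_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abund_table"))
  header <- paste(c("taxon", colnames(x$values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(rownames(x$values)[i],
            format(x$values[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Total-sum scale a table to percent
#'
#' Divides each sample column by its total and multiplies by 100, the
#' standard relative-abundance convention. Percent input is returned
#' unchanged up to re-closure (the operation is idempotent).
#'
#' @param table an \code{abund_table} (counts, fraction, or percent).
#' @return an \code{abund_table} with \code{unit = "percent"}.
#' @export
total_sum_scale <- function(table) {
  stopifnot(inherits(table, "abund_table"))
  sums <- colSums(table$values)
  zero <- which(sums == 0)
  if (length(zero) > 0) {
    stop_degenerate(sprintf(
      "sample '%s' has zero total abundance and cannot be scaled",
      colnames(table$values)[zero[1]]
    ))
  }
  vals <- sweep(table$values, 2, sums, "/") * 100
  abundance_table(vals, unit = "percent")
}

#' Read a sample design table
#'
#' Expects a delimited text table with columns \code{sample}, \code{site},
#' \code{host_role}, \code{group}, \code{replicate}. \code{host_role} must
#' be \code{target} (the focal host plant) or \code{companion} (an adjacent
#' plant sharing the plot, used as the host-specificity background).
#'
#' @param path path to the design TSV.
#' @return a \code{study_design} data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("design file not found: '%s'", path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  study_design(df)
}

#' Construct and validate a study design
#'
#' @param df data frame with columns \code{sample}, \code{site},
#'   \code{host_role}, \code{group}, \code{replicate}.
#' @return the validated design, classed \code{study_design}.
#' @export
study_design <- function(df) {
  needed <- c("sample", "site", "host_role", "group", "replicate")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("design is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) stop_validation("design table is empty")
  df <- df[needed]
  df$sample <- as.character(df$sample)
  df$site <- as.character(df$site)
  df$host_role <- as.character(df$host_role)
  df$group <- as.character(df$group)
  df$replicate <- as.integer(df$replicate)
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup) > 0) {
    stop_validation(sprintf("duplicate sample id in design: '%s'", dup[1]))
  }
  bad_role <- setdiff(unique(df$host_role), c("target", "companion"))
  if (length(bad_role) > 0) {
    stop_validation(sprintf(
      "unknown host_role '%s' (must be 'target' or 'companion')", bad_role[1]
    ))
  }
  if (anyNA(df$replicate) || any(df$replicate < 1)) {
    stop_validation("replicate indices must be positive integers")
  }
  class(df) <- c("study_design", "data.frame")
  df
}

# Samples belonging to one group, in design order; errors on unknown/empty.
group_samples <- function(design, group) {
  if (!group %in% design$group) {
    stop_validation(sprintf("unknown group '%s' in design", group))
  }
  s <- design$sample[design$group == group]
  if (length(s) == 0) stop_validation(sprintf("group '%s' has no samples", group))
  s
}

# Align an abundance table against a design: every design sample must be a
# table column. Warns below 3 replicates, errors below 2 when testing.
check_table_design <- function(table, design, groups = unique(design$group),
                               min_n = 2L) {
  miss <- setdiff(design$sample[design$group %in% groups], colnames(table$values))
  if (length(miss) > 0) {
    stop_validation(sprintf("design sample '%s' is absent from the table", miss[1]))
  }
  for (g in groups) {
    n <- sum(design$group == g)
    if (n < min_n) {
      stop_validation(sprintf("group '%s' has %d sample(s); need >= %d", g, n, min_n))
    }
    if (n < 3) {
      warn_irmdma(sprintf("group '%s' has only %d samples; tests will have little power", g, n),
                  class = "irmdma_small_group_warning")
    }
  }
  invisible(TRUE)
}

# Percent-scale view of a table regardless of the stored unit.
as_percent <- function(table) {
  if (table$unit == "percent") table else total_sum_scale(table)
}
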