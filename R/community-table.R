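#' Sample-by-taxon community table
#'
#' The central container of the package: a numeric matrix with samples in
#' rows and taxa in columns, tagged with the microbial kingdom, the
#' taxonomic level of the columns, and whether the values are counts or
#' row-normalized proportions.
#'
#' @param values numeric matrix, samples in rows, taxa in columns; both
#'   dimensions must carry unique names. Counts must be non-negative
#'   integers; proportions must make every row sum to 1.
#' @param kingdom one of `"bacteria"`, `"fungi"`, `"oomycetes"`.
#' @param level one of `"ASV"`, `"OTU"`, `"phylum"`, `"custom"`.
#' @param is_relative logical; `TRUE` when rows are proportions.
#' @return an object of class `community_table`: the matrix plus
#'   `kingdom`, `level` and `is_relative` attributes.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' ct <- community_table(m, kingdom = "bacteria", level = "ASV")
#' @export
community_table <- function(values,
                            kingdom = c("bacteria", "fungi", "oomycetes"),
                            level = c("ASV", "OTU", "phylum", "custom"),
                            is_relative = FALSE) {
  kingdom <- match.arg(kingdom)
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample (row) and taxon (column) names")
  x <- structure(values,
                 kingdom = kingdom, level = level,
                 is_relative = isTRUE(is_relative),
                 class = c("community_table", "matrix", "array"))
  validate_community_table(x)
}

#' @rdname community_table
#' @param x a `community_table`.
#' @export
validate_community_table <- function(x) {
  v <- unclass(x)
  if (anyNA(v)) stop("community table contains NA values")
  neg <- which(v < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at sample '%s', taxon '%s'",
                 rownames(v)[neg[1, 1]], colnames(v)[neg[1, 2]]))
  if (anyDuplicated(rownames(v)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (isTRUE(attr(x, "is_relative"))) {
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative table has rows not summing to 1: ",
           paste(rownames(v)[abs(rs - 1) > 1e-9][1], collapse = ", "))
  } else {
    if (any(abs(v - round(v)) > 1e-8))
      stop("count table contains non-integer values")
  }
  x
}

#' @rdname community_table
#' @export
is_relative <- function(x) isTRUE(attr(x, "is_relative"))

#' @rdname community_table
#' @export
table_kingdom <- function(x) attr(x, "kingdom")

#' @rdname community_table
#' @export
table_level <- function(x) attr(x, "level")

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d samples x %d taxa [%s, level %s, %s]\n",
              nrow(x), ncol(x), attr(x, "kingdom"), attr(x, "level"),
              if (is_relative(x)) "relative" else "counts"))
  invisible(x)
}

# rebuild a community_table after a matrix operation, carrying tags over
retag <- function(values, template, level = NULL, is_relative = NULL) {
  community_table(values,
                  kingdom = attr(template, "kingdom"),
                  level = if (is.null(level)) attr(template, "level") else level,
                  is_relative = if (is.null(is_relative))
                    attr(template, "is_relative") else is_relative)
}

#' Read a delimited community count table
#'
#' Reads a tab-separated sample-by-taxon count table. Both orientations are
#' accepted; taxa-in-rows is the common amplicon-pipeline dialect, where the
#' header line may start with a `#` (e.g. `#OTU ID`). The returned table is
#' always samples-in-rows.
#'
#' @param path file path.
#' @param orientation `"taxa_in_rows"` (default, classic OTU-table dialect)
#'   or `"samples_in_rows"`.
#' @inheritParams community_table
#' @return a `community_table` of counts.
#' @export
read_community_table <- function(path,
                                 orientation = c("taxa_in_rows",
                                                 "samples_in_rows"),
                                 kingdom = "bacteria", level = "ASV") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("table file has no data rows: ", path)
  # classic BIOM-era TSV dialect: header may be prefixed with '#'
  lines[1] <- sub("^#\\s*", "", lines[1])
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in table body: ", path)
  if (orientation == "taxa_in_rows") m <- t(m)
  storage.mode(m) <- "double"
  community_table(m, kingdom = kingdom, level = level, is_relative = FALSE)
}

#' Write a community table as tab-separated text
#'
#' Writes taxa-in-rows with a `#OTU ID` header, the dialect
#' [read_community_table()] reads back. Proportions are written with six
#' decimals; counts as integers.
#'
#' @param x a `community_table`.
#' @param path output path.
#' @export
write_community_table <- function(x, path) {
  m <- t(unclass(x))
  body <- if (is_relative(x)) formatC(m, format = "f", digits = 6)
          else formatC(m, format = "d")
  lines <- c(paste(c("#OTU ID", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], body[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a BIOM-format (JSON) community table
#'
#' Reader-only support for the dense/sparse JSON BIOM variant, via the
#' biomformat package.
#'
#' @inheritParams read_community_table
#' @return a `community_table` of counts (samples in rows).
#' @export
read_biom_community <- function(path, kingdom = "bacteria", level = "ASV") {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
  storage.mode(m) <- "double"
  community_table(t(m), kingdom = kingdom, level = level,
                  is_relative = FALSE)
}

#' Read sample metadata
#'
#' Tab-separated, with mandatory columns `sample_id`, `field`, `management`,
#' `plot`, `genotype`, `compartment`, `stage`.
#'
#' @param path file path.
#' @return a data.frame of per-sample factors (character columns).
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param metadata a metadata data.frame.
#' @export
validate_sample_metadata <- function(metadata) {
  need <- c("sample_id", "field", "management", "plot", "genotype",
            "compartment", "stage")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0)
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- metadata$compartment == "soil" & metadata$stage == "unplanted" &
    metadata$genotype != "none"
  if (any(bad))
    stop("unplanted soil samples must have genotype 'none': ",
         metadata$sample_id[bad][1])
  metadata
}

# metadata rows aligned to a table's samples, erroring on any mismatch
match_metadata <- function(x, metadata) {
  idx <- match(rownames(x), metadata$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(utils::head(rownames(x)[is.na(idx)], 5), collapse = ", "))
  metadata[idx, , drop = FALSE]
}

#' Read a taxonomy table
#'
#' Accepts two tab-separated dialects: a `taxonomy` column with
#' semicolon-joined ranks (kingdom;phylum;class;order;family;genus), or one
#' column per rank. Missing ranks become the `"unassigned"` sentinel.
#'
#' @param path file path.
#' @return a data.frame with columns `taxon_id`, `kingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (!"taxon_id" %in% names(df))
    names(df)[1] <- "taxon_id"
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if ("taxonomy" %in% names(df)) {
    parts <- strsplit(df$taxonomy, ";", fixed = TRUE)
    rk <- t(vapply(parts, function(p) {
      p <- trimws(p)
      c(p, rep("", 6))[1:6]
    }, character(6)))
    colnames(rk) <- ranks
    df <- cbind(df["taxon_id"], as.data.frame(rk))
  }
  for (r in ranks) {
    if (!r %in% names(df)) df[[r]] <- "unassigned"
    empty <- is.na(df[[r]]) | !nzchar(trimws(df[[r]]))
    df[[r]][empty] <- "unassigned"
  }
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in taxonomy")
  df[c("taxon_id", ranks)]
}
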