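#' Experimental group labels
#'
#' The three groups of the LPS lung-inflammation design: saline-instilled
#' controls (\code{SHAM}), LPS-instilled mice with circulating neutrophils
#' (\code{LPS_PMN}) and LPS-instilled, NIMP-R14 neutrophil-depleted mice
#' (\code{LPS_NOPMN}).
#'
#' @return Character vector of the three allowed group labels.
#' @export
lung_groups <- function() c("SHAM", "LPS_PMN", "LPS_NOPMN")

# Required spot-table columns, in canonical order.
SPOT_COLUMNS <- c("array_id", "spot_id", "probe_id", "gene_symbol",
                  "spot_kind", "sample_signal", "reference_signal")

SPOT_KINDS <- c("regular", "positive_control", "negative_control")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and classify a spot table
#'
#' @param x data.frame with the canonical spot-table columns.
#' @param floor_value positive value substituted for non-positive signals
#'   (local-background subtraction upstream can push raw signals below zero;
#'   flooring keeps the subsequent natural-log step total).
#' @return The validated table with class \code{spot_table}; floored signals
#'   are counted and reported via \code{message()}.
#' @export
as_spot_table <- function(x, floor_value = 1.0) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(SPOT_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("spot table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, SPOT_COLUMNS]
  for (col in c("array_id", "spot_id", "probe_id", "gene_symbol", "spot_kind")) {
    x[[col]] <- as.character(x[[col]])
  }
  x$gene_symbol[is.na(x$gene_symbol)] <- ""
  bad_kind <- setdiff(unique(x$spot_kind), SPOT_KINDS)
  if (length(bad_kind) > 0L) {
    stop("unknown spot_kind value(s): ", paste(bad_kind, collapse = ", "),
         "; allowed: ", paste(SPOT_KINDS, collapse = ", "), call. = FALSE)
  }
  for (col in c("sample_signal", "reference_signal")) {
    x[[col]] <- as.numeric(x[[col]])
    if (anyNA(x[[col]])) stop("non-numeric or missing values in ", col, call. = FALSE)
    n_floor <- sum(x[[col]] <= 0)
    if (n_floor > 0L) {
      message("floored ", n_floor, " non-positive value(s) in ", col,
              " to ", floor_value, " AU")
      x[[col]][x[[col]] <= 0] <- floor_value
    }
  }
  key <- paste(x$array_id, x$spot_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (array_id, spot_id) pairs, e.g. ",
         sub("\r", " / ", key[duplicated(key)][1L]), call. = FALSE)
  }
  spot_sets <- lapply(split(x$spot_id, x$array_id), sort)
  if (length(unique(spot_sets)) > 1L) {
    stop("arrays do not share an identical spot set; ",
         "every array must carry the same spot_ids", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("spot_table", "data.frame")
  x
}

#' Read per-array two-channel spot intensity tables
#'
#' Accepts either one long tab-delimited file with an \code{array_id} column
#' or several per-array files; all are merged into one validated long table.
#' Control spots are retained but flagged through \code{spot_kind}.
#'
#' @param paths character vector of TSV paths with columns
#'   \code{array_id, spot_id, probe_id, gene_symbol, spot_kind,
#'   sample_signal, reference_signal}.
#' @param floor_value see [as_spot_table()].
#' @return A \code{spot_table}.
#' @export
read_spot_tables <- function(paths, floor_value = 1.0) {
  stopifnot(length(paths) >= 1L)
  parts <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("spot table file not found: ", p, call. = FALSE)
    utils::read.delim(p, colClasses = "character", check.names = FALSE,
                      na.strings = NULL)
  })
  as_spot_table(do.call(rbind, parts), floor_value = floor_value)
}

#' Write a spot table
#' @param x spot_table
#' @param path output TSV path
#' @return \code{path}, invisibly.
#' @export
write_spot_tables <- function(x, path) {
  stopifnot(inherits(x, "spot_table"))
  write_tsv_(as.data.frame(x), path)
}

# deterministic TSV writer shared by all outputs
write_tsv_ <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write file '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a study design table
#'
#' @param path TSV with columns \code{sample_id} and \code{group}; groups
#'   must be the labels of [lung_groups()] and all three must be present.
#' @return data.frame of class \code{study_design}.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  as_study_design(df)
}

#' @rdname read_design
#' @param x data.frame with sample_id and group columns.
#' @export
as_study_design <- function(x) {
  missing_cols <- setdiff(c("sample_id", "group"), names(x))
  if (length(missing_cols) > 0L) {
    stop("design is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- data.frame(sample_id = as.character(x$sample_id),
                  group = as.character(x$group), stringsAsFactors = FALSE)
  bad <- setdiff(unique(x$group), lung_groups())
  if (length(bad) > 0L) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(lung_groups(), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id in design", call. = FALSE)
  absent <- setdiff(lung_groups(), unique(x$group))
  if (length(absent) > 0L) {
    stop("design has empty group(s): ", paste(absent, collapse = ", "),
         "; all of ", paste(lung_groups(), collapse = ", "),
         " must be non-empty", call. = FALSE)
  }
  class(x) <- c("study_design", "data.frame")
  x
}

#' @rdname read_design
#' @export
write_design <- function(x, path) {
  stopifnot(inherits(x, "study_design"))
  write_tsv_(as.data.frame(x), path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line,
#' \code{name TAB description TAB member TAB member ...}. Duplicate members
#' within a set are removed (first occurrence kept).
#'
#' @param path GMT file path.
#' @return Named list of class \code{gene_set_collection}; each element is
#'   \code{list(name, description, members)}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(stats::setNames(list(), character()),
                     class = "gene_set_collection"))
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT format error at line ", i,
           ": need at least 3 tab-separated fields (name, description, members)",
           call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("GMT format error at line ", i, ": set '", fields[[1L]],
           "' has no members", call. = FALSE)
    }
    nms[[i]] <- fields[[1L]]
    sets[[i]] <- list(name = fields[[1L]], description = fields[[2L]],
                      members = members)
  }
  if (anyDuplicated(nms)) {
    stop("duplicated set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(sets, nms), class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param x gene_set_collection
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(x, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-animal phenotype table
#'
#' Columns: \code{sample_id}, \code{mpo_balf_activity} (mU/ml, >= 0),
#' \code{mpo_below_detection} (TRUE/FALSE), \code{mpo_lung_protein}
#' (ng MPO/mg protein, >= 0) and \code{m1dg} (adducts per 1e8 nucleotides,
#' finite and > 0).
#'
#' @param path TSV path.
#' @param design optional \code{study_design}; if given, phenotype
#'   sample_ids must be a subset of the design's.
#' @return data.frame of class \code{phenotype_table}.
#' @export
read_phenotypes <- function(path, design = NULL) {
  df <- utils::read.delim(path)
  as_phenotype_table(df, design = design)
}

#' @rdname read_phenotypes
#' @param x data.frame of phenotype records.
#' @export
as_phenotype_table <- function(x, design = NULL) {
  need <- c("sample_id", "mpo_balf_activity", "mpo_below_detection",
            "mpo_lung_protein", "m1dg")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, need]
  x$sample_id <- as.character(x$sample_id)
  x$mpo_below_detection <- as.logical(x$mpo_below_detection)
  for (col in c("mpo_balf_activity", "mpo_lung_protein", "m1dg")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  if (any(!is.finite(x$m1dg)) || any(x$m1dg <= 0)) {
    stop("m1dg must be finite and strictly positive", call. = FALSE)
  }
  if (any(x$mpo_balf_activity < 0) || any(x$mpo_lung_protein < 0)) {
    stop("MPO values must be non-negative", call. = FALSE)
  }
  if (!is.null(design)) {
    extra <- setdiff(x$sample_id, design$sample_id)
    if (length(extra) > 0L) {
      stop("phenotype sample_id(s) absent from design: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  rownames(x) <- NULL
  class(x) <- c("phenotype_table", "data.frame")
  x
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(x, path) {
  stopifnot(inherits(x, "phenotype_table"))
  write_tsv_(as.data.frame(x), path)
}

#' Read / write a probe-to-gene annotation table
#'
#' @param path TSV with columns \code{probe_id}, \code{gene_symbol}
#'   (empty symbol = unannotated probe; symbols are case-sensitive).
#' @return data.frame with probe_id and gene_symbol.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(c("probe_id", "gene_symbol"), names(df))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) stop("duplicated probe_id in annotation", call. = FALSE)
  df[, c("probe_id", "gene_symbol")]
}

#' @rdname read_annotation
#' @param x annotation data.frame.
#' @export
write_annotation <- function(x, path) write_tsv_(x, path)

#' Write / read a genes-by-samples expression matrix
#'
#' TSV with gene symbols in the first column (\code{gene_symbol}) and one
#' column per sample. Full double precision is preserved so a write/read
#' round trip reproduces the matrix to better than 1e-9.
#'
#' @param matrix numeric matrix, unique non-empty rownames (gene symbols),
#'   colnames = sample ids.
#' @param path TSV path.
#' @return \code{path} invisibly (writer); numeric matrix (reader).
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || any(!nzchar(rownames(matrix)))) {
    stop("matrix must have non-empty gene-symbol rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) {
    stop("duplicate gene symbols in matrix; collapse spots to genes first",
         call. = FALSE)
  }
  if (is.null(colnames(matrix))) stop("matrix must have sample_id colnames", call. = FALSE)
  df <- data.frame(gene_symbol = rownames(matrix),
                   matrix, check.names = FALSE, stringsAsFactors = FALSE)
  # format() at 17 significant digits keeps the round trip exact to double
  # precision; write.table's default 15 digits would only reach ~1e-15 rel.
  for (j in seq_len(ncol(matrix)) + 1L) {
    df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write_tsv_(df, path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1L] != "gene_symbol") {
    stop("expression matrix TSV must start with a gene_symbol column", call. = FALSE)
  }
  genes <- df[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene symbols in matrix file", call. = FALSE)
  m <- vapply(df[-1L], as.numeric, numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(genes, names(df)[-1L]))
  if (anyNA(m)) stop("non-numeric values in matrix file", call. = FALSE)
  m
}
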