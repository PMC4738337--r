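#' Construct an expression matrix
#'
#' Container for log2-scale expression values of one species, genes in rows
#' and samples in columns. Gene and sample identifiers must be unique and the
#' body must be complete (no missing entries).
#'
#' @param values Numeric matrix, genes x samples, with `rownames` (gene
#'   identifiers) and `colnames` (sample identifiers).
#' @param species Single label, e.g. `"mouse"` or `"human"`.
#' @return An object of class `expr_matrix`: the validated matrix with a
#'   `species` attribute. Use [gene_ids()], [sample_ids()] and
#'   [expr_species()] to query it; the object behaves as a plain matrix.
#' @export
expression_matrix <- function(values, species) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  }
  dup <- gid[duplicated(gid)]
  if (length(dup) > 0L) {
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- sid[duplicated(sid)]
  if (length(dup) > 0L) {
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene row %d, sample column %d",
                 idx[["row"]], idx[["col"]]), call. = FALSE)
  }
  if (!is.character(species) || length(species) != 1L || is.na(species)) {
    stop("`species` must be a single label", call. = FALSE)
  }
  structure(values, species = species, class = c("expr_matrix", class(values)))
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname expression_matrix
#' @export
expr_species <- function(x) attr(x, "species")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (species: %s)\n",
              nrow(x), ncol(x), expr_species(x)))
  invisible(x)
}

#' Load a tab-delimited expression matrix
#'
#' Expects a UTF-8 TSV whose first column holds gene identifiers and whose
#' header row holds sample identifiers; the body must be numeric. Row and
#' column order are preserved. Duplicate gene identifiers, non-numeric cells
#' and (by default) missing values are load errors.
#'
#' @param path Path to the TSV file.
#' @param species Species label attached to the result.
#' @param na_action `"error"` (default) rejects any missing/non-numeric cell;
#'   `"drop"` removes genes containing one, with a message. Values are never
#'   imputed.
#' @return An [expression_matrix()].
#' @export
load_expression_matrix <- function(path, species, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty expression matrix in ", path, call. = FALSE)
  }
  gid <- raw[[1L]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup) > 0L) {
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- is.na(num)
  if (any(bad)) {
    if (na_action == "error") {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "non-numeric or missing value at gene row %d ('%s'), sample column %d ('%s') in %s",
        idx[["row"]], gid[idx[["row"]]], idx[["col"]],
        colnames(body)[idx[["col"]]], path), call. = FALSE)
    }
    drop_rows <- unique(which(bad, arr.ind = TRUE)[, "row"])
    message("dropping ", length(drop_rows), " gene(s) with missing values")
    keep <- setdiff(seq_len(nrow(num)), drop_rows)
    num <- num[keep, , drop = FALSE]
    gid <- gid[keep]
  }
  rownames(num) <- gid
  colnames(num) <- colnames(body)
  expression_matrix(num, species)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression_matrix()]: header `gene_id\t<sample ids...>`,
#' one gene per row. Round trips are value-identical.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a sample annotation table
#'
#' TSV with columns `sample_id`, `species`, `group`, `role`; `role` must be
#' `tumour` or `reference`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four columns.
#' @export
load_sample_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  needed <- c("sample_id", "species", "group", "role")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(ann$role), c("tumour", "reference"))
  if (length(bad) > 0L) {
    stop("unknown role value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ann[, needed]
}

#' Check an annotation against an expression matrix
#'
#' Verifies that every annotated sample of the matrix's species exists in the
#' matrix exactly once and matches its species label.
#'
#' @param x An `expr_matrix`.
#' @param annotation Annotation data.frame (see [load_sample_annotation()]).
#' @return The subset of `annotation` rows for `x`'s samples, in column order.
#' @export
check_annotation <- function(x, annotation) {
  sp <- expr_species(x)
  ann <- annotation[annotation$species == sp, , drop = FALSE]
  missing_samp <- setdiff(ann$sample_id, sample_ids(x))
  if (length(missing_samp) > 0L) {
    stop("annotated sample(s) absent from the ", sp, " matrix: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  }
  ann[match(intersect(sample_ids(x), ann$sample_id), ann$sample_id), ,
      drop = FALSE]
}

#' Construct an ortholog map
#'
#' Pairs of gene identifiers linking species A to species B. Exact duplicate
#' pairs are collapsed; multi-mapped relations are retained until
#' [to_1to1()] is applied.
#'
#' @param gene_a,gene_b Character vectors of equal length.
#' @param provenance Free-text note on the map's origin.
#' @return An object of class `ortholog_map`: a data.frame with columns
#'   `gene_a`, `gene_b` and attributes `provenance` and `n_1to1` (size of the
#'   1:1-reducible core under the drop-all policy).
#' @export
ortholog_map <- function(gene_a, gene_b, provenance = "unspecified") {
  if (length(gene_a) != length(gene_b)) {
    stop("`gene_a` and `gene_b` must have equal length", call. = FALSE)
  }
  df <- data.frame(gene_a = as.character(gene_a), gene_b = as.character(gene_b),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  core <- df$gene_a %in% df$gene_a[!(duplicated(df$gene_a) | duplicated(df$gene_a, fromLast = TRUE))] &
    df$gene_b %in% df$gene_b[!(duplicated(df$gene_b) | duplicated(df$gene_b, fromLast = TRUE))]
  structure(df, provenance = provenance, n_1to1 = sum(core),
            class = c("ortholog_map", "data.frame"))
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map: %d pair(s), %d in 1:1 core (provenance: %s)\n",
              nrow(x), attr(x, "n_1to1"), attr(x, "provenance")))
  invisible(x)
}

#' Load a two-column ortholog map
#'
#' One tab-separated pair per line, no header by default. A line without
#' exactly two fields is an error naming the line number. Exact duplicate
#' pairs are collapsed with a message; an empty file yields an empty map with
#' a warning.
#'
#' @param path Path to the TSV file.
#' @param provenance Free-text origin note stored on the map.
#' @return An [ortholog_map()].
#' @export
load_ortholog_map <- function(path, provenance = path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty ortholog map: ", path, call. = FALSE)
    return(ortholog_map(character(0), character(0), provenance))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop("line ", which(nf != 2L)[1L], " of ", path,
         " does not have exactly two fields", call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  n_raw <- length(a)
  map <- ortholog_map(a, b, provenance)
  if (nrow(map) < n_raw) {
    message("collapsed ", n_raw - nrow(map), " duplicate pair(s)")
  }
  map
}

#' Write an ortholog map as two-column TSV
#'
#' @param map An `ortholog_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reduce an ortholog map to a one-to-one core
#'
#' Cross-species expression comparison requires an unambiguous gene pairing.
#' The default `"drop"` policy removes every pair touching a gene identifier
#' that appears in more than one pair on either side — the conservative
#' standard. The `"first"` policy instead keeps, scanning pairs in their
#' listed order, each pair whose identifiers are both still unclaimed.
#' Both policies are deterministic and idempotent.
#'
#' @param map An `ortholog_map`.
#' @param policy `"drop"` (default) or `"first"`.
#' @return An `ortholog_map` satisfying the 1:1 invariant.
#' @export
to_1to1 <- function(map, policy = c("drop", "first")) {
  policy <- match.arg(policy)
  if (nrow(map) == 0L) {
    return(map)
  }
  if (policy == "drop") {
    multi_a <- duplicated(map$gene_a) | duplicated(map$gene_a, fromLast = TRUE)
    multi_b <- duplicated(map$gene_b) | duplicated(map$gene_b, fromLast = TRUE)
    keep <- !(multi_a | multi_b)
  } else {
    keep <- logical(nrow(map))
    seen_a <- seen_b <- character(0)
    for (i in seq_len(nrow(map))) {
      if (!(map$gene_a[i] %in% seen_a) && !(map$gene_b[i] %in% seen_b)) {
        keep[i] <- TRUE
        seen_a <- c(seen_a, map$gene_a[i])
        seen_b <- c(seen_b, map$gene_b[i])
      }
    }
  }
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  ortholog_map(out$gene_a, out$gene_b, attr(map, "provenance"))
}
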