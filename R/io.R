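#' Read a feature matrix from delimited text
#'
#' Expects a header row of feature ids and a first column of cell-line ids
#' (the corner cell is ignored). Every data cell must parse as a number.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, tab by default.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, delimiter = "\t") {
  tab <- read_labelled_table(path, delimiter)
  vals <- suppressWarnings(apply(tab$data, 2L, as.numeric))
  vals <- matrix(vals, nrow = nrow(tab$data))
  bad <- is.na(vals) & !is.na(tab$data)
  if (any(bad) || anyNA(tab$data)) {
    stop(sprintf("non-numeric or missing cells in feature matrix '%s'", path),
         call. = FALSE)
  }
  feature_matrix(vals, cell_line_ids = tab$row_ids, feature_ids = tab$col_ids)
}

#' Read a response matrix from delimited text
#'
#' Same layout as [read_feature_matrix()]; cells equal to `na_token` become
#' unobserved entries of the mask.
#'
#' @param path Path to the file.
#' @param na_token String marking a missing response, `"NA"` by default.
#' @param delimiter Field separator.
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path, na_token = "NA", delimiter = "\t") {
  tab <- read_labelled_table(path, delimiter)
  cells <- tab$data
  miss <- cells == na_token | is.na(cells)
  vals <- suppressWarnings(apply(cells, 2L, as.numeric))
  vals <- matrix(vals, nrow = nrow(cells))
  if (any(is.na(vals) & !miss)) {
    stop(sprintf("non-numeric response cells in '%s'", path), call. = FALSE)
  }
  vals[miss] <- NA_real_
  response_matrix(vals, mask = !miss,
                  cell_line_ids = tab$row_ids, drug_ids = tab$col_ids)
}

read_labelled_table <- function(path, delimiter) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop(sprintf("'%s' has a header but no data rows", path), call. = FALSE)
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  header <- parts[[1L]]
  body <- parts[-1L]
  width <- length(header)
  nf <- lengths(body)
  if (any(nf != width)) {
    stop(sprintf("ragged rows in '%s': header has %d fields, row %d has %d",
                 path, width, which(nf != width)[1L], nf[nf != width][1L]),
         call. = FALSE)
  }
  col_ids <- header[-1L]
  row_ids <- vapply(body, `[`, character(1L), 1L)
  data <- t(vapply(body, function(p) p[-1L], character(width - 1L)))
  if (width == 2L) data <- matrix(data, ncol = 1L)
  list(row_ids = row_ids, col_ids = col_ids, data = data)
}

#' Write a feature or response matrix as delimited text
#'
#' Values are printed at full precision (17 significant digits) so a
#' write/read round trip is bit-identical; unobserved response entries are
#' written as `na_token`.
#'
#' @param x A [feature_matrix()] or [response_matrix()].
#' @param path Output path.
#' @param delimiter Field separator.
#' @param na_token Token for unobserved responses.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, delimiter = "\t", na_token = "NA") {
  vals <- x$values
  col_ids <- colnames(vals)
  rows <- apply(vals, 1L, function(v) {
    s <- vapply(v, format_full, character(1L))
    s[is.na(v)] <- na_token
    s
  })
  rows <- if (is.matrix(rows)) t(rows) else matrix(rows, ncol = 1L)
  lines <- c(paste(c("id", col_ids), collapse = delimiter),
             paste(rownames(vals),
                   apply(rows, 1L, paste, collapse = delimiter),
                   sep = delimiter))
  writeLines(lines, path)
  invisible(path)
}

format_full <- function(v) {
  format(v, digits = 17L, scientific = FALSE, trim = TRUE)
}

#' Read drug mechanism-of-action annotations
#'
#' Two-column delimited text without header: drug id, mechanism class label.
#'
#' @param path Path to the file.
#' @param delimiter Field separator.
#' @return Named character vector mapping drug id to class label.
#' @export
read_drug_annotation <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2L) {
    stop("drug annotation file needs two columns: drug id, class",
         call. = FALSE)
  }
  if (anyDuplicated(tab[[1L]])) {
    stop("duplicated drug ids in annotation file", call. = FALSE)
  }
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated member ids.
#' Members are intersected with `background` when one is supplied; sets that
#' become empty are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @param background Optional character vector of feature ids defining the
#'   enrichment universe. Defaults to the union of all set members.
#' @return An object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1L]),
         call. = FALSE)
  }
  names(parts) <- vapply(parts, `[`, character(1L), 1L)
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  gene_set_collection(sets, background)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of feature ids.
#' @param background Character vector of feature ids; the universe against
#'   which enrichment is tested. Defaults to the union of the sets.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("gene sets must be named", call. = FALSE)
  }
  if (is.null(background)) background <- sort(unique(unlist(sets)))
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)),
                                             background))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping empty gene sets after background intersection: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no non-empty gene sets", call. = FALSE)
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Export a fitted multitask model as text files
#'
#' Writes the coefficient matrix (features x drugs) and intercepts as TSV
#' plus a small JSON sidecar with the regularization parameter, penalty
#' parameter, iteration count and convergence flag.
#'
#' @param model A `multitask_model` from [fit_trace_norm()].
#' @param dir Output directory, created if needed.
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_multitask_model <- function(model, dir, prefix = "trace_norm") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w_path <- file.path(dir, paste0(prefix, "_W.tsv"))
  b_path <- file.path(dir, paste0(prefix, "_b.tsv"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  W <- model$W
  write_matrix_tsv(list(values = W), w_path)
  writeLines(c("drug\tintercept",
               paste(colnames(W), vapply(model$b, format_full, character(1L)),
                     sep = "\t")), b_path)
  jsonlite::write_json(list(lambda = model$lambda, rho = model$rho,
                            n_iter = model$n_iter,
                            converged = model$converged,
                            standardized = model$standardized),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(W = w_path, b = b_path, meta = meta_path))
}
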