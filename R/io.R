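#' Write a collection to disk as Matrix Market + TSV sidecars
#'
#' Each study gets its own subdirectory holding `matrix.mtx` (coordinate
#' Matrix Market, 1-based), `genes.tsv`, `cells.tsv` and `labels.tsv`
#' (`cell_id`, `cell_type`, `cell_subtype`). If the collection carries a
#' planted-low-quality truth table it is written as `truth.tsv` at the root.
#'
#' @param collection A `cell_collection` or plain list of `swarm_study`
#'   objects.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @seealso [read_collection()]
#' @export
write_collection <- function(collection, directory) {
  studies <- if (inherits(collection, "cell_collection")) collection$studies else collection
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (st in studies) {
    d <- file.path(directory, st$study_id)
    dir.create(d, showWarnings = FALSE)
    mtx <- file.path(d, "matrix.mtx")
    Matrix::writeMM(st$counts, mtx)
    writeLines(st$gene_ids, file.path(d, "genes.tsv"))
    writeLines(st$cell_ids, file.path(d, "cells.tsv"))
    lab <- data.frame(
      cell_id = st$cell_ids,
      cell_type = st$labels_type,
      cell_subtype = st$labels_subtype %||% rep(NA_character_, length(st$cell_ids)),
      stringsAsFactors = FALSE
    )
    utils::write.table(lab, file.path(d, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, mtx, file.path(d, c("genes.tsv", "cells.tsv", "labels.tsv")))
  }
  if (inherits(collection, "cell_collection") && !is.null(collection$truth)) {
    tf <- file.path(directory, "truth.tsv")
    utils::write.table(collection$truth, tf, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, tf)
  }
  invisible(files)
}

#' Read a collection written by [write_collection()]
#'
#' Validates the Matrix Market header (declared non-zero entry count against
#' the actual number of data lines) and the sidecar lengths before parsing;
#' malformed inputs raise errors naming the offending file.
#'
#' @param directory Directory produced by [write_collection()].
#' @return A list of `swarm_study` objects (named by study id); if a
#'   `truth.tsv` is present it is attached as attribute `truth`.
#' @export
read_collection <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory, call. = FALSE)
  subdirs <- sort(list.dirs(directory, recursive = FALSE))
  subdirs <- subdirs[file.exists(file.path(subdirs, "matrix.mtx"))]
  if (length(subdirs) == 0) {
    stop("no study subdirectories with matrix.mtx under ", directory, call. = FALSE)
  }
  studies <- lapply(subdirs, read_study_dir)
  names(studies) <- vapply(studies, function(x) x$study_id, character(1))
  tf <- file.path(directory, "truth.tsv")
  if (file.exists(tf)) {
    attr(studies, "truth") <- utils::read.delim(tf, stringsAsFactors = FALSE)
  }
  studies
}

read_study_dir <- function(d) {
  mtx <- file.path(d, "matrix.mtx")
  check_mtx_header(mtx)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("failed to parse ", mtx, ": ",
                                         conditionMessage(e), call. = FALSE))
  m <- methods::as(m, "CsparseMatrix")
  genes <- readLines(file.path(d, "genes.tsv"))
  cells <- readLines(file.path(d, "cells.tsv"))
  if (length(genes) != ncol(m)) {
    stop(sprintf("%s/genes.tsv has %d entries but matrix.mtx declares %d columns",
                 d, length(genes), ncol(m)), call. = FALSE)
  }
  if (length(cells) != nrow(m)) {
    stop(sprintf("%s/cells.tsv has %d entries but matrix.mtx declares %d rows",
                 d, length(cells), nrow(m)), call. = FALSE)
  }
  lab <- utils::read.delim(file.path(d, "labels.tsv"), stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(lab) != length(cells) || !identical(lab$cell_id, cells)) {
    stop(sprintf("%s/labels.tsv does not align with cells.tsv", d), call. = FALSE)
  }
  sub <- lab$cell_subtype
  if (all(is.na(sub) | sub == "NA")) sub <- NULL
  new_swarm_study(
    study_id = basename(d),
    counts = m,
    gene_ids = genes,
    cell_ids = cells,
    labels_type = lab$cell_type,
    labels_subtype = sub
  )
}

# Light structural validation of a coordinate MatrixMarket file: the declared
# non-zero count in the size line must match the number of data lines.
check_mtx_header <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (length(body) == 0) stop("empty Matrix Market file: ", path, call. = FALSE)
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]]))
  if (length(hdr) != 3 || anyNA(hdr)) {
    stop("malformed Matrix Market size line in ", path, call. = FALSE)
  }
  nnz_declared <- hdr[3]
  nnz_actual <- length(body) - 1L
  if (nnz_actual != nnz_declared) {
    stop(sprintf("%s declares %d entries but contains %d",
                 path, nnz_declared, nnz_actual), call. = FALSE)
  }
  invisible(TRUE)
}

## Model serialization -------------------------------------------------------

#' Save / load a fitted classifier
#'
#' The archive is a single versioned RDS file holding layer shapes, weights,
#' the class vocabulary and the feature (gene) identifiers.
#'
#' @param model A `swarm_mlp` object.
#' @param path File path.
#' @return `write_swarm_mlp` returns `path` invisibly; `read_swarm_mlp`
#'   returns the restored model.
#' @export
write_swarm_mlp <- function(model, path) {
  stopifnot(inherits(model, "swarm_mlp"))
  saveRDS(list(format = "swarmcell_mlp", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_swarm_mlp
#' @export
read_swarm_mlp <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "swarmcell_mlp")) {
    stop(path, " is not a swarmcell model archive", call. = FALSE)
  }
  x$model
}
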