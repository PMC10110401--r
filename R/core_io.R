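#' Construct a count matrix with sample metadata
#'
#' The common substrate of the RNA-seq and RIP-seq stages: a genes x samples
#' integer matrix plus a sample sheet describing condition, assay and
#' replicate for every column.
#'
#' @param counts Integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns. All entries must be non-negative whole numbers;
#'   fractional "expected counts" are rejected because the downstream
#'   negative-binomial model assumes integer observations.
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (one of `"control"`, `"stimulus"`, `"stimulus_drug"`), `assay`
#'   (one of `"input"`, `"ip"`, `"igg"`) and `replicate` (positive integer),
#'   one row per column of `counts`, in column order.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  check_integer_counts(counts)
  storage.mode(counts) <- "integer"
  samples <- validate_sample_sheet(samples)
  if (nrow(samples) != ncol(counts))
    stop("sample sheet has ", nrow(samples), " rows but counts has ",
         ncol(counts), " columns")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("assays:", paste(sort(unique(x$samples$assay)), collapse = ", "),
      "| conditions:", paste(sort(unique(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

rc_conditions <- c("control", "stimulus", "stimulus_drug")
rc_assays <- c("input", "ip", "igg")

validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "assay", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  samples$assay <- as.character(samples$assay)
  bad <- setdiff(unique(samples$condition), rc_conditions)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$assay), rc_assays)
  if (length(bad)) stop("unknown assay(s): ", paste(bad, collapse = ", "))
  rep_num <- suppressWarnings(as.numeric(samples$replicate))
  if (any(!is.finite(rep_num)) || any(rep_num < 1) || any(rep_num != round(rep_num)))
    stop("replicate must be a positive integer")
  samples$replicate <- as.integer(rep_num)
  rownames(samples) <- NULL
  samples[need]
}

check_integer_counts <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (any(!is.finite(v))) stop("counts contain missing or non-numeric values")
  if (any(v < 0)) stop("counts contain negative values")
  if (any(v != round(v)))
    stop("counts contain fractional values; integer counts are required ",
         "(round or re-count upstream rather than loading expected counts)")
  invisible(TRUE)
}

#' Read a count table plus sample sheet
#'
#' Accepts either a TSV table (genes in rows, first column the gene id,
#' remaining columns one per sample, header row mandatory) or a MatrixMarket
#' coordinate file (`.mtx`, integer, 1-based) with sidecar files
#' `<path>.rownames` and `<path>.colnames` holding one gene / sample id per
#' line. Columns are reordered to the sample-sheet order.
#'
#' @param path Path to the `.tsv`/`.txt` or `.mtx` count file.
#' @param sample_sheet Path to a TSV sample sheet with columns
#'   `sample_id`, `condition`, `assay`, `replicate`.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, sample_sheet) {
  if (!file.exists(path)) stop("count file not found: ", path)
  if (!file.exists(sample_sheet)) stop("sample sheet not found: ", sample_sheet)
  t0 <- proc.time()[["elapsed"]]
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- Matrix::readMM(path)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("MatrixMarket dimensions do not match sidecar name files")
    mat <- as.matrix(m)
    dimnames(mat) <- list(rn, cn)
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("count TSV needs a gene-id column plus sample columns")
    ids <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- ids
  }
  check_integer_counts(mat)
  sheet <- utils::read.delim(sample_sheet, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(sheet$sample_id, colnames(mat))
  if (length(missing))
    stop("sample(s) in sheet but not in count matrix: ",
         paste(missing, collapse = ", "))
  mat <- mat[, sheet$sample_id, drop = FALSE]
  out <- count_matrix(mat, sheet)
  rc_log("read_count_table: %d genes x %d samples [%.2fs]",
         nrow(mat), ncol(mat), proc.time()[["elapsed"]] - t0)
  out
}

#' Write a count matrix
#'
#' Writes the counts in either dialect understood by [read_count_table()]
#' and the sample sheet alongside. The TSV dialect is UTF-8,
#' tab-separated, header row, no quoting; the MatrixMarket dialect is
#' coordinate integer with `<path>.rownames`/`<path>.colnames` sidecars.
#'
#' @param x A [count_matrix()].
#' @param path Output path for the matrix (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`; defaults from the file extension.
#' @param sample_sheet Optional path for the sample sheet TSV;
#'   `NULL` suppresses it.
#' @return Invisibly, the character vector of files written.
#' @export
write_count_table <- function(x, path, format = NULL, sample_sheet = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  format <- match.arg(format, c("tsv", "mtx"))
  written <- character()
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(x$counts), x$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- path
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(x$counts), paste0(path, ".rownames"))
    writeLines(colnames(x$counts), paste0(path, ".colnames"))
    written <- c(path, paste0(path, ".rownames"), paste0(path, ".colnames"))
  }
  if (!is.null(sample_sheet)) {
    utils::write.table(x$samples, sample_sheet, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, sample_sheet)
  }
  invisible(written)
}

#' Read 3'-UTR (or probe) sequences from FASTA
#'
#' Sequences are normalized to the RNA alphabet on load: lowercase is folded
#' to uppercase and T is mapped to U, so all downstream ARE patterns are
#' defined over `{A,C,G,U,N}` only. Record ids are the first
#' whitespace-delimited token of each header; input order is preserved.
#'
#' @param path FASTA file. An empty file yields an empty vector.
#' @return Named character vector of RNA sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("zero-length sequence for record(s): ", paste(ids[empty], collapse = ", "))
  mixed <- grepl("T", seqs, fixed = TRUE) & grepl("U", seqs, fixed = TRUE)
  if (any(mixed))
    stop("record(s) mix T and U in one sequence: ", paste(ids[mixed], collapse = ", "))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    stop("record(s) contain characters outside {A,C,G,U,T,N}: ",
         paste(ids[bad], collapse = ", "))
  rc_log("read_sequences: %d records", length(seqs))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector as returned by [read_sequences()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_sequences <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene-set collection (GMT)
#'
#' GMT dialect: one set per line, tab-separated as
#' `name <TAB> description <TAB> member...`. Duplicate members within a set
#' are removed; set order is preserved.
#'
#' @param path GMT file. An empty file yields an empty collection.
#' @return A named list of character vectors (class
#'   `gene_set_collection`) with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " has no members")
    sets[[f[[1]]]] <- members
    desc[[f[[1]]]] <- f[[2]]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write a gene-set collection (GMT)
#'
#' @param collection A `gene_set_collection` (or plain named list of
#'   character vectors).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Subset a count matrix by assay and/or condition
#'
#' @param x A [count_matrix()].
#' @param assay,condition Optional values to keep.
#' @param genes Optional gene ids to keep.
#' @return A [count_matrix()] restricted to the selection.
#' @export
subset_counts <- function(x, assay = NULL, condition = NULL, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(assay)) keep <- keep & x$samples$assay %in% assay
  if (!is.null(condition)) keep <- keep & x$samples$condition %in% condition
  if (!any(keep)) stop("selection removes every sample")
  counts <- x$counts[, keep, drop = FALSE]
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(counts))
    if (length(miss)) stop("gene(s) not present: ", paste(utils::head(miss, 5), collapse = ", "))
    counts <- counts[genes, , drop = FALSE]
  }
  count_matrix(counts, x$samples[keep, , drop = FALSE])
}

# INFO-level logging; enabled via options(ripcouple.verbose = TRUE)
rc_log <- function(fmt, ...) {
  if (isTRUE(getOption("ripcouple.verbose", FALSE)))
    message(sprintf(paste0("[ripcouple] ", fmt), ...))
  invisible(NULL)
}
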