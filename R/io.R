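#' Read a FASTA file into a named character vector
#'
#' Preserves record order, uppercases sequences, and rejects duplicate ids
#' and empty records.
#'
#' @param path FASTA file path.
#' @return Named character vector (id -> sequence).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(ss) == 0L))
    stop("empty FASTA record(s): ",
         paste(ids[Biostrings::width(ss) == 0L], collapse = ", "))
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and validate a TSV table against a column schema
#'
#' @param path TSV file (tab-separated, UTF-8, header row).
#' @param schema Named character vector column -> type, types in
#'   "character", "numeric", "integer". Listed columns are required and
#'   coerced; a non-coercible cell aborts with its row and column.
#' @param row_names Optional: name of the column to use as row names.
#' @return data.frame with enforced types.
#' @export
read_table <- function(path, schema = NULL, row_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("table has no data rows: ", path)
  for (col in names(schema)) {
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path)
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad) > 0L)
        stop("non-numeric value in column '", col, "', row ", bad[1L],
             " of ", path)
      df[[col]] <- if (type == "integer") as.integer(round(v)) else v
    } else df[[col]] <- as.character(df[[col]])
  }
  if (!is.null(row_names)) {
    rownames(df) <- df[[row_names]]
    df[[row_names]] <- NULL
  }
  df
}

#' Read an ASV count table (samples as rows) from TSV
#'
#' First column holds sample ids; remaining columns are ASV read counts.
#' Negative or non-integer cells abort with the offending row and column.
#'
#' @param path TSV path.
#' @return Samples x ASVs integer matrix.
#' @export
read_counts <- function(path) {
  df <- read_table(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("invalid count at row '", rownames(m)[bad[1L, 1L]],
         "', column '", colnames(m)[bad[1L, 2L]], "' of ", path)
  storage.mode(num) <- "integer"
  num
}

#' Write a matrix as TSV with an id column for the rows
#'
#' @param m Matrix or data.frame.
#' @param path Output path.
#' @param id_col Name for the row-id column.
#' @export
write_tsv_matrix <- function(m, path, id_col = "sample") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated community to disk
#'
#' Emits the canonical file set: counts TSV (samples as rows), ASV FASTA,
#' sample metadata TSV, and a ground-truth JSON map (strain -> ASVs with
#' multiplicities).
#'
#' @param tab An `asv_table` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_asv_table <- function(tab, dir) {
  stopifnot(inherits(tab, "asv_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "asv_counts.tsv"),
             species = file.path(dir, "asv_species.tsv"),
             fasta = file.path(dir, "asv_seqs.fasta"),
             meta = file.path(dir, "sample_metadata.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_tsv_matrix(tab$counts, paths["counts"], id_col = "sample")
  utils::write.table(
    data.frame(asv_id = names(tab$asv_species), species = tab$asv_species),
    paths["species"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tab$asv_seqs)) write_fasta(tab$asv_seqs, paths["fasta"])
  if (!is.null(tab$sample_meta))
    utils::write.table(tab$sample_meta, paths["meta"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(tab$truth))
    jsonlite::write_json(tab$truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read an `asv_table` back from a directory written by [write_asv_table()]
#'
#' @param dir Directory containing `asv_counts.tsv` and `asv_species.tsv`.
#' @return An `asv_table`.
#' @export
read_asv_table <- function(dir) {
  counts <- read_counts(file.path(dir, "asv_counts.tsv"))
  spp <- read_table(file.path(dir, "asv_species.tsv"),
                    schema = c(asv_id = "character", species = "character"))
  seqs <- NULL
  fp <- file.path(dir, "asv_seqs.fasta")
  if (file.exists(fp)) seqs <- read_fasta(fp)
  meta <- NULL
  mp <- file.path(dir, "sample_metadata.tsv")
  if (file.exists(mp)) meta <- read_table(mp)
  asv_table(counts,
            asv_species = stats::setNames(spp$species, spp$asv_id),
            asv_seqs = seqs, sample_meta = meta)
}
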