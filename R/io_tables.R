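#' Read an rMATS Junction-Counts result table
#'
#' Consumes the tab-separated JC output of a pairwise rMATS comparison.
#' `IncLevel1`/`IncLevel2` hold comma-separated per-replicate PSI values
#' ("NA" allowed and preserved as missing); `FDR` is the event's false
#' discovery rate. Rows whose PSI values are all missing in either group
#' are rejected with a warning.
#'
#' @param path tab-separated file with at least IncLevel1, IncLevel2, FDR.
#' @param event_type rMATS event type of this table (JC files are written
#'   per type); overridden by an `event_type` column when present.
#' @return data.frame with columns event_id, gene, event_type, fdr and
#'   list-columns psi_group1, psi_group2 (numeric vectors with NAs).
#' @export
read_rmats_jc <- function(path, event_type = "SE") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("IncLevel1", "IncLevel2", "FDR")
  if (!all(needed %in% names(tab)))
    stop("rMATS JC table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  parse_psi <- function(x) {
    lapply(strsplit(as.character(x), ",", fixed = TRUE), function(v) {
      out <- suppressWarnings(as.numeric(v))
      if (any(out < 0 | out > 1, na.rm = TRUE))
        stop("PSI value outside [0,1]", call. = FALSE)
      out
    })
  }
  id_col <- intersect(c("event_id", "ID"), names(tab))[1]
  gene_col <- intersect(c("gene", "geneSymbol", "GeneID"), names(tab))[1]
  et <- if ("event_type" %in% names(tab)) as.character(tab$event_type)
        else rep(event_type, nrow(tab))
  if (!all(et %in% c("SE", "A5SS", "A3SS", "MXE", "RI")))
    stop("event_type outside the rMATS vocabulary", call. = FALSE)
  out <- data.frame(
    event_id = if (!is.na(id_col)) as.character(tab[[id_col]])
               else as.character(seq_len(nrow(tab))),
    gene = if (!is.na(gene_col)) as.character(tab[[gene_col]])
           else NA_character_,
    event_type = et,
    fdr = as.numeric(tab$FDR),
    stringsAsFactors = FALSE
  )
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE))
    stop("FDR outside [0,1]", call. = FALSE)
  out$psi_group1 <- parse_psi(tab$IncLevel1)
  out$psi_group2 <- parse_psi(tab$IncLevel2)
  all_na <- function(col) vapply(col, function(v) all(is.na(v)), logical(1))
  bad <- all_na(out$psi_group1) | all_na(out$psi_group2)
  if (any(bad)) {
    warning(sum(bad), " event(s) rejected: all PSI values missing in a group",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  .log_counts("read_rmats_jc", nrow(tab), nrow(out))
  rownames(out) <- NULL
  out
}

#' Write splice rows in rMATS-JC form
#'
#' Inverse of [read_rmats_jc()] on the consumed columns; used by the
#' splice-table simulator.
#'
#' @param rows data.frame as returned by [read_rmats_jc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmats_jc <- function(rows, path) {
  fmt_psi <- function(col) vapply(col, function(v) {
    s <- ifelse(is.na(v), "NA", formatC(v, digits = 17, format = "g"))
    paste(s, collapse = ",")
  }, character(1))
  tab <- data.frame(
    ID = rows$event_id, geneSymbol = rows$gene, event_type = rows$event_type,
    IncLevel1 = fmt_psi(rows$psi_group1), IncLevel2 = fmt_psi(rows$psi_group2),
    FDR = formatC(rows$fdr, digits = 17, format = "g"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like region annotation
#'
#' Four tab-separated columns: chrom, start (0-based inclusive), end
#' (0-based exclusive), class. Classes come from the fixed vocabulary
#' {exonic, intronic, UTR5, UTR3}.
#'
#' @param path annotation path (no header, or a header line starting `#`).
#' @return data.frame with columns chrom, start, end, class.
#' @export
read_region_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("region annotation needs 4 columns: chrom, start, end, class",
         call. = FALSE)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    class = as.character(tab[[4]]),
                    stringsAsFactors = FALSE)
  region_annotation(out)
}

#' Construct/validate a region annotation table
#'
#' @param df data.frame with chrom, start (0-based), end (exclusive), class.
#' @return validated data.frame of class `region_annotation`.
#' @export
region_annotation <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(df)))
  if (any(df$start >= df$end))
    stop("intervals must satisfy start < end", call. = FALSE)
  ok <- df$class %in% c("exonic", "intronic", "UTR5", "UTR3")
  if (!all(ok))
    stop("unknown region class: ",
         paste(unique(df$class[!ok]), collapse = ", "), call. = FALSE)
  class(df) <- unique(c("region_annotation", class(df)))
  df
}

#' Read an aligned-reads table
#'
#' One aligned read sequence per line (plain text) or a FASTA file. Reads
#' are aligned to the amplicon window: equal length, with `-` marking a
#' deleted base.
#'
#' @param path input path.
#' @return character vector of read sequences.
#' @export
read_reads_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    reads <- as.character(Biostrings::readBStringSet(path))
    names(reads) <- NULL
  } else {
    reads <- readLines(path, warn = FALSE)
    reads <- reads[nzchar(reads)]
  }
  toupper(reads)
}

#' Read/write a reference FASTA
#'
#' Wrappers over Biostrings returning plain named character vectors,
#' which is the reference representation the pipeline passes around.
#'
#' @param path FASTA path.
#' @return named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of contig sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read an expression matrix with cell metadata
#'
#' The matrix is a genes x cells TSV (first column = gene id, header =
#' cell ids); the metadata TSV has columns cell_id, condition, cluster.
#'
#' @param matrix_path,metadata_path input paths.
#' @return list with `expression` (numeric matrix, genes x cells) and
#'   `metadata` (data.frame), checked for consistency.
#' @export
read_expression_matrix <- function(matrix_path, metadata_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "condition", "cluster") %in% names(meta)))
  cell_matrix(m, meta)
}

#' Construct/validate a cell matrix
#'
#' @param expression non-negative genes x cells matrix with unique
#'   dimnames.
#' @param metadata data.frame with cell_id, condition, cluster; one row
#'   per matrix column.
#' @return list of class `cell_matrix`.
#' @export
cell_matrix <- function(expression, metadata) {
  stopifnot(is.matrix(expression))
  if (anyDuplicated(rownames(expression)) || anyDuplicated(colnames(expression)))
    stop("duplicate gene or cell identifiers", call. = FALSE)
  if (any(expression < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (!setequal(colnames(expression), metadata$cell_id) ||
      anyDuplicated(metadata$cell_id))
    stop("metadata cell_id must match matrix columns exactly", call. = FALSE)
  metadata <- metadata[match(colnames(expression), metadata$cell_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(expression = expression, metadata = metadata),
            class = "cell_matrix")
}
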