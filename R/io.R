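#' Write and read allele read-count matrices
#'
#' The TSV dialect has one row per marker and one column per individual;
#' each cell is `"xA,xB"`. The VCF dialect is a minimal VCFv4.2 with an
#' `AD` FORMAT field holding the same two counts.
#'
#' @param reads a `read_counts` object.
#' @param path output file path.
#' @param marker_info optional data.frame with columns `marker`, `chrom`,
#'   `pos_cM` used to fill CHROM/POS in the VCF; otherwise placeholders
#'   are written.
#' @return `path`, invisibly (writers); a `read_counts` object (readers).
#' @name read_counts_io
NULL

#' @rdname read_counts_io
#' @export
write_read_counts <- function(reads, path) {
  stopifnot(inherits(reads, "read_counts"))
  cells <- matrix(paste(reads$xA, reads$xB, sep = ","),
                  nrow(reads$xA), dimnames = dimnames(reads$xA))
  df <- data.frame(marker = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_counts_io
#' @export
read_read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mk <- df$marker
  cells <- as.matrix(df[, -1, drop = FALSE])
  xA <- apply(cells, 2, function(col) as.integer(sub(",.*", "", col)))
  xB <- apply(cells, 2, function(col) as.integer(sub(".*,", "", col)))
  dim(xA) <- dim(xB) <- dim(cells)
  dimnames(xA) <- dimnames(xB) <- list(mk, colnames(cells))
  structure(list(xA = xA, xB = xB, replicate_map = list()),
            class = "read_counts")
}

#' @rdname read_counts_io
#' @export
write_read_counts_vcf <- function(reads, path, marker_info = NULL) {
  stopifnot(inherits(reads, "read_counts"))
  mk <- rownames(reads$xA)
  if (!is.null(marker_info)) {
    i <- match(mk, marker_info$marker)
    chrom <- marker_info$chrom[i]
    # integer bp placeholder derived from cM so positions stay ordered
    pos <- as.integer(round(marker_info$pos_cM[i] * 1e4)) + 1L
  } else {
    chrom <- rep("1", length(mk))
    pos <- seq_along(mk)
  }
  ad <- matrix(paste(reads$xA, reads$xB, sep = ","), nrow(reads$xA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(reads$xA)), collapse = "\t")),
             con)
  body <- cbind(chrom, pos, mk, "A", "C", ".", ".", ".", "AD", ad)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname read_counts_io
#' @export
read_read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  rownames(ad) <- v@fix[, "ID"]
  xA <- apply(ad, 2, function(col) as.integer(sub(",.*", "", col)))
  xB <- apply(ad, 2, function(col) as.integer(sub(".*,", "", col)))
  dim(xA) <- dim(xB) <- dim(ad)
  dimnames(xA) <- dimnames(xB) <- dimnames(ad)
  structure(list(xA = xA, xB = xB, replicate_map = list()),
            class = "read_counts")
}

#' Export a truth set as plain-text tables
#'
#' Writes the per-individual dosage table (`marker`, `individual`,
#' `dosage`, long format) and the true map (`chrom`, `homolog`, `marker`,
#' `pos_cM`, `parent`, `type`).
#'
#' @param truth a `truth_set`.
#' @param dosage_path,map_path output paths (`NULL` skips that table).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dosage_path = NULL, map_path = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!is.null(dosage_path)) {
    d <- truth$dosage
    long <- data.frame(marker = rep(rownames(d), ncol(d)),
                       individual = rep(colnames(d), each = nrow(d)),
                       dosage = as.vector(d))
    utils::write.table(long, dosage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(map_path)) {
    utils::write.table(
      truth$map[, c("chrom", "homolog", "marker", "pos_cM", "parent", "type")],
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(dosage_path, map_path))
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Malformed rows are
#' reported with their line numbers and dropped. The subject position is
#' taken as `min(sstart, send)`.
#'
#' @param path path to the tab-separated hit table (no header).
#' @return data.frame with columns `marker`, `subject`, `subject_pos`,
#'   `evalue`, `bitscore` plus the raw columns.
#' @export
read_blast_table <- function(path) {
  lines <- readLines(path)
  lineno <- which(nzchar(lines))
  fields <- strsplit(lines[lineno], "\t", fixed = TRUE)
  ok <- vapply(fields, length, 0L) == 12L
  if (any(!ok)) {
    warning(sprintf("dropping %d malformed row(s) at line(s): %s",
                    sum(!ok), paste(lineno[!ok], collapse = ", ")))
    fields <- fields[ok]
    lineno <- lineno[ok]
  }
  if (!length(fields))
    return(data.frame(marker = character(0), subject = character(0),
                      subject_pos = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0)))
  m <- do.call(rbind, fields)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  df <- data.frame(marker = m[, 1], subject = m[, 2],
                   sstart = num(9), send = num(10),
                   evalue = num(11), bitscore = num(12),
                   stringsAsFactors = FALSE)
  bad <- !stats::complete.cases(df[, c("sstart", "send", "evalue", "bitscore")])
  if (any(bad)) {
    warning(sprintf("dropping %d non-numeric row(s) at line(s): %s",
                    sum(bad), paste(lineno[bad], collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  df$subject_pos <- pmin(df$sstart, df$send)
  df[, c("marker", "subject", "subject_pos", "evalue", "bitscore")]
}
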