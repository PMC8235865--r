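#' Read BLAST tabular (12-column) alignment hits
#'
#' Parses the standard 12-column tabular dialect (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score). Subject coordinates are kept as
#' printed — `s_start > s_end` encodes a minus-strand hit — and normalized
#' columns `s_min`, `s_max` and `strand` are added. Rows violating the hit
#' invariants (query start after end, identity outside [0, 100], alignment
#' length < 1, negative e-value) are rejected with their row number.
#'
#' @param path Path to a tab-separated hit table without header. Extra
#'   columns beyond the twelfth are ignored.
#' @return data.frame with columns `query_acc`, `subject_id`,
#'   `identity_pct`, `aln_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, `s_min`, `s_max`,
#'   `strand`. An empty file yields a zero-row data.frame.
#' @export
readBlastTab <- function(path) {
  stopifnot(file.exists(path))
  cols <- c("query_acc", "subject_id", "identity_pct", "aln_len",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  empty <- data.frame(
    query_acc = character(), subject_id = character(),
    identity_pct = numeric(), aln_len = integer(), mismatches = integer(),
    gap_opens = integer(), q_start = integer(), q_end = integer(),
    s_start = numeric(), s_end = numeric(), evalue = numeric(),
    bitscore = numeric(), s_min = numeric(), s_max = numeric(),
    strand = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop(sprintf("malformed hit table: row %d has %d field(s), expected >= 12",
                 which(nf < 12L)[1L], nf[which(nf < 12L)[1L]]))
  m <- do.call(rbind, lapply(fields, `[`, seq_len(12L)))
  df <- data.frame(
    query_acc = m[, 1L], subject_id = m[, 2L],
    identity_pct = as.numeric(m[, 3L]), aln_len = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gap_opens = as.integer(m[, 6L]),
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    s_start = as.numeric(m[, 9L]), s_end = as.numeric(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  num <- df[c("identity_pct", "aln_len", "q_start", "q_end", "s_start",
              "s_end", "evalue")]
  if (anyNA(num))
    stop(sprintf("malformed hit table: non-numeric field in row %d",
                 which(rowSums(is.na(num)) > 0)[1L]))
  bad <- which(df$q_start > df$q_end | df$identity_pct < 0 |
                 df$identity_pct > 100 | df$aln_len < 1L | df$evalue < 0)
  if (length(bad))
    stop(sprintf("hit invariants violated in row %d", bad[1L]))
  df$s_min <- pmin(df$s_start, df$s_end)
  df$s_max <- pmax(df$s_start, df$s_end)
  df$strand <- ifelse(df$s_start <= df$s_end, "+", "-")
  df
}

#' Read a curated EVE table
#'
#' Reads a tab-separated table with a header naming at least the seven
#' required columns `identifier`, `virus`, `v_start`, `v_end`, `chrom`,
#' `h_start`, `h_end`. An optional `length` column is checked against the
#' coordinate-difference convention `|h_end - h_start|` (mismatches warn
#' and the printed value is kept). Any derived gap columns are ignored;
#' gaps are recomputed downstream by [computeGap()]. The table bundled
#' with the package (see [aegyptiEveTable()]) is in this format.
#'
#' @param path Path to the TSV file.
#' @return An [EveSet-class] in file order.
#' @export
readEveTable <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("identifier", "virus", "v_start", "v_end", "chrom",
            "h_start", "h_end")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("EVE table missing required column(s): ",
         paste(miss, collapse = ", "))
  EveSet(identifier = df$identifier, virus = df$virus,
         vStart = df$v_start, vEnd = df$v_end, chrom = df$chrom,
         hStart = df$h_start, hEnd = df$h_end,
         length = if ("length" %in% colnames(df)) df$length else NULL)
}

#' The flavivirus EVE fragments curated from the Ae. aegypti assembly
#'
#' Returns the 29 curated flavivirus EVE fragments of the *Aedes aegypti*
#' AaegL5 reference assembly (identifiers AE1.1 to AE29.4, viruses XAFV
#' and Modoc virus) bundled with the package, the worked example used
#' throughout the documentation.
#'
#' @return An [EveSet-class] with 29 records.
#' @examples
#' length(aegyptiEveTable())
#' @export
aegyptiEveTable <- function() {
  readEveTable(system.file("extdata", "aegypti_flavivirus_eves.tsv",
                           package = "eveTrace", mustWork = TRUE))
}

#' Write EVE fragments as BED6
#'
#' Converts the 1-based inclusive host footprints to 0-based half-open
#' BED intervals; the name column carries the identifier and the strand
#' column the coordinate orientation.
#'
#' @param x An [EveSet-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(x, path) {
  stopifnot(methods::is(x, "EveSet"))
  df <- as.data.frame(x)
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t.\t%s",
                   df$chrom, pmin(df$h_start, df$h_end) - 1,
                   pmax(df$h_start, df$h_end), df$identifier, df$strand)
  writeLines(if (nrow(df)) lines else character(), path)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Three tab-separated columns: contig, 1-based position, depth. Positions
#' must be strictly increasing within each contig; zero-depth positions may
#' be omitted (absent positions are treated as depth 0 downstream).
#'
#' @param path Path to the TSV file (no header).
#' @param sampleId Sample label attached as the `sample_id` attribute
#'   (default: file name without extension).
#' @return data.frame with columns `contig`, `pos`, `depth`.
#' @export
readDepthTable <- function(path, sampleId = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t",
                      col.names = c("contig", "pos", "depth"),
                      colClasses = c("character", "numeric", "numeric"),
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed depth table: ", conditionMessage(e)))
  if (nrow(df)) {
    if (any(df$depth < 0)) stop("negative depth value")
    mono <- unlist(lapply(split(df$pos, df$contig), function(p)
      all(diff(p) > 0)), use.names = TRUE)
    if (!all(mono))
      stop("positions not strictly increasing on contig ",
           names(mono)[!mono][1L])
  }
  attr(df, "sample_id") <- sampleId
  df
}

#' Read variant records from a VCF file (minimal subset)
#'
#' Accepts a standard VCF and keeps chromosome, position, reference and
#' alternate alleles only (genotypes, qualities and filters are ignored, as
#' the densities downstream are computed on unfiltered variant counts).
#' Multi-allelic records are expanded to one row per alternate allele, and
#' each row is typed `SNP` when both alleles are single bases, `InDel`
#' otherwise.
#'
#' @param path Path to the VCF file.
#' @param sampleId Sample label stored in the `sample_id` column
#'   (default: file name without extension).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `type`,
#'   `sample_id`.
#' @export
readVariants <- function(path, sampleId = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (!nrow(fix))
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      type = character(), sample_id = character(),
                      stringsAsFactors = FALSE))
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n <- lengths(alts)
  df <- data.frame(
    chrom = rep(as.character(fix[, "CHROM"]), n),
    pos = rep(as.numeric(fix[, "POS"]), n),
    ref = rep(as.character(fix[, "REF"]), n),
    alt = unlist(alts),
    stringsAsFactors = FALSE)
  if (any(df$pos < 1)) stop("variant position < 1")
  df$type <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L,
                    "SNP", "InDel")
  df$sample_id <- sampleId
  df
}

#' Read small-RNA alignment records
#'
#' Four tab-separated columns: contig, 1-based 5'-most position, strand
#' (`+`/`-`), read length in nt.
#'
#' @param path Path to the TSV file (no header).
#' @return data.frame with columns `contig`, `pos`, `strand`,
#'   `read_length`.
#' @export
readSmallRna <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "pos", "strand",
                                        "read_length"),
                          colClasses = c("character", "numeric",
                                         "character", "integer"),
                          stringsAsFactors = FALSE)
  if (nrow(df)) {
    bad <- !df$strand %in% c("+", "-")
    if (any(bad))
      stop(sprintf("unknown strand symbol '%s' in row %d",
                   df$strand[which(bad)[1L]], which(bad)[1L]))
    if (any(df$read_length < 1L)) stop("read_length must be >= 1")
    if (any(df$pos < 1)) stop("position must be >= 1")
  }
  df
}

#' Writers for the simulator's tabular outputs
#'
#' `writeHitTable()` writes a 12-column BLAST-style tabular file readable
#' by [readBlastTab()]; `writeDepthTable()` and `writeSmallRna()` write
#' the depth and small-RNA TSVs readable by their counterparts;
#' `writeVcfMinimal()` writes a minimal sites-only VCF readable by
#' [readVariants()].
#'
#' @param x The table to write (as produced by the simulator or readers).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @name tabular-writers
NULL

#' @rdname tabular-writers
#' @export
writeHitTable <- function(x, path) {
  cols <- c("query_acc", "subject_id", "identity_pct", "aln_len",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  stopifnot(all(cols %in% colnames(x)))
  utils::write.table(format(x[cols], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname tabular-writers
#' @export
writeDepthTable <- function(x, path) {
  stopifnot(all(c("contig", "pos", "depth") %in% colnames(x)))
  utils::write.table(x[c("contig", "pos", "depth")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname tabular-writers
#' @export
writeSmallRna <- function(x, path) {
  stopifnot(all(c("contig", "pos", "strand", "read_length") %in%
                  colnames(x)))
  utils::write.table(x[c("contig", "pos", "strand", "read_length")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname tabular-writers
#' @export
writeVcfMinimal <- function(x, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% colnames(x)))
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%.0f\t.\t%s\t%s\t.\t.\t.",
                  x$chrom, x$pos, x$ref, x$alt)
  writeLines(c(header, body), path)
  invisible(path)
}
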