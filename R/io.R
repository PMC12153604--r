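#' Read per-site cytosine methylation calls
#'
#' Reads the canonical 6-column tab-separated call table: chromosome,
#' 1-based position, strand (+/-), context (CG/CHG/CHH), methylated read
#' count, total read count. Blank lines are skipped and lines starting with
#' `#` are comments. Sites with `total == 0` (uncovered) are dropped with a
#' message rather than treated as 0% methylated.
#'
#' @param path file path.
#' @param sample_id label attached to every call.
#' @return `data.table` with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `meth`, `total`, `sample_id`.
#' @export
read_methylation_calls <- function(path, sample_id) {
  stopifnot(file.exists(path))
  sk <- .leading_noise(path)
  if (is.na(sk)) {
    warning("empty methylation call file: ", path)
    return(.empty_calls(sample_id))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          blank.lines.skip = TRUE, skip = sk,
                          colClasses = list(character = c(1, 3, 4)))
  if (nrow(dt) == 0L) {
    warning("empty methylation call file: ", path)
    return(.empty_calls(sample_id))
  }
  comment <- startsWith(dt[[1]], "#")
  dt <- dt[!comment]
  if (nrow(dt) == 0L) return(.empty_calls(sample_id))
  if (ncol(dt) < 6L) stop("expected 6 tab-separated columns in ", path)
  data.table::setnames(dt, 1:6, c("chrom", "pos", "strand", "context", "meth", "total"))
  dt <- dt[, 1:6]
  .validate_calls(dt, path)
  n0 <- dt[total == 0L, .N]
  if (n0 > 0L) {
    message("dropping ", n0, " uncovered sites (total_count = 0) from ", basename(path))
    dt <- dt[total > 0L]
  }
  dt[, sample_id := sample_id]
  dt[]
}

## number of leading blank or '#'-comment lines, or NA when the file holds no
## data lines at all (fread mis-detects the column count when the first line
## it sees is a comment without separators, and errors when skip == n_lines)
.leading_noise <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 512L, warn = FALSE)
    if (length(chunk) == 0L) return(NA_integer_)
    noise <- !nzchar(trimws(chunk)) | startsWith(chunk, "#")
    if (all(noise)) n <- n + length(chunk)
    else return(n + which(!noise)[1L] - 1L)
  }
}

.empty_calls <- function(sample_id) {
  data.table::data.table(chrom = character(), pos = integer(),
                         strand = character(), context = character(),
                         meth = integer(), total = integer(),
                         sample_id = character())
}

.validate_calls <- function(dt, path = "<calls>") {
  bad <- which(!is.finite(dt$pos) | !is.finite(dt$meth) | !is.finite(dt$total))
  if (length(bad)) stop("malformed line: data row ", bad[1], " of ", path)
  if (any(dt$pos < 1L)) stop("positions must be 1-based (>= 1) in ", path)
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at data row ", bad[1], " of ", path)
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) stop("invalid context at data row ", bad[1], " of ", path)
  bad <- which(dt$meth < 0L | dt$total < 0L | dt$meth > dt$total)
  if (length(bad)) {
    stop("meth_count outside [0, total_count] at data row ", bad[1], " of ", path)
  }
  invisible(TRUE)
}

#' Read a Bismark-style CX report and convert to canonical calls
#'
#' CX reports carry columns chromosome, position (1-based), strand,
#' methylated count, unmethylated count, context, trinucleotide; the total
#' read count is the sum of the two count columns.
#'
#' @inheritParams read_methylation_calls
#' @return `data.table` in the canonical call layout (see
#'   [read_methylation_calls()]), uncovered sites dropped.
#' @export
read_cx_report <- function(path, sample_id) {
  stopifnot(file.exists(path))
  sk <- .leading_noise(path)
  if (is.na(sk)) stop("no data rows in CX report ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          blank.lines.skip = TRUE, skip = sk)
  dt <- dt[!startsWith(as.character(dt[[1]]), "#")]
  if (ncol(dt) < 6L) stop("expected >= 6 columns in CX report ", path)
  out <- data.table::data.table(
    chrom = as.character(dt[[1]]), pos = as.integer(dt[[2]]),
    strand = as.character(dt[[3]]), context = as.character(dt[[6]]),
    meth = as.integer(dt[[4]]), total = as.integer(dt[[4]]) + as.integer(dt[[5]]))
  .validate_calls(out, path)
  out <- out[total > 0L]
  out[, sample_id := sample_id]
  out[]
}

#' Write methylation calls in the canonical 6-column layout
#' @param calls call `data.table` (see [read_methylation_calls()]).
#' @param path output file.
#' @export
write_methylation_calls <- function(calls, path) {
  data.table::fwrite(calls[, .(chrom, pos, strand, context, meth, total)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GTF
#'
#' BED input is used as-is (0-based half-open, name column = gene id). From
#' GTF only rows with feature type `gene` are used and coordinates are
#' converted from 1-based closed to 0-based half-open. Duplicate gene ids
#' and missing strands are errors.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gtf"`.
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = format)
  if (format == "gtf") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (length(gr) == 0L) stop("no 'gene' feature rows in ", path)
    ids <- as.character(gr$gene_id)
  } else {
    ids <- as.character(gr$name)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("missing strand in annotation ", path)
  genes <- data.table::data.table(
    gene_id = ids, chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # both formats come back 1-based from import()
    end = BiocGenerics::end(gr), strand = strand)
  if (anyNA(genes$gene_id)) stop("missing gene identifiers in ", path)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop("duplicate gene_id in annotation: ", dup[1])
  if (any(genes$start >= genes$end)) stop("gene with start >= end in ", path)
  genes[]
}

#' Write gene models as BED6
#' @param genes gene `data.table` (see [read_gene_annotation()]).
#' @param path output file.
#' @export
write_gene_annotation <- function(genes, path) {
  bed <- genes[, .(chrom, start, end, name = gene_id, score = 0L, strand)]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression table
#'
#' TSV with a header row of sample ids and gene ids in the first column;
#' values are RPKM/FPKM (treated as synonymous). Returns the long form.
#'
#' @param path file path.
#' @return `data.table` with `gene_id`, `sample_id`, `rpkm`.
#' @export
read_expression_table <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (nrow(dt) == 0L) {
    warning("expression table has no data rows: ", path)
    return(data.table::data.table(gene_id = character(),
                                  sample_id = character(), rpkm = numeric()))
  }
  data.table::setnames(dt, 1L, "gene_id")
  samples <- names(dt)[-1L]
  for (s in samples) {
    v <- dt[[s]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric expression value at gene '", dt$gene_id[bad],
           "', sample '", s, "' in ", path)
    }
    data.table::set(dt, j = s, value = as.numeric(v))  # uniform type for melt
  }
  long <- data.table::melt(dt, id.vars = "gene_id", variable.name = "sample_id",
                           value.name = "rpkm", variable.factor = FALSE)
  if (any(long$rpkm < 0, na.rm = TRUE)) {
    bad <- long[rpkm < 0][1]
    stop("negative expression value at gene '", bad$gene_id, "', sample '",
         bad$sample_id, "' in ", path)
  }
  if (anyNA(long$rpkm)) stop("missing expression values in ", path)
  long[]
}

#' Write an expression table (wide TSV, genes x samples)
#' @param expr long-form expression `data.table` (`gene_id`, `sample_id`, `rpkm`).
#' @param path output file.
#' @export
write_expression_table <- function(expr, path) {
  wide <- data.table::dcast(expr, gene_id ~ sample_id, value.var = "rpkm")
  data.table::fwrite(wide, path, sep = "\t")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set id, description, then one or more member gene ids,
#' tab-separated. Duplicate members within a set are removed with a warning;
#' lines with fewer than three fields are errors.
#'
#' @param path GMT file.
#' @return named list of gene sets; each element is a list with `set_id`,
#'   `name`, `members`.
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line ", i, " has fewer than 3 fields")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in gene set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    if (length(members) == 0L) stop("GMT line ", i, " has no members")
    list(set_id = f[1], name = f[2], members = members)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  sets
}

#' Write gene sets in GMT format
#' @param sets list of gene sets as returned by [read_gene_sets()].
#' @param path output file.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write DMRs as BED with score = round(-10 log10 p)
#' @param dmrs DMR `data.table` from [call_dmrs()].
#' @param path output file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- dmrs[, .(chrom, start, end,
                  name = paste(context, direction, sep = "|"),
                  score = round(-10 * log10(pmax(p_value, 1e-300))),
                  strand = ".")]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
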