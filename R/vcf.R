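# Minimal VCF v4.2 reading and writing. Internal representation of both truth
# and called variants is a data.frame with columns:
#   contig, pos (0-based), ref, alt (comma-joined ALTs), gt ("0/1" style),
#   qual (numeric), filter
# Only the fields the pipeline needs are handled (GT and GQ).

#' Read a VCF file
#'
#' @param path VCF path (plain text or gzip)
#' @return data.frame with columns contig, pos (0-based), ref, alt, gt, qual,
#'   filter
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), qual = numeric(0),
                      filter = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  gt <- vapply(f, function(x) {
    if (length(x) < 10L) return("1/1")
    keys <- strsplit(x[9], ":", fixed = TRUE)[[1]]
    vals <- strsplit(x[10], ":", fixed = TRUE)[[1]]
    g <- vals[match("GT", keys)]
    if (is.na(g)) "1/1" else gsub("|", "/", g, fixed = TRUE)
  }, character(1))
  data.frame(
    contig = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
    ref = vapply(f, `[[`, character(1), 4L),
    alt = vapply(f, `[[`, character(1), 5L),
    gt = gt,
    qual = suppressWarnings(as.numeric(vapply(f, `[[`, character(1), 6L))),
    filter = vapply(f, `[[`, character(1), 7L),
    stringsAsFactors = FALSE)
}

#' Write variant calls as VCF v4.2
#'
#' @param calls data.frame with columns contig, pos (0-based), ref, alt, gt,
#'   qual, filter (missing qual/filter filled in)
#' @param ref a `reference` (for contig header lines)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, ref, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=depthlift",
    sprintf("##contig=<ID=%s,length=%d>", names(ref$lengths), ref$lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE", sep = "\t"))
  if (nrow(calls)) {
    if (is.null(calls$qual)) calls$qual <- 60
    if (is.null(calls$filter)) calls$filter <- "PASS"
    calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
    gq <- as.integer(round(calls$qual))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t%s\t.\tGT:GQ\t%s:%d",
                    calls$contig, calls$pos + 1L, calls$ref, calls$alt,
                    calls$qual, calls$filter, calls$gt, gq)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Left-normalize one (pos, ref, alt-set) representation: shared trailing then
# leading context is trimmed (position advanced), keeping at least one base.
normalize_variant <- function(pos, ref, alts) {
  repeat {
    lastr <- substring(ref, nchar(ref), nchar(ref))
    lasta <- substring(alts, nchar(alts), nchar(alts))
    if (nchar(ref) > 1L && all(nchar(alts) > 1L) && all(lasta == lastr)) {
      ref <- substring(ref, 1L, nchar(ref) - 1L)
      alts <- substring(alts, 1L, nchar(alts) - 1L)
    } else break
  }
  repeat {
    firstr <- substring(ref, 1L, 1L)
    firsta <- substring(alts, 1L, 1L)
    if (nchar(ref) > 1L && all(nchar(alts) > 1L) && all(firsta == firstr)) {
      ref <- substring(ref, 2L)
      alts <- substring(alts, 2L)
      pos <- pos + 1L
    } else break
  }
  list(pos = pos, ref = ref, alts = alts)
}

# Canonical matching key: contig:pos:ref:{sorted alt set}:{genotype as sorted
# allele symbols}. Genotypes are compared unordered and through the sorted
# alt set so 0/1 == 1/0 and allele renumbering cannot split a match.
variant_key <- function(contig, pos, ref, alt, gt) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  nv <- normalize_variant(pos, ref, alts)
  o <- order(nv$alts)
  gt_idx <- suppressWarnings(
    as.integer(strsplit(gt, "[/|]")[[1]]))
  gt_idx[is.na(gt_idx)] <- 0L
  sym <- ifelse(gt_idx == 0L, nv$ref, nv$alts[gt_idx])
  paste(contig, nv$pos, nv$ref, paste(nv$alts[o], collapse = ","),
        paste(sort(sym), collapse = "/"), sep = ":")
}

# One truth record (as a list) at a 0-based position, or NULL.
truth_at <- function(truth, contig, pos) {
  hit <- which(truth$contig == contig & truth$pos == pos)
  if (!length(hit)) return(NULL)
  r <- truth[hit[1], ]
  alts <- strsplit(r$alt, ",", fixed = TRUE)[[1]]
  gt <- suppressWarnings(as.integer(strsplit(r$gt, "[/|]")[[1]]))
  gt[is.na(gt)] <- 0L
  list(pos = r$pos, ref = r$ref, alt = alts, gt = gt)
}
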