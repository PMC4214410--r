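# Standard-format readers/writers. FASTA/FASTQ go through Biostrings; GFF3
# through rtracklayer/GenomicRanges; VCF is written by a small formatter
# (cross-checked against VariantAnnotation in the tests); AGP v2.1 and the TSV
# tables are plain read/write. GFF3/VCF/AGP coordinates are 1-based inclusive;
# BED-like outputs are 0-based half-open.

#' Write sequences to FASTA (60-column wrapping)
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write paired reads to FASTQ (Phred+33, constant quality)
#' @param reads character vector.
#' @param path output file.
#' @param ids optional read names.
#' @param qual_char quality character (default "I" = Q40).
#' @export
write_fastq <- function(reads, path, ids = NULL, qual_char = "I") {
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(qual_char, n), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path input file.
#' @return named character vector of reads.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write gene models to GFF3
#' @param genes data.frame with id, start, end, strand.
#' @param path output file.
#' @param seqid sequence name.
#' @export
write_gff3 <- function(genes, path, seqid = "chr1") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path input file.
#' @return data.frame with id, start, end, strand.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(id = gr$ID, start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Normalise a call/truth table to VCF allele conventions
#'
#' InDel records gain their left anchor base (VCF convention); SNVs pass
#' through unchanged.
#'
#' @param calls data.frame with pos, ref, alt, type.
#' @param genome the reference sequence the positions refer to.
#' @return the normalised table.
#' @export
vcf_normalise <- function(calls, genome) {
  out <- calls
  for (i in seq_len(nrow(out))) {
    if (out$type[i] == "SNV") next
    p <- out$pos[i]
    if (out$type[i] == "deletion") {
      anchor <- substring(genome, p - 1, p - 1)
      out$pos[i] <- p - 1
      out$alt[i] <- anchor
      out$ref[i] <- paste0(anchor, out$ref[i])
    } else { # insertion before pos
      anchor <- substring(genome, p - 1, p - 1)
      out$pos[i] <- p - 1
      out$ref[i] <- anchor
      out$alt[i] <- paste0(anchor, out$alt[i])
    }
  }
  out
}

#' Write variant calls to VCF 4.2
#'
#' @param calls data.frame with seqid, pos, ref, alt plus optional depth and
#'   alt_fraction (emitted as INFO DP / AF). InDel records must already carry
#'   their anchor base (see the truth tables or [vcf_normalise()]).
#' @param path output file.
#' @param contigs named integer vector of contig lengths for the header.
#' @export
write_vcf <- function(calls, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  calls <- calls[order(calls$seqid, calls$pos), , drop = FALSE]
  info <- rep(".", nrow(calls))
  if (!is.null(calls$depth)) {
    info <- sprintf("DP=%d", as.integer(calls$depth))
    if (!is.null(calls$alt_fraction)) {
      info <- sprintf("%s;AF=%.4f", info, calls$alt_fraction)
    }
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$seqid,
                  as.integer(calls$pos), calls$ref, calls$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file written by this package
#' @param path input file.
#' @return data.frame with seqid, pos, ref, alt, info.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(data.frame(seqid = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      info = character(0)))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  data.frame(seqid = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
             alt = f[, 5], info = f[, 8], stringsAsFactors = FALSE)
}

#' Write an AGP v2.1 file
#' @param agp data.frame from [emit_pseudomolecule()].
#' @param path output file.
#' @export
write_agp <- function(agp, path) {
  lines <- c("##agp-version\t2.1",
             apply(agp, 1, function(r) paste(r, collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read an AGP v2.1 file written by this package
#' @param path input file.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  data.frame(object = f[, 1], object_beg = as.integer(f[, 2]),
             object_end = as.integer(f[, 3]), part_number = as.integer(f[, 4]),
             component_type = f[, 5], component_id = f[, 6],
             component_beg = f[, 7], component_end = f[, 8],
             orientation = f[, 9], stringsAsFactors = FALSE)
}

#' Write a TSV table
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path input file.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a BED-like table (0-based half-open) from 1-based inclusive intervals
#' @param df data.frame with seqid, start, end plus extra columns.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  out <- df
  out$start <- out$start - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
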