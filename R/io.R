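# Readers and writers for the standard formats the pipeline touches, backed
# by Biostrings (FASTA), rtracklayer (GFF3, BED) and Rsamtools /
# GenomicAlignments (SAM).  Internal convention everywhere: 1-based closed
# coordinates, strand-explicit; BED files stay 0-based half-open on disk and
# GFF3 stays 1-based closed, with conversion at the boundary.

.IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

#' Read genome sequences from FASTA
#'
#' Sequences are uppercased and U is mapped to T on input.  Duplicate record
#' ids and non-IUPAC characters are rejected.
#'
#' @param path FASTA file path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(chartr("Uu", "Tt", as.character(ss)))
  bad <- unique(setdiff(unlist(strsplit(seqs, "", fixed = TRUE)), .IUPAC_DNA))
  if (length(bad) > 0L) {
    stop("non-IUPAC character(s) in FASTA: ", paste(bad, collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write genome sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read an annotation index from GFF3
#'
#' Coordinates are kept 1-based closed (the GFF3 convention, also the
#' package-internal one).  Introns absent from the file are derived from the
#' exon structure and stored explicitly.
#'
#' @param path GFF3 file path.
#' @return annotation data.frame with columns `feature_id`, `type`, `chrom`,
#'   `start`, `end`, `strand`, `parent`, `class`, `idx`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get_col <- function(name, default) {
    if (name %in% names(mc)) as.character(mc[[name]]) else
      rep(default, length(gr))
  }
  parent <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) {
      if (length(p) == 0L) NA_character_ else paste(p, collapse = ",")
    }, character(1))
  } else rep(NA_character_, length(gr))
  feats <- data.frame(
    feature_id = get_col("ID", NA_character_),
    type = as.character(mc$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    parent = parent,
    class = get_col("class", NA_character_),
    idx = suppressWarnings(as.integer(get_col("idx", NA_character_))),
    stringsAsFactors = FALSE)
  if (any(!feats$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in GFF3: ",
         paste(unique(setdiff(feats$strand, c("+", "-"))), collapse = ", "))
  }
  if (!any(feats$type == "intron") && any(feats$type == "exon")) {
    feats <- rbind(feats, derive_introns(feats))
  }
  feats
}

#' Write an annotation index to GFF3
#'
#' @param features annotation data.frame (see [read_annotation_gff3()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$source <- "snoforge"
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$feature_id
  S4Vectors::mcols(gr)$Parent <- features$parent
  S4Vectors::mcols(gr)$class <- features$class
  S4Vectors::mcols(gr)$idx <- as.character(features$idx)
  S4Vectors::mcols(gr)$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Derive introns from exon structure
#'
#' Introns are the gaps between consecutive exons of one transcript;
#' `idx` counts introns 1-based along the direction of transcription.
#'
#' @param features annotation data.frame containing `exon` rows with a
#'   `parent` transcript id.
#' @return a data.frame of intron features (same columns).
#' @export
derive_introns <- function(features) {
  ex <- features[features$type == "exon" & !is.na(features$parent), ]
  out <- NULL
  for (tx in unique(ex$parent)) {
    e <- ex[ex$parent == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2L) next
    for (k in seq_len(nrow(e) - 1L)) {
      idx <- if (e$strand[1] == "-") nrow(e) - k else k
      out <- rbind(out, data.frame(
        feature_id = paste0(tx, ".intron", idx), type = "intron",
        chrom = e$chrom[1], start = e$end[k] + 1L, end = e$start[k + 1L] - 1L,
        strand = e$strand[1], parent = tx, class = NA_character_,
        idx = as.integer(idx), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- features[0, ]
  }
  out
}

.SIZE_WINDOWS <- list(mnc_tap_plus = c(50L, 300L), mnc_tap_minus = c(50L, 300L),
                      srna = c(19L, 50L))

#' Read aligned reads from BED6 or SAM
#'
#' BED input (0-based half-open on disk) is converted to the internal 1-based
#' closed convention; the BED score column carries the mismatch count.  SAM
#' input takes the reference span from POS and the CIGAR; the mismatch count
#' is taken from the NM tag when present, else 0.  Reads violating the
#' library's size window are flagged (`in_size_window = FALSE`), not dropped.
#'
#' @param path input file.
#' @param library one of `"mnc_tap_plus"`, `"mnc_tap_minus"`, `"srna"`.
#' @param replicate replicate number recorded on every read.
#' @param format `"bed"`, `"sam"`, or `"auto"` (by file extension).
#' @param genome optional genome bundle; when given, read coordinates are
#'   validated against chromosome bounds.
#' @return a data.frame of aligned reads (same columns as
#'   [simulate_libraries()], plus `in_size_window`).
#' @export
read_alignments <- function(path, library, replicate = 1L,
                            format = c("auto", "bed", "sam"), genome = NULL) {
  library <- match.arg(library, .LIBRARIES)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    mm <- if ("score" %in% names(S4Vectors::mcols(gr))) {
      as.integer(S4Vectors::mcols(gr)$score)
    } else rep(0L, length(gr))
    ids <- if ("name" %in% names(S4Vectors::mcols(gr))) {
      as.character(S4Vectors::mcols(gr)$name)
    } else sprintf("read_%07d", seq_along(gr))
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(what = c("qname"),
                                           tag = "NM"))
    gr <- GenomicRanges::granges(ga)
    tags <- S4Vectors::mcols(ga)$NM
    mm <- if (is.null(tags)) rep(0L, length(ga)) else {
      ifelse(is.na(tags), 0L, as.integer(tags))
    }
    ids <- as.character(S4Vectors::mcols(ga)$qname)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand symbol in alignments: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  }
  reads <- data.frame(
    library = library, replicate = as.integer(replicate), read_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = strand, mismatches = mm, stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    len <- vapply(genome$seq, nchar, integer(1))
    bad <- reads$start < 1L | reads$end > len[reads$chrom] |
      !(reads$chrom %in% names(len))
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      stop("alignment coordinates outside chromosome bounds: ",
           paste(utils::head(reads$read_id[which(bad | is.na(bad))], 3),
                 collapse = ", "))
    }
  }
  win <- .SIZE_WINDOWS[[library]]
  width <- reads$end - reads$start + 1L
  reads$in_size_window <- width >= win[1] & width <= win[2]
  reads[, c("library", "replicate", "read_id", "chrom", "strand",
            "start", "end", "mismatches", "in_size_window")]
}

#' Write aligned reads to BED6
#'
#' Internal 1-based closed intervals are converted to BED's 0-based
#' half-open; the read id goes in the name column and the mismatch count in
#' the score column.
#'
#' @param reads aligned-read data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(reads$start, reads$end),
    strand = reads$strand)
  S4Vectors::mcols(gr)$name <- reads$read_id
  S4Vectors::mcols(gr)$score <- reads$mismatches
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read a tab-separated table with a provenance header
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param header_note character comment lines (without the leading `#`).
#' @return `path` (write) or the data.frame (read).
#' @export
write_tsv <- function(df, path, header_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_note)) {
    writeLines(paste0("# ", header_note), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assemble a genome bundle from sequences and annotation
#'
#' @param seq named character vector of chromosome sequences.
#' @param features annotation data.frame; introns are derived from exons when
#'   absent.
#' @return a `genome_bundle` (list with `$seq` and `$features`).
#' @export
genome_bundle <- function(seq, features) {
  if (!any(features$type == "intron") && any(features$type == "exon")) {
    features <- rbind(features, derive_introns(features))
  }
  structure(list(seq = seq, features = features), class = "genome_bundle")
}

#' Query annotation features overlapping an interval
#'
#' @param genome a genome bundle.
#' @param chrom,start,end interval (1-based closed).
#' @param strand optional strand filter (`"+"`, `"-"`, or `NULL` for both).
#' @param types optional feature-type filter.
#' @return the overlapping rows of the annotation data.frame.
#' @export
features_overlapping <- function(genome, chrom, start, end, strand = NULL,
                                 types = NULL) {
  f <- genome$features
  keep <- f$chrom == chrom & f$start <= end & f$end >= start
  if (!is.null(strand)) keep <- keep & f$strand == strand
  if (!is.null(types)) keep <- keep & f$type %in% types
  f[keep, , drop = FALSE]
}
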