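#' Read a FASTA file with strict validation
#'
#' Thin wrapper around the Biostrings FASTA reader that enforces the
#' contracts the pipeline relies on: record ids unique within the file,
#' no empty records, sequences uppercased. CRLF files parse identically to
#' LF files. Errors report the offending record's header line number.
#'
#' @param path file path.
#' @param type \code{"AA"}, \code{"DNA"}, or \code{"auto"} (guess from the
#'   alphabet).
#' @return an \code{AAStringSet} or \code{DNAStringSet}.
#' @seealso [writeFastaFile()]
#' @export
readFastaFile <- function(path, type = c("auto", "AA", "DNA")) {
    type <- match.arg(type)
    if (!file.exists(path)) .stop_input("file not found: %s", path)
    x <- Biostrings::readBStringSet(path)
    nm <- sub("\r$", "", names(x))
    seqs <- toupper(gsub("\r", "", as.character(x)))
    .header_line <- function(k) {
        lines <- readLines(path, warn = FALSE)
        which(startsWith(lines, ">"))[k]
    }
    if (anyDuplicated(nm)) {
        k <- which(duplicated(nm))[1L]
        .stop_input("duplicate FASTA id '%s' at line %d", nm[k],
                    .header_line(k))
    }
    if (any(nchar(seqs) == 0L)) {
        k <- which(nchar(seqs) == 0L)[1L]
        .stop_input("empty FASTA record '%s' at line %d", nm[k],
                    .header_line(k))
    }
    if (type == "auto") {
        letters <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
        type <- if (all(letters %in% c("A", "C", "G", "T", "N"))) "DNA"
                else "AA"
    }
    out <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
           else Biostrings::AAStringSet(seqs)
    names(out) <- nm
    out
}

#' Write sequences as 60-column FASTA
#'
#' Writing then reading back with [readFastaFile()] is the identity, and the
#' byte layout is stable (60-column wrapping, LF line endings).
#'
#' @param x an \code{XStringSet}.
#' @param path output path.
#' @export
writeFastaFile <- function(x, path) {
    Biostrings::writeXStringSet(x, path, width = 60L)
    invisible(path)
}

#' Read and write the GFF-lite gene coordinate table
#'
#' A 5-column TSV with header: strain, gene_id, start, end, strand.
#' Coordinates are 0-based half-open.
#'
#' @param path file path.
#' @return \code{readGffLite}: a data.frame with the five columns.
#' @export
readGffLite <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("strain", "gene_id", "start", "end", "strand")
    if (!all(need %in% names(df)))
        .stop_input("GFF-lite file %s must have columns: %s", path,
                    paste(need, collapse = ", "))
    df[need]
}

#' @rdname readGffLite
#' @param df a data.frame with columns strain, gene_id, start, end, strand.
#' @export
writeGffLite <- function(df, path) {
    need <- c("strain", "gene_id", "start", "end", "strand")
    stopifnot(all(need %in% names(df)))
    write.table(df[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Genome summary statistics
#'
#' Per-replicon and total summary rows computed from the sequences and the
#' CDS coordinate table: replicon length, GC percentage (ambiguous bases
#' excluded), CDS count, coding percentage (overlapping CDS merged before
#' summing) and mean CDS length (rounded half-up). The totals row satisfies
#' total length = sum of replicon lengths and total CDS = sum of replicon
#' CDS counts.
#'
#' @param replicons named \code{DNAStringSet} of replicon sequences.
#' @param cdsTable data.frame with columns \code{strain} (the replicon name),
#'   \code{gene_id}, \code{start}, \code{end} (0-based half-open).
#' @return data.frame with one row per replicon plus a \code{"total"} row;
#'   columns replicon, length_bp, gc_percent, n_cds, coding_percent,
#'   mean_cds_len_bp.
#' @seealso [summaryTotals()] for the totals arithmetic alone.
#' @export
genomeSummary <- function(replicons, cdsTable) {
    stopifnot(!is.null(names(replicons)))
    rows <- lapply(names(replicons), function(r) {
        seq <- replicons[[r]]
        len <- length(seq)
        cds <- cdsTable[cdsTable$strain == r, , drop = FALSE]
        if (nrow(cds)) {
            if (any(cds$start < 0) || any(cds$end > len) ||
                any(cds$end <= cds$start)) {
                bad <- cds$gene_id[which(cds$start < 0 | cds$end > len |
                                         cds$end <= cds$start)[1L]]
                .stop_input("CDS '%s' out of bounds on replicon '%s'", bad, r)
            }
            ir <- IRanges::reduce(IRanges::IRanges(start = cds$start + 1L,
                                                   end = cds$end))
            span <- sum(IRanges::width(ir))
            mean_len <- floor(mean(cds$end - cds$start) + 0.5)
        } else {
            span <- 0L
            mean_len <- NA_integer_
        }
        counts <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
        data.frame(replicon = r, length_bp = len,
                   gc_percent = round(100 * sum(counts[c("C", "G")]) /
                                      sum(counts), 2),
                   n_cds = nrow(cds),
                   coding_percent = round(100 * span / len, 2),
                   mean_cds_len_bp = mean_len, stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    rbind(per, summaryTotals(per))
}

#' Totals row of a genome summary table
#'
#' Computes the totals row from per-replicon summary rows: total length and
#' CDS count are straight sums; GC and coding percentages are
#' length-weighted means; the mean CDS length is the CDS-count-weighted mean
#' (rounded half-up).
#'
#' @param per data.frame of per-replicon rows as produced by
#'   [genomeSummary()] (columns replicon, length_bp, gc_percent, n_cds,
#'   coding_percent, mean_cds_len_bp).
#' @return a one-row data.frame with \code{replicon == "total"}.
#' @examples
#' per <- data.frame(replicon = c("chr", "plasmid"),
#'                   length_bp = c(1000L, 100L), gc_percent = c(40, 30),
#'                   n_cds = c(10L, 1L), coding_percent = c(80, 60),
#'                   mean_cds_len_bp = c(80L, 60L))
#' summaryTotals(per)
#' @export
summaryTotals <- function(per) {
    w <- per$length_bp / sum(per$length_bp)
    has_cds <- per$n_cds > 0
    mean_cds <- if (any(has_cds))
        floor(sum(per$mean_cds_len_bp[has_cds] * per$n_cds[has_cds]) /
              sum(per$n_cds[has_cds]) + 0.5) else NA_integer_
    data.frame(replicon = "total",
               length_bp = sum(per$length_bp),
               gc_percent = round(sum(per$gc_percent * w), 2),
               n_cds = sum(per$n_cds),
               coding_percent = round(sum(per$coding_percent * w), 2),
               mean_cds_len_bp = mean_cds, stringsAsFactors = FALSE)
}

#' Read and write a square PHYLIP distance matrix
#'
#' @param d symmetric numeric matrix with taxon dimnames.
#' @param path file path.
#' @return \code{readPhylip}: the matrix.
#' @export
writePhylip <- function(d, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
        writeLines(paste(formatC(rownames(d)[i], width = -10),
                         paste(sprintf("%.8f", d[i, ]), collapse = "  ")),
                   con)
    }
    invisible(path)
}

#' @rdname writePhylip
#' @export
readPhylip <- function(path) {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1L]))
    parts <- strsplit(trimws(lines[1L + seq_len(n)]), "[[:space:]]+")
    taxa <- vapply(parts, `[[`, "", 1L)
    d <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
    dimnames(d) <- list(taxa, taxa)
    d
}

#' Read and write similarity hits in BLAST outfmt-6 layout
#'
#' Twelve tab-separated columns in the standard order: qseqid, sseqid,
#' pident (percentage), length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore. [writeHits()] maps the package's fractional
#' identity to the percentage convention of the format.
#'
#' @param hits data.frame of hits as produced by [allVsAll()].
#' @param path file path.
#' @return \code{readHits}: data.frame with the 12 columns plus
#'   \code{identity} (fraction).
#' @export
writeHits <- function(hits, path) {
    out <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                      pident = round(100 * hits$identity, 2),
                      length = hits$aln_length, mismatch = hits$mismatches,
                      gapopen = hits$gap_opens, qstart = hits$q_start,
                      qend = hits$q_end, sstart = hits$s_start,
                      send = hits$s_end,
                      evalue = signif(hits$e_value, 3),
                      bitscore = round(hits$bit_score, 1))
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    df <- read.delim(path, header = FALSE, col.names = cols,
                     stringsAsFactors = FALSE)
    df$identity <- df$pident / 100
    df
}
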