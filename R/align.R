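.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protein alignment scoring parameters
#'
#' Smith-Waterman scoring used throughout the protein side of the pipeline:
#' BLOSUM62 with affine gaps (a gap of length L costs
#' \code{gapOpening + L * gapExtension}; 11 and 1 are the conventional
#' defaults of the BLAST protein ecosystem). Unknown residues \code{X} score
#' 0 against everything. Raw scores are converted to bit scores with the
#' standard Karlin-Altschul transformation
#' \code{S' = (lambda * S - ln K) / ln 2} using the gapped BLOSUM62
#' constants.
#'
#' @param gapOpening,gapExtension affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul constants for the bit-score conversion.
#' @return a list of class \code{pg_scoring} with the substitution matrix
#'   and parameters.
#' @export
scoringParams <- function(gapOpening = 11, gapExtension = 1,
                          lambda = 0.267, K = 0.041) {
    mat <- .blosum62_x0()
    structure(list(matrix = mat, gapOpening = gapOpening,
                   gapExtension = gapExtension, lambda = lambda, K = K),
              class = "pg_scoring")
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62_x0 <- function() {
    if (is.null(.blosum62_cache$mat)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        mat <- e$BLOSUM62
        mat["X", ] <- 0L
        mat[, "X"] <- 0L
        .blosum62_cache$mat <- mat
    }
    .blosum62_cache$mat
}

.check_protein <- function(seq, what) {
    s <- as.character(seq)
    if (!nzchar(s)) .stop_input("empty %s sequence", what)
    letters <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(letters, c(.AA20, "X"))
    if (length(bad))
        .stop_input("unknown residue '%s' in %s sequence", bad[1L], what)
    s
}

.bit_score <- function(raw, scoring) {
    (scoring$lambda * raw - log(scoring$K)) / log(2)
}

# Hit statistics from a PairwiseAlignments object (vectorized).
.hit_stats <- function(pa, len_q, len_s, scoring) {
    aln_len <- Biostrings::nchar(pa)
    nmatch <- Biostrings::nmatch(pa)
    span_q <- IRanges::end(Biostrings::pattern(pa)) -
        IRanges::start(Biostrings::pattern(pa)) + 1L
    span_s <- IRanges::end(Biostrings::subject(pa)) -
        IRanges::start(Biostrings::subject(pa)) + 1L
    longest <- pmax(len_q, len_s)
    bits <- .bit_score(Biostrings::score(pa), scoring)
    ins <- Biostrings::nindel(pa)@insertion
    del <- Biostrings::nindel(pa)@deletion
    gaps_q <- ins[, "WidthSum"]
    gaps_s <- del[, "WidthSum"]
    opens <- ins[, "Length"] + del[, "Length"]
    data.frame(
        identity = ifelse(aln_len > 0, nmatch / aln_len, 0),
        coverage = pmax(span_q, span_s) / longest,
        bit_score = bits,
        e_value = eValue(bits, len_q, len_s),
        aln_length = aln_len,
        mismatches = aln_len - nmatch - gaps_q - gaps_s,
        gap_opens = opens,
        q_start = IRanges::start(Biostrings::pattern(pa)),
        q_end = IRanges::end(Biostrings::pattern(pa)),
        s_start = IRanges::start(Biostrings::subject(pa)),
        s_end = IRanges::end(Biostrings::subject(pa))
    )
}

#' Align two proteins locally and report the similarity hit
#'
#' Smith-Waterman local alignment under the configured scoring. The
#' identity is the fraction of identical columns over all alignment columns
#' (gap columns count in the denominator but never the numerator); the
#' coverage is the aligned span divided by the length of the longer of the
#' two sequences, so a self-hit always has identity 1 and coverage 1 and
#' swapping the sequences changes neither.
#'
#' @param a,b protein sequences (\code{AAString} or character) over the
#'   20-letter alphabet; \code{X} is tolerated and scores 0.
#' @param scoring a [scoringParams()] list.
#' @return one-row data.frame: query_id, subject_id, identity, coverage,
#'   bit_score, e_value, aln_length, mismatches, gap_opens and the 1-based
#'   alignment spans.
#' @examples
#' alignProteins("ACDEFGHIKL", "ACDEFGHIKV")$identity
#' @export
alignProteins <- function(a, b, scoring = scoringParams()) {
    sa <- .check_protein(a, "first")
    sb <- .check_protein(b, "second")
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(sa), Biostrings::AAString(sb), type = "local",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
    cbind(data.frame(query_id = if (!is.null(names(a))) names(a) else "a",
                     subject_id = if (!is.null(names(b))) names(b) else "b",
                     stringsAsFactors = FALSE),
          .hit_stats(pa, nchar(sa), nchar(sb), scoring))
}

#' Expectation value from a bit score
#'
#' The standard bit-score identity \code{E = m * n * 2^(-S')}: monotone
#' decreasing in the score and linear in both sequence lengths.
#'
#' @param bitScore bit score (>= 0).
#' @param m,n the two sequence lengths (>= 1).
#' @return the expectation value.
#' @examples
#' eValue(0, 1, 1)   # 1
#' @export
eValue <- function(bitScore, m, n) {
    if (any(bitScore < 0) || any(m < 1) || any(n < 1))
        .stop_input("eValue needs bitScore >= 0 and m, n >= 1")
    m * n * 2^(-bitScore)
}

#' Hit-filtering thresholds for ortholog clustering
#'
#' The defaults follow the gene-family clustering convention the pipeline is
#' built around: at least 50\% identity, at least 50\% coverage of the
#' longer sequence, and an e-value of at most 1e-5.
#'
#' @param minIdentity minimum identity fraction.
#' @param minCoverage minimum coverage-of-longest fraction.
#' @param maxEvalue maximum e-value.
#' @return a list of class \code{pg_thresholds}.
#' @export
clusterThresholds <- function(minIdentity = 0.5, minCoverage = 0.5,
                              maxEvalue = 1e-5) {
    structure(list(minIdentity = minIdentity, minCoverage = minCoverage,
                   maxEvalue = maxEvalue), class = "pg_thresholds")
}

#' All-vs-all protein similarity search
#'
#' Exhaustive Smith-Waterman comparison of every gene pair across the panel
#' (desk-scale inputs make full dynamic programming feasible; there is no
#' heuristic seeding). Exactly one undirected hit is emitted per pair that
#' passes all thresholds; self-hits are excluded.
#'
#' @param proteomes named list of \code{AAStringSet}, one per strain, with
#'   globally unique gene names.
#' @param scoring a [scoringParams()] list.
#' @param thresholds a [clusterThresholds()] list.
#' @return data.frame of passing hits with query/subject strain and gene
#'   ids plus the columns of [alignProteins()].
#' @seealso [clusterFamilies()]
#' @export
allVsAll <- function(proteomes, scoring = scoringParams(),
                     thresholds = clusterThresholds()) {
    if (length(proteomes) < 1L) .stop_input("need at least one proteome")
    all_genes <- do.call(c, unname(lapply(proteomes, as.character)))
    strain_of <- rep(names(proteomes), vapply(proteomes, length, 0L))
    ids <- unlist(lapply(proteomes, names), use.names = FALSE)
    if (anyDuplicated(ids))
        .stop_input("duplicate gene id '%s'", ids[which(duplicated(ids))[1L]])
    names(all_genes) <- ids
    set <- Biostrings::AAStringSet(all_genes)
    lens <- Biostrings::width(set)
    G <- length(set)
    out <- vector("list", G)
    for (i in seq_len(G - 1L)) {
        js <- (i + 1L):G
        pa <- Biostrings::pairwiseAlignment(
            set[js], set[[i]], type = "local",
            substitutionMatrix = scoring$matrix,
            gapOpening = scoring$gapOpening,
            gapExtension = scoring$gapExtension)
        st <- .hit_stats(pa, lens[js], lens[i], scoring)
        keep <- st$identity >= thresholds$minIdentity &
            st$coverage >= thresholds$minCoverage &
            st$e_value <= thresholds$maxEvalue
        if (any(keep)) {
            st <- st[keep, , drop = FALSE]
            out[[i]] <- cbind(
                data.frame(query_id = ids[i], query_strain = strain_of[i],
                           subject_id = ids[js][keep],
                           subject_strain = strain_of[js][keep],
                           stringsAsFactors = FALSE),
                st)
        }
    }
    hits <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(hits)) {
        hits <- data.frame(query_id = character(), query_strain = character(),
                           subject_id = character(),
                           subject_strain = character(), identity = numeric(),
                           coverage = numeric(), bit_score = numeric(),
                           e_value = numeric(), aln_length = integer(),
                           mismatches = integer(), gap_opens = integer(),
                           q_start = integer(), q_end = integer(),
                           s_start = integer(), s_end = integer())
    }
    rownames(hits) <- NULL
    hits
}
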