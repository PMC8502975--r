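#' Fragment-based ANI parameters
#'
#' Defaults follow the classical fragment-based ANI recipe: the query
#' genome is cut into consecutive 1,020-bp fragments, each fragment is
#' locally aligned to the whole subject genome, and a fragment is retained
#' when its alignment identity is at least 30\% and its alignable span
#' covers at least 70\% of the fragment. Nucleotide scoring is +1/-1 with
#' affine gaps (open 4, extend 1).
#'
#' @param fragmentLen fragment length in bp.
#' @param minIdentity fragment retention identity threshold (fraction).
#' @param minAlnFrac minimum alignable span as a fraction of fragment
#'   length.
#' @param match,mismatch,gapOpening,gapExtension nucleotide scoring.
#' @return a list of class \code{pg_ani_params}.
#' @export
aniParams <- function(fragmentLen = 1020L, minIdentity = 0.30,
                      minAlnFrac = 0.70, match = 1, mismatch = -1,
                      gapOpening = 4, gapExtension = 1) {
    structure(list(fragmentLen = as.integer(fragmentLen),
                   minIdentity = minIdentity, minAlnFrac = minAlnFrac,
                   match = match, mismatch = mismatch,
                   gapOpening = gapOpening, gapExtension = gapExtension),
              class = "pg_ani_params")
}

.as_dna <- function(x, what) {
    if (is.character(x)) {
        if (length(x) != 1L) .stop_input("%s must be a single sequence", what)
        Biostrings::DNAString(x)
    } else if (methods::is(x, "DNAStringSet")) {
        if (length(x) != 1L) .stop_input("%s must be a single sequence", what)
        x[[1L]]
    } else if (methods::is(x, "DNAString")) {
        x
    } else {
        .stop_input("%s must be a DNAString or character", what)
    }
}

#' Directional fragment-based average nucleotide identity
#'
#' Cuts \code{genomeA} into consecutive non-overlapping fragments, locally
#' aligns each fragment against the whole of \code{genomeB}, retains
#' fragments passing the identity and alignable-span thresholds, and
#' reports the mean identity of retained fragments as a percentage. When no
#' fragment survives the filter the ANI is undefined and \code{NA} is
#' returned (never 0).
#'
#' @param genomeA,genomeB genome sequences (\code{DNAString} or character);
#'   both must be at least twice the fragment length.
#' @param params an [aniParams()] list.
#' @return list with \code{ani} (percentage or NA) and \code{n_fragments}
#'   (retained fragment count).
#' @seealso [aniMatrix()] for the symmetric direction-mean over a panel.
#' @export
computeAni <- function(genomeA, genomeB, params = aniParams()) {
    a <- .as_dna(genomeA, "genomeA")
    b <- .as_dna(genomeB, "genomeB")
    fl <- params$fragmentLen
    if (length(a) < 2L * fl || length(b) < 2L * fl)
        .stop_input("genome too short for ANI: need >= %d bp, got %d and %d",
                    2L * fl, length(a), length(b))
    starts <- seq(1L, length(a) - fl + 1L, by = fl)
    frags <- Biostrings::DNAStringSet(
        vapply(starts, function(s)
            as.character(Biostrings::subseq(a, s, s + fl - 1L)), ""))
    mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
        frags, b, type = "local", substitutionMatrix = mat,
        gapOpening = params$gapOpening, gapExtension = params$gapExtension)
    aln_len <- Biostrings::nchar(pa)
    identity <- ifelse(aln_len > 0, Biostrings::nmatch(pa) / aln_len, 0)
    span <- IRanges::end(Biostrings::pattern(pa)) -
        IRanges::start(Biostrings::pattern(pa)) + 1L
    keep <- identity >= params$minIdentity & span >= params$minAlnFrac * fl
    if (!any(keep)) return(list(ani = NA_real_, n_fragments = 0L))
    list(ani = 100 * mean(identity[keep]), n_fragments = sum(keep))
}

#' ANI matrix over a genome panel
#'
#' Computes the directional fragment-based ANI for every ordered pair and
#' reports the mean of the two directions as the pair's symmetric value.
#' The diagonal is exactly 100. Per-pair failures (e.g. a genome too short)
#' are recorded as NA rather than aborting the panel.
#'
#' @param genomes named \code{DNAStringSet} (or named list of sequences)
#'   with at least two genomes.
#' @param params an [aniParams()] list.
#' @return an [AniMatrix-class].
#' @export
aniMatrix <- function(genomes, params = aniParams()) {
    if (is.list(genomes))
        genomes <- Biostrings::DNAStringSet(
            vapply(genomes, as.character, ""))
    n <- length(genomes)
    if (n < 2L) .stop_input("need at least 2 genomes")
    ids <- names(genomes)
    if (is.null(ids)) .stop_input("genomes must be named")
    dir_ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    nfrag <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        res <- tryCatch(computeAni(genomes[[i]], genomes[[j]], params),
                        error = function(e) list(ani = NA_real_,
                                                 n_fragments = 0L))
        dir_ani[i, j] <- res$ani
        nfrag[i, j] <- res$n_fragments
    }
    vals <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) { vals[i, j] <- 100; next }
        two <- c(dir_ani[i, j], dir_ani[j, i])
        vals[i, j] <- if (all(is.na(two))) NA_real_ else mean(two, na.rm = TRUE)
    }
    new("AniMatrix", values = vals, nFragments = nfrag)
}

#' Group strains into species at an ANI threshold
#'
#' Species groups are the connected components of the graph with an edge
#' between two strains whenever their ANI exceeds the threshold (the
#' conventional same-species boundary is 95\%). Undefined (NA) pairs count
#' as below threshold. Raising the threshold can only split groups, never
#' merge them.
#'
#' @param mat an [AniMatrix-class].
#' @param threshold ANI percentage; edges require ANI strictly above it.
#' @return a [SpeciesGrouping-class].
#' @export
speciesGroups <- function(mat, threshold = 95) {
    v <- aniValues(mat)
    ids <- rownames(v)
    adj <- !is.na(v) & v > threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
    comp <- igraph::components(g)$membership
    grp <- split(ids, comp)
    grp <- grp[order(vapply(grp, min, ""))]
    names(grp) <- NULL
    new("SpeciesGrouping", threshold = threshold, groups = grp)
}

#' Write an ANI matrix as TSV
#'
#' @param mat an [AniMatrix-class].
#' @param path file path.
#' @export
writeAniMatrix <- function(mat, path) {
    v <- aniValues(mat)
    df <- data.frame(strain = rownames(v), round(v, 4), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
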