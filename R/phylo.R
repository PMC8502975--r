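#' Single-copy core families
#'
#' Families with copy count exactly 1 in every strain: the input for the
#' concatenated core phylogeny. Families with any zero or any paralogous
#' extra copy are excluded.
#'
#' @param mat a [PresenceAbsenceMatrix-class].
#' @return character vector of family ids (possibly empty).
#' @export
singleCopyCore <- function(mat) {
    m <- famCounts(mat)
    rownames(m)[rowSums(m == 1L) == ncol(m)]
}

# Global-alignment p-distance counts for one sequence pair: differing and
# total columns where neither sequence is gapped.
.pdist_counts <- function(a, b, scoring) {
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ok <- p != "-" & s != "-"
    c(diff = sum(p[ok] != s[ok]), cols = sum(ok))
}

# Per-family, per-pair difference/column counts for a set of single-copy
# families; the cached substrate for concatenated distances and the family
# bootstrap.
.family_pair_stats <- function(families, proteomes, familyIds, scoring) {
    taxa <- names(proteomes)
    pairs <- utils::combn(taxa, 2L)
    np <- ncol(pairs)
    nf <- length(familyIds)
    diffs <- cols <- matrix(0, nf, np,
                            dimnames = list(familyIds, NULL))
    gene_of <- function(f, s) {
        g <- families$gene_id[families$family_id == f & families$strain == s]
        if (length(g) != 1L)
            .stop_input("family '%s' is not single-copy in strain '%s'", f, s)
        g
    }
    seqs <- lapply(familyIds, function(f)
        setNames(lapply(taxa, function(s)
            as.character(proteomes[[s]][[gene_of(f, s)]])), taxa))
    for (fi in seq_len(nf)) {
        for (pi in seq_len(np)) {
            cnt <- .pdist_counts(seqs[[fi]][[pairs[1L, pi]]],
                                 seqs[[fi]][[pairs[2L, pi]]], scoring)
            diffs[fi, pi] <- cnt["diff"]
            cols[fi, pi] <- cnt["cols"]
        }
    }
    list(taxa = taxa, pairs = pairs, diffs = diffs, cols = cols)
}

.pairs_to_matrix <- function(taxa, pairs, vals) {
    n <- length(taxa)
    d <- matrix(0, n, n, dimnames = list(taxa, taxa))
    for (pi in seq_len(ncol(pairs))) {
        d[pairs[1L, pi], pairs[2L, pi]] <- vals[pi]
        d[pairs[2L, pi], pairs[1L, pi]] <- vals[pi]
    }
    d
}

#' Concatenated p-distances over single-copy core families
#'
#' For every strain pair, globally aligns the two members of each family,
#' pools the aligned columns across families, and reports the p-distance:
#' the proportion of differing columns among columns where neither sequence
#' is gapped. Identical proteomes give an all-zero matrix.
#'
#' @param families data.frame from [clusterFamilies()].
#' @param proteomes named list of \code{AAStringSet}, one per strain (at
#'   least 3 strains).
#' @param familyIds families to concatenate; defaults to all families that
#'   are single-copy in every strain. A claimed family missing a member
#'   for some strain is a consistency error.
#' @param scoring a [scoringParams()] list (global alignment mode).
#' @return symmetric distance matrix with zero diagonal; the per-family
#'   counts are attached as attribute \code{"familyStats"} for reuse by
#'   [bootstrapSupport()].
#' @export
concatDistances <- function(families, proteomes, familyIds = NULL,
                            scoring = scoringParams()) {
    if (length(proteomes) < 3L) .stop_input("need at least 3 strains")
    if (is.null(familyIds)) {
        mat <- buildMatrix(families, strains = names(proteomes))
        familyIds <- singleCopyCore(mat)
    }
    if (!length(familyIds)) .stop_input("no single-copy core families")
    st <- .family_pair_stats(families, proteomes, familyIds, scoring)
    tot_cols <- pmax(colSums(st$cols), 1)
    d <- .pairs_to_matrix(st$taxa, st$pairs, colSums(st$diffs) / tot_cols)
    attr(d, "familyStats") <- st
    d
}

#' Neighbor-joining tree
#'
#' Canonical agglomeration with the Q-criterion: at each step the pair
#' minimizing \code{Q(i,j) = (r-2) d(i,j) - R_i - R_j} is joined, ties
#' broken deterministically by the lexicographically lowest pair of node
#' labels (a merged node is labelled by its smallest member). Negative
#' branch lengths are clamped to 0. On an additive distance matrix the
#' generating tree is recovered exactly. The result is unrooted (a basal
#' trifurcation); use \code{ape::root()} to root at an outgroup leaf.
#'
#' @param d symmetric non-negative matrix with taxon dimnames, zero
#'   diagonal, at least 3 taxa. Non-symmetric input is an error.
#' @return an \code{ape::phylo} tree.
#' @examples
#' d <- matrix(c(0,3,7,8, 3,0,8,9, 7,8,0,9, 8,9,9,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' njTree(d)
#' @export
njTree <- function(d) {
    d <- unclass(d)
    attr(d, "familyStats") <- NULL
    if (!is.matrix(d) || nrow(d) != ncol(d))
        .stop_input("distance input must be a square matrix")
    if (max(abs(d - t(d))) > 1e-9)
        .stop_input("distance matrix must be symmetric")
    if (is.null(rownames(d))) .stop_input("distance matrix needs taxon names")
    n <- nrow(d)
    if (n < 3L) .stop_input("need at least 3 taxa")

    labs <- rownames(d)          # representative (smallest leaf) per node
    nwk <- labs                  # newick fragment per active node
    D <- d
    fmt <- function(x) sprintf("%.12g", max(x, 0))

    while (length(labs) > 3L) {
        r <- length(labs)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, "+")
        diag(Q) <- Inf
        qmin <- min(Q)
        cand <- which(Q <= qmin + 1e-9 * (abs(qmin) + 1), arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        key1 <- pmin(labs[cand[, 1L]], labs[cand[, 2L]])
        key2 <- pmax(labs[cand[, 1L]], labs[cand[, 2L]])
        pick <- order(key1, key2)[1L]
        i <- cand[pick, 1L]; j <- cand[pick, 2L]
        li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        lj <- D[i, j] - li
        merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
        dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                    c(dk[keep], 0))
        labs <- c(labs[keep], min(labs[i], labs[j]))
        nwk <- c(nwk[keep], merged)
        dimnames(D2) <- list(labs, labs)
        D <- D2
    }
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    text <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2], fmt(lb),
                    nwk[3], fmt(lc))
    ape::read.tree(text = text)
}

#' Family-bootstrap supports for the concatenated NJ tree
#'
#' Resamples gene families with replacement, recomputes the pooled
#' p-distances and the NJ tree per replicate, and reports for each internal
#' edge of the original tree the percentage of replicates containing the
#' same bipartition. Family-level resampling (rather than column-level) is
#' the standard unit for concatenated gene sets. Seeded runs reproduce
#' bit-exactly.
#'
#' @param families,proteomes,familyIds,scoring as in [concatDistances()].
#' @param nReps number of bootstrap replicates.
#' @param seed integer seed.
#' @return the original NJ tree with \code{node.label} set to integer
#'   support percentages (NA on the basal node, whose trivial bipartition
#'   has no support value).
#' @export
bootstrapSupport <- function(families, proteomes, nReps = 500L, seed = 1L,
                             familyIds = NULL, scoring = scoringParams()) {
    if (nReps < 1L) .stop_input("nReps must be >= 1")
    d <- concatDistances(families, proteomes, familyIds, scoring)
    st <- attr(d, "familyStats")
    orig <- njTree(d)
    reps <- .with_seed(seed, {
        lapply(seq_len(nReps), function(rep) {
            idx <- sample.int(nrow(st$diffs), replace = TRUE)
            cols <- pmax(colSums(st$cols[idx, , drop = FALSE]), 1)
            vals <- colSums(st$diffs[idx, , drop = FALSE]) / cols
            njTree(.pairs_to_matrix(st$taxa, st$pairs, vals))
        })
    })
    counts <- ape::prop.clades(orig, reps, rooted = FALSE)
    orig$node.label <- as.integer(round(100 * counts / nReps))
    orig
}
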